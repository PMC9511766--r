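#' @import methods
#' @importFrom GenomicRanges GRanges GRangesList
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols
#' @importFrom S4Vectors mcols<-
#' @importFrom IRanges CharacterList
#' @importFrom GenomeInfoDb seqnames seqlevels seqlengths
#' @importFrom GenomeInfoDb seqlengths<-
#' @importFrom GenomeInfoDb seqlevels<-
#' @importFrom stats setNames
NULL

## ---------------------------------------------------------------------------
## GenotypePanel: diploid genotypes for a set of samples over a site table.
##
## Coordinates follow VCF convention (1-based positions) at this boundary;
## window and BED interval arithmetic is 0-based half-open internally.
## ---------------------------------------------------------------------------

#' GenotypePanel: labeled diploid genotypes over a SNP site table
#'
#' Holds two sites-by-samples integer matrices of allele indices (0 = REF,
#' 1 = first ALT, ...; `NA` = missing/uncalled), a [GenomicRanges::GRanges]
#' of sites (1-based VCF positions, with `ref` and `alt` metadata columns),
#' and a group label per sample (typically `"wild"` and `"classical_inbred"`).
#' Genotypes are unphased; ploidy is fixed at 2.
#'
#' @slot a1,a2 integer matrices, sites x samples; the two allele indices of
#'   each diploid genotype (order carries no meaning).
#' @slot sites `GRanges` with one range per SNP, width 1, metadata columns
#'   `ref` (character) and `alt` (`CharacterList`, one or more ALT alleles).
#' @slot groups factor of length `ncol(a1)`, the group label of each sample.
#' @export
setClass("GenotypePanel",
    slots = c(a1 = "matrix", a2 = "matrix", sites = "GRanges",
              groups = "factor"))

setValidity("GenotypePanel", function(object) {
    msg <- character()
    if (!identical(dim(object@a1), dim(object@a2)))
        msg <- c(msg, "a1 and a2 must have identical dimensions")
    if (nrow(object@a1) != length(object@sites))
        msg <- c(msg, "number of matrix rows must equal number of sites")
    if (length(object@groups) != ncol(object@a1))
        msg <- c(msg, "one group label required per sample")
    if (is.null(colnames(object@a1)))
        msg <- c(msg, "samples must be named (matrix column names)")
    if (!all(c("ref", "alt") %in% names(mcols(object@sites))))
        msg <- c(msg, "sites must carry 'ref' and 'alt' metadata columns")
    if (length(object@sites) > 1L && S4Vectors::isSorted(object@sites) == FALSE)
        msg <- c(msg, "sites must be sorted by (chrom, pos)")
    xor_na <- is.na(object@a1) != is.na(object@a2)
    if (any(xor_na))
        msg <- c(msg, "half-missing genotypes are not supported")
    if (length(msg)) msg else TRUE
})

#' Construct a GenotypePanel
#'
#' @param a1,a2 integer matrices (sites x samples) of allele indices; `NA`
#'   marks a missing genotype (both matrices must agree on missingness).
#' @param sites `GRanges` of SNP positions with `ref`/`alt` metadata columns.
#' @param groups character or factor of per-sample group labels, in column
#'   order (or named by sample).
#' @return A `GenotypePanel`.
#' @examples
#' sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 200), width = 1),
#'     ref = c("A", "T"), alt = S4Vectors::CharacterList("G", "C"))
#' a1 <- matrix(c(0L, 1L, 0L, 0L), 2, 2, dimnames = list(NULL, c("s1", "s2")))
#' gp <- GenotypePanel(a1, a1, sites, c(s1 = "wild", s2 = "classical_inbred"))
#' nSites(gp)
#' @export
GenotypePanel <- function(a1, a2, sites, groups) {
    storage.mode(a1) <- "integer"
    storage.mode(a2) <- "integer"
    if (!is.null(names(groups)))
        groups <- groups[colnames(a1)]
    new("GenotypePanel", a1 = a1, a2 = a2, sites = sites,
        groups = as.factor(unname(groups)))
}

#' @rdname GenotypePanel-accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))
#' @rdname GenotypePanel-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname GenotypePanel-accessors
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))
#' @rdname GenotypePanel-accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))
#' @rdname GenotypePanel-accessors
#' @export
setGeneric("siteRanges", function(x) standardGeneric("siteRanges"))
#' @rdname GenotypePanel-accessors
#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))

#' Accessors for GenotypePanel
#'
#' `nSites()`/`nSamples()` give panel dimensions; `sampleNames()` and
#' `sampleGroups()` the sample labels; `siteRanges()` the site `GRanges`;
#' `alleles()` the pair of allele-index matrices as `list(a1, a2)`.
#'
#' @param x A `GenotypePanel`.
#' @name GenotypePanel-accessors
#' @rdname GenotypePanel-accessors
#' @aliases nSites,GenotypePanel-method nSamples,GenotypePanel-method
#'   sampleNames,GenotypePanel-method sampleGroups,GenotypePanel-method
#'   siteRanges,GenotypePanel-method alleles,GenotypePanel-method
NULL

#' @rdname GenotypePanel-accessors
#' @export
setMethod("nSites", "GenotypePanel", function(x) nrow(x@a1))
#' @rdname GenotypePanel-accessors
#' @export
setMethod("nSamples", "GenotypePanel", function(x) ncol(x@a1))
#' @rdname GenotypePanel-accessors
#' @export
setMethod("sampleNames", "GenotypePanel", function(x) colnames(x@a1))
#' @rdname GenotypePanel-accessors
#' @export
setMethod("sampleGroups", "GenotypePanel", function(x)
    stats::setNames(x@groups, colnames(x@a1)))
#' @rdname GenotypePanel-accessors
#' @export
setMethod("siteRanges", "GenotypePanel", function(x) x@sites)
#' @rdname GenotypePanel-accessors
#' @export
setMethod("alleles", "GenotypePanel", function(x) list(a1 = x@a1, a2 = x@a2))

setMethod("show", "GenotypePanel", function(object) {
    cat("GenotypePanel:", nSites(object), "sites x", nSamples(object),
        "samples\n")
    print(table(groups = object@groups))
    miss <- mean(is.na(object@a1))
    cat(sprintf("missing genotypes: %.2f%%; chromosomes: %s\n",
        100 * miss, paste(seqlevels(object@sites), collapse = ", ")))
})

## Subset sites (i) and/or samples (j); used by the site filters.
setMethod("[", "GenotypePanel", function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nSites(x))
    if (missing(j)) j <- seq_len(nSamples(x))
    GenotypePanel(x@a1[i, j, drop = FALSE], x@a2[i, j, drop = FALSE],
                  x@sites[i], as.character(x@groups[j]))
})

#' Combine two panels over identical sites (column bind of samples)
#'
#' @param x,y `GenotypePanel` objects over the same site table.
#' @return A combined `GenotypePanel`.
#' @export
combinePanels <- function(x, y) {
    stopifnot(identical(as.character(seqnames(x@sites)),
                        as.character(seqnames(y@sites))),
              identical(GenomicRanges::start(x@sites),
                        GenomicRanges::start(y@sites)))
    GenotypePanel(cbind(x@a1, y@a1), cbind(x@a2, y@a2), x@sites,
                  c(as.character(x@groups), as.character(y@groups)))
}

## ---------------------------------------------------------------------------
## GeneModelSet: gene spans plus exon sub-intervals (simplified annotation).
## ---------------------------------------------------------------------------

#' GeneModelSet: gene spans with exon sub-intervals
#'
#' A lightweight stand-in for transcript-level annotation: each gene is a
#' span on a chromosome plus a set of exon intervals within the span. Used
#' for the exonic/intronic/intergenic site classifier and for mapping
#' selected windows to genes.
#'
#' @slot spans `GRanges`, one per gene, named by gene id (1-based inclusive).
#' @slot exons `GRangesList` parallel to `spans`, exons of each gene.
#' @export
setClass("GeneModelSet", slots = c(spans = "GRanges", exons = "GRangesList"))

setValidity("GeneModelSet", function(object) {
    msg <- character()
    if (is.null(names(object@spans)))
        msg <- c(msg, "gene spans must be named by gene id")
    if (!identical(names(object@spans), names(object@exons)))
        msg <- c(msg, "spans and exons must share gene ids in order")
    within <- all(unlist(GenomicRanges::start(object@exons)) >=
                      rep(GenomicRanges::start(object@spans),
                          lengths(object@exons))) &&
        all(unlist(GenomicRanges::end(object@exons)) <=
                rep(GenomicRanges::end(object@spans), lengths(object@exons)))
    if (length(object@spans) && !within)
        msg <- c(msg, "exons must lie within their gene span")
    if (length(msg)) msg else TRUE
})

#' Construct a GeneModelSet
#'
#' @param spans `GRanges` of gene spans, named by gene id.
#' @param exons `GRangesList` of exon intervals, same names/order as `spans`;
#'   if omitted, each gene gets a single exon equal to its span.
#' @return A `GeneModelSet`.
#' @export
GeneModelSet <- function(spans, exons = NULL) {
    if (is.null(exons)) {
        exons <- GenomicRanges::split(spans, factor(names(spans),
                                                    levels = names(spans)))
    }
    new("GeneModelSet", spans = spans, exons = exons)
}

#' @rdname GeneModelSet-accessors
#' @export
setGeneric("geneSpans", function(x) standardGeneric("geneSpans"))
#' @rdname GeneModelSet-accessors
#' @export
setGeneric("geneExons", function(x) standardGeneric("geneExons"))
#' @rdname GeneModelSet-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Accessors for GeneModelSet
#' @param x A `GeneModelSet`.
#' @name GeneModelSet-accessors
#' @rdname GeneModelSet-accessors
NULL

#' @rdname GeneModelSet-accessors
#' @export
setMethod("geneSpans", "GeneModelSet", function(x) x@spans)
#' @rdname GeneModelSet-accessors
#' @export
setMethod("geneExons", "GeneModelSet", function(x) x@exons)
#' @rdname GeneModelSet-accessors
#' @export
setMethod("geneIds", "GeneModelSet", function(x) names(x@spans))

setMethod("show", "GeneModelSet", function(object) {
    cat("GeneModelSet:", length(object@spans), "genes,",
        sum(lengths(object@exons)), "exons\n")
})

## ---------------------------------------------------------------------------
## XpclrParams: tuning of the composite likelihood sweep model.
## ---------------------------------------------------------------------------

#' Parameters of the XP-CLR style composite likelihood scan
#'
#' @slot omega numeric, drift variance scale of the neutral model: the latent
#'   object-population frequency is Normal(p1, omega * p1 * (1 - p1)),
#'   truncated to (0, 1) with the out-of-range mass placed at the boundaries.
#' @slot theta_grid numeric, ascending grid of sweep length scales in bp over
#'   which the selected model is maximised; must include a near-neutral
#'   (small) value so the neutral model is nested and scores are >= 0.
#' @slot freq_grid_size integer, number of grid cells for the frequency
#'   integration.
#' @slot min_snps integer, windows with fewer informative SNPs are masked.
#' @export
setClass("XpclrParams",
    slots = c(omega = "numeric", theta_grid = "numeric",
              freq_grid_size = "integer", min_snps = "integer"))

setValidity("XpclrParams", function(object) {
    msg <- character()
    if (object@omega <= 0 || object@omega >= 10)
        msg <- c(msg, "omega must lie in (0, 10)")
    if (is.unsorted(object@theta_grid, strictly = TRUE))
        msg <- c(msg, "theta_grid must be strictly ascending")
    if (min(object@theta_grid) > 1e3)
        msg <- c(msg, "theta_grid must include a near-neutral value (<= 1e3)")
    if (object@freq_grid_size < 10L)
        msg <- c(msg, "freq_grid_size too small")
    if (object@min_snps < 1L)
        msg <- c(msg, "min_snps must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct XpclrParams
#'
#' Defaults: 15 log-spaced sweep scales spanning 1e2 to 1e7 bp, a 200-point
#' frequency grid, and a minimum of 10 SNPs per scored window. `omega` above
#' the admissible range (as can happen for strongly bottlenecked panels when
#' estimated from mean Fst) is capped at 9.99.
#'
#' @param omega drift variance scale, in (0, 10).
#' @param theta_grid ascending sweep-scale grid (bp).
#' @param freq_grid_size frequency integration grid size.
#' @param min_snps minimum SNPs per window.
#' @return An `XpclrParams` object.
#' @export
XpclrParams <- function(omega = 0.5,
                        theta_grid = 10^seq(2, 7, length.out = 15),
                        freq_grid_size = 200L, min_snps = 10L) {
    new("XpclrParams", omega = min(as.numeric(omega), 9.99),
        theta_grid = as.numeric(theta_grid),
        freq_grid_size = as.integer(freq_grid_size),
        min_snps = as.integer(min_snps))
}

setMethod("show", "XpclrParams", function(object) {
    cat(sprintf(
        "XpclrParams: omega=%.3g, %d theta values in [%.3g, %.3g] bp, %d-point grid, min_snps=%d\n",
        object@omega, length(object@theta_grid), min(object@theta_grid),
        max(object@theta_grid), object@freq_grid_size, object@min_snps))
})
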