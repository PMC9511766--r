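## Genotype and gene-interval IO plus the site filters of the scan.
##
## Coordinate conventions: VCF positions are 1-based at the file boundary;
## BED is 0-based half-open; GRanges (1-based inclusive) is the in-memory
## representation everywhere.

#' Read a GT-only VCF into a GenotypePanel
#'
#' Parsing is done by [VariantAnnotation::readVcf()]; phased (`0|1`) and
#' unphased (`0/1`) genotypes are treated identically, `./.` is preserved as
#' missing, and multi-allelic sites are retained with all ALT alleles.
#'
#' @param path path to an (uncompressed or bgzipped) VCF file.
#' @param group_map named character vector mapping every sample in the file
#'   to a group label (e.g. `"wild"`, `"classical_inbred"`).
#' @return A [GenotypePanel()].
#' @export
readGenotypeVcf <- function(path, group_map) {
    vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
    gt <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gt)) stopf("VCF %s has no GT field", path)
    samples <- colnames(gt)
    if (!all(samples %in% names(group_map)))
        stopf("samples missing from group_map: %s",
              paste(setdiff(samples, names(group_map)), collapse = ", "))
    rr <- SummarizedExperiment::rowRanges(vcf)
    sites <- GRanges(seqnames(rr), IRanges::ranges(rr))
    mcols(sites)$ref <- as.character(rr$REF)
    mcols(sites)$alt <- methods::as(rr$ALT, "CharacterList")
    ## GT strings -> two allele-index matrices; "." becomes NA
    gtv <- sub(":.*", "", as.vector(gt))
    parts <- strsplit(gtv, "[/|]", perl = FALSE)
    bad <- lengths(parts) != 2L
    if (any(bad))
        stopf("malformed GT at record %d of %s",
              ((which(bad)[1] - 1) %% nrow(gt)) + 1, path)
    m <- matrix(unlist(parts), nrow = 2L)
    toIdx <- function(x) {
        x[x == "."] <- NA_character_
        matrix(as.integer(x), nrow(gt), ncol(gt))
    }
    a1 <- toIdx(m[1, ])
    a2 <- toIdx(m[2, ])
    half <- is.na(a1) != is.na(a2)
    if (any(half)) { a1[half] <- NA_integer_; a2[half] <- NA_integer_ }
    colnames(a1) <- colnames(a2) <- samples
    ord <- GenomicRanges::order(sites)
    GenotypePanel(a1[ord, , drop = FALSE], a2[ord, , drop = FALSE],
                  sites[ord], group_map[samples])
}

#' Write a GenotypePanel as VCF 4.2 (GT only)
#'
#' @param panel A [GenotypePanel()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeGenotypeVcf <- function(panel, path) {
    sites <- siteRanges(panel)
    lens <- seqlengths(sites)
    contigs <- if (all(is.na(lens))) {
        sprintf("##contig=<ID=%s>", seqlevels(sites))
    } else {
        sprintf("##contig=<ID=%s,length=%d>", seqlevels(sites), lens)
    }
    header <- c("##fileformat=VCFv4.2", contigs,
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", sampleNames(panel)), collapse = "\t"))
    al <- alleles(panel)
    fmt <- function(a) ifelse(is.na(a), ".", as.character(a))
    gt <- matrix(paste(fmt(al$a1), fmt(al$a2), sep = "/"),
                 nSites(panel), nSamples(panel))
    alt <- vapply(mcols(sites)$alt, paste, "", collapse = ",")
    body <- paste(as.character(seqnames(sites)),
                  GenomicRanges::start(sites),
                  sprintf("site_%06d", seq_len(nSites(panel))),
                  mcols(sites)$ref, alt, ".", "PASS", ".", "GT",
                  apply(gt, 1L, paste, collapse = "\t"),
                  sep = "\t")
    writeLines(c(header, body), path)
    invisible(path)
}

#' Write gene models as BED12
#'
#' 0-based half-open intervals; exons become the block fields.
#'
#' @param genes A [GeneModelSet()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeGeneModelsBed <- function(genes, path) {
    spans <- geneSpans(genes)
    exons <- geneExons(genes)
    start0 <- GenomicRanges::start(spans) - 1L
    end0 <- GenomicRanges::end(spans)
    lines <- vapply(seq_along(spans), function(i) {
        ex <- exons[[i]]
        ex <- GenomicRanges::sort(ex)
        sizes <- GenomicRanges::width(ex)
        offs <- GenomicRanges::start(ex) - 1L - start0[i]
        paste(as.character(seqnames(spans))[i], start0[i], end0[i],
              names(spans)[i], 0, "+", start0[i], end0[i], "0",
              length(ex), paste0(paste(sizes, collapse = ","), ","),
              paste0(paste(offs, collapse = ","), ","),
              sep = "\t")
    }, "")
    writeLines(lines, path)
    invisible(path)
}

#' Read gene models from BED (BED12 exon blocks honoured)
#'
#' Uses [rtracklayer::import()]; when block fields are present they become
#' the exon intervals, otherwise each gene is a single exon spanning it.
#'
#' @param path path to a BED file with gene names in column 4.
#' @return A [GeneModelSet()].
#' @export
readGeneModelsBed <- function(path) {
    bed <- rtracklayer::import(path, format = "bed")
    if (is.null(bed$name) || anyNA(bed$name))
        stopf("BED %s must carry gene ids in the name column", path)
    spans <- GRanges(seqnames(bed), IRanges::ranges(bed))
    names(spans) <- bed$name
    if (!is.null(bed$blocks)) {
        exons <- GRangesList(lapply(seq_along(bed), function(i) {
            GenomicRanges::shift(GRanges(seqnames(bed)[i], bed$blocks[[i]]),
                                 GenomicRanges::start(bed)[i] - 1L)
        }))
        names(exons) <- bed$name
        GeneModelSet(spans, exons)
    } else {
        GeneModelSet(spans)
    }
}

#' Apply the scan's site filters
#'
#' Retains sites that are bi-allelic SNPs (exactly one ALT, REF and ALT of
#' length 1, when `biallelic_only`) with missing-genotype fraction strictly
#' below `max_missing` computed over the merged sample set.
#'
#' @param panel A [GenotypePanel()].
#' @param biallelic_only drop multi-allelic and non-SNP sites.
#' @param max_missing exclusive missingness threshold (default 0.1, i.e.
#'   a site missing in exactly 10% of samples is removed).
#' @return The filtered [GenotypePanel()].
#' @export
filterSites <- function(panel, biallelic_only = TRUE, max_missing = 0.1) {
    sites <- siteRanges(panel)
    keep <- rep(TRUE, nSites(panel))
    if (biallelic_only) {
        alt <- mcols(sites)$alt
        keep <- lengths(alt) == 1L &
            nchar(mcols(sites)$ref) == 1L &
            vapply(alt, function(a) all(nchar(a) == 1L), TRUE)
    }
    miss_frac <- rowMeans(is.na(panel@a1))
    keep <- keep & miss_frac < max_missing
    panel[which(keep), ]
}

#' Per-site allele counts and frequencies within a group
#'
#' Counts are over called alleles only; frequencies renormalise over the
#' called alleles and sum to 1 at every site with at least one call. Sites
#' with zero called alleles in the group are flagged undefined.
#'
#' @param panel A [GenotypePanel()].
#' @param group a group label present in `sampleGroups(panel)`.
#' @return A list: `counts` (sites x alleles matrix, column `k` = allele
#'   index `k - 1`), `n_called` (called alleles per site), `freq_ref`,
#'   `freq_alt` (frequency of allele 1, for bi-allelic use), `undefined`
#'   (logical flag per site).
#' @export
groupAlleleCounts <- function(panel, group) {
    if (!group %in% levels(sampleGroups(panel)))
        stopf("no such group: %s", group)
    j <- which(sampleGroups(panel) == group)
    a1 <- panel@a1[, j, drop = FALSE]
    a2 <- panel@a2[, j, drop = FALSE]
    max_allele <- max(1L, suppressWarnings(max(c(a1, a2), na.rm = TRUE)))
    counts <- vapply(0:max_allele, function(k)
        rowSums(a1 == k, na.rm = TRUE) + rowSums(a2 == k, na.rm = TRUE),
        numeric(nrow(a1)))
    counts <- matrix(counts, nrow = nrow(a1),
                     dimnames = list(NULL, paste0("allele", 0:max_allele)))
    n_called <- as.vector(rowSums(counts))
    undefined <- n_called == 0
    freq <- counts / ifelse(n_called == 0, NA_real_, n_called)
    list(counts = counts, n_called = n_called,
         freq_ref = as.vector(freq[, 1L]),
         freq_alt = if (ncol(freq) >= 2L) as.vector(freq[, 2L])
                    else rep(0, nrow(a1)),
         freq = freq, undefined = undefined)
}

#' Classify sites as exonic, intronic or intergenic
#'
#' Precedence is exonic > intronic > intergenic: a site inside any exon of
#' any gene is exonic; inside a gene span but no exon, intronic; otherwise
#' intergenic. Sites on chromosomes absent from the annotation are
#' intergenic with a warning.
#'
#' @param sites a `GRanges` of sites (e.g. `siteRanges(panel)`).
#' @param genes a [GeneModelSet()].
#' @return A list: `class` (factor per site) and `tally` (named counts).
#' @export
classifySites <- function(sites, genes) {
    spans <- geneSpans(genes)
    exons <- unlist(geneExons(genes))
    unknown <- !(as.character(seqnames(sites)) %in%
                     as.character(unique(seqnames(spans))))
    if (any(unknown))
        warnf("%d site(s) on chromosomes absent from the gene annotation; classified intergenic",
              sum(unknown))
    cls <- rep("intergenic", length(sites))
    suppressWarnings({
        cls[IRanges::overlapsAny(sites, spans)] <- "intronic"
        cls[IRanges::overlapsAny(sites, exons)] <- "exonic"
    })
    cls <- factor(cls, levels = c("exonic", "intronic", "intergenic"))
    list(class = cls, tally = table(cls))
}
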