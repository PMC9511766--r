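## Candidate-SNP selection rules for mouse-model construction: the strict
## homozygosity rule, the relaxed 20%-frequency rule, and allelicity
## classification.

#' Strict candidate rule: reference homozygosity split
#'
#' A site passes when reference-allele homozygosity occurs in no wild
#' sample but in every classical-inbred sample. Any missing genotype in
#' either group makes the site ineligible (conservative, reproducible).
#'
#' @param panel A [GenotypePanel()].
#' @param site_idx site indices (default: all sites).
#' @param wild_group,inbred_group group labels.
#' @return A list: `pass` (logical per site) and `reason` (character:
#'   `"pass"`, `"missing"`, `"wild_homref"`, `"inbred_not_homref"`).
#' @export
strictCandidateRule <- function(panel, site_idx = seq_len(nSites(panel)),
                                wild_group = "wild",
                                inbred_group = "classical_inbred") {
    jw <- which(sampleGroups(panel) == wild_group)
    ji <- which(sampleGroups(panel) == inbred_group)
    a1 <- panel@a1[site_idx, , drop = FALSE]
    a2 <- panel@a2[site_idx, , drop = FALSE]
    homref <- a1 == 0L & a2 == 0L
    miss <- rowSums(is.na(a1[, c(jw, ji), drop = FALSE])) > 0
    wild_homref <- rowSums(homref[, jw, drop = FALSE], na.rm = TRUE) > 0
    inbred_all <- rowSums(homref[, ji, drop = FALSE], na.rm = TRUE) ==
        length(ji)
    pass <- !miss & !wild_homref & inbred_all
    reason <- rep("pass", length(site_idx))
    reason[!inbred_all] <- "inbred_not_homref"
    reason[wild_homref] <- "wild_homref"
    reason[miss] <- "missing"
    list(pass = pass, reason = reason)
}

#' Relaxed candidate rule: wild reference frequency below a fraction of
#' the inbred reference frequency
#'
#' Passes when `f_ref_wild < factor * f_ref_inbred` (strict); an inbred
#' reference frequency of 0 always fails.
#'
#' @param f_ref_wild,f_ref_inbred reference-allele frequencies in `[0, 1]`.
#' @param factor the frequency fraction (default 0.2, i.e. "less than 20%
#'   of the frequency in classical inbred mice").
#' @return Logical vector.
#' @examples
#' relaxedCandidateRule(0.0417, 0.793)  # TRUE
#' relaxedCandidateRule(0.2, 1.0)       # FALSE (strict boundary)
#' @export
relaxedCandidateRule <- function(f_ref_wild, f_ref_inbred, factor = 0.2) {
    bad <- !is.na(f_ref_wild) & (f_ref_wild < 0 | f_ref_wild > 1) |
        !is.na(f_ref_inbred) & (f_ref_inbred < 0 | f_ref_inbred > 1)
    if (any(bad)) stopf("frequencies must lie in [0, 1]")
    f_ref_inbred > 0 & f_ref_wild < factor * f_ref_inbred
}

#' Allelicity of sites within a group
#'
#' Number of distinct alleles among the called genotypes of the group:
#' 1 = single, 2 = bi, >= 3 = tri.
#'
#' @param panel A [GenotypePanel()].
#' @param group group label.
#' @param site_idx site indices (default: all sites).
#' @return Factor with levels `single`, `bi`, `tri` (`NA` where the group
#'   has no called genotype).
#' @export
siteAllelicity <- function(panel, group,
                           site_idx = seq_len(nSites(panel))) {
    counts <- groupAlleleCounts(panel[site_idx, ], group)
    n_alleles <- rowSums(counts$counts > 0)
    cls <- cut(n_alleles, breaks = c(-Inf, 0.5, 1.5, 2.5, Inf),
               labels = c(NA, "single", "bi", "tri"))
    cls[counts$undefined] <- NA
    factor(as.character(cls), levels = c("single", "bi", "tri"))
}

#' Evaluate candidate rules over all sites of a gene
#'
#' @param panel A [GenotypePanel()].
#' @param gene_span a `GRanges` of length 1 (the gene span), or a
#'   [GeneModelSet()] plus `gene_id`.
#' @param gene_id gene id when `gene_span` is a `GeneModelSet`.
#' @param factor relaxed-rule factor.
#' @param wild_group,inbred_group group labels.
#' @return data.frame (one row per site in the span): chrom, pos, ref,
#'   f_ref_wild, f_ref_inbred, strict_pass, strict_reason, relaxed_pass,
#'   allelicity_wild, allelicity_inbred. Summary counts are attached as
#'   attribute `"summary"`.
#' @export
scanGeneCandidates <- function(panel, gene_span, gene_id = NULL,
                               factor = 0.2, wild_group = "wild",
                               inbred_group = "classical_inbred") {
    if (is(gene_span, "GeneModelSet")) {
        stopifnot(!is.null(gene_id))
        gene_span <- geneSpans(gene_span)[gene_id]
    }
    stopifnot(is(gene_span, "GRanges"), length(gene_span) == 1L)
    idx <- which(IRanges::overlapsAny(siteRanges(panel), gene_span))
    if (!length(idx)) {
        warnf("gene span %s:%d-%d contains no sites",
              as.character(seqnames(gene_span)),
              GenomicRanges::start(gene_span),
              GenomicRanges::end(gene_span))
        return(structure(data.frame(), summary = list(n_sites = 0L)))
    }
    sub <- panel[idx, ]
    cw <- groupAlleleCounts(sub, wild_group)
    ci <- groupAlleleCounts(sub, inbred_group)
    strict <- strictCandidateRule(panel, idx, wild_group, inbred_group)
    relaxed <- relaxedCandidateRule(cw$freq_ref, ci$freq_ref, factor)
    relaxed[is.na(relaxed)] <- FALSE
    tab <- data.frame(
        chrom = as.character(seqnames(siteRanges(sub))),
        pos = GenomicRanges::start(siteRanges(sub)),
        ref = mcols(siteRanges(sub))$ref,
        f_ref_wild = cw$freq_ref,
        f_ref_inbred = ci$freq_ref,
        strict_pass = strict$pass,
        strict_reason = strict$reason,
        relaxed_pass = relaxed,
        allelicity_wild = siteAllelicity(panel, wild_group, idx),
        allelicity_inbred = siteAllelicity(panel, inbred_group, idx))
    attr(tab, "summary") <- list(
        n_sites = nrow(tab),
        n_strict = sum(tab$strict_pass),
        n_relaxed = sum(tab$relaxed_pass),
        allelicity_wild = table(tab$allelicity_wild),
        allelicity_inbred = table(tab$allelicity_inbred))
    tab
}
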