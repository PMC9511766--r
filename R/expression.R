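## Expression-enrichment arithmetic: tissue-category merging, the 2-fold
## "highly expressed" rule, the brain-vs-other rank-sum test, phenotype
## fold enrichment, and DE-ratio elevation among PSGs.

#' Merge tissue columns into category means
#'
#' Each category's value per gene is the arithmetic mean of its member
#' tissues' RPKM. The default mapping ([defaultTissueCategories()])
#' reproduces the 17 standard categories (immature brain, brain, immature
#' liver, bowel, immune system, fat, plus singleton organs).
#'
#' @param rpkm numeric matrix, genes x tissues (non-negative RPKM).
#' @param mapping named character vector mapping every tissue column to a
#'   category; defaults to [defaultTissueCategories()] of the column names.
#' @return Numeric matrix, genes x categories (category order = first
#'   appearance in the tissue columns).
#' @export
mergeTissueCategories <- function(rpkm,
                                  mapping = defaultTissueCategories(
                                      colnames(rpkm))) {
    tissues <- colnames(rpkm)
    if (!all(tissues %in% names(mapping)))
        stopf("unmapped tissue column(s): %s",
              paste(setdiff(tissues, names(mapping)), collapse = ", "))
    cats <- unique(unname(mapping[tissues]))
    out <- vapply(cats, function(cat) {
        cols <- tissues[mapping[tissues] == cat]
        rowMeans(rpkm[, cols, drop = FALSE])
    }, numeric(nrow(rpkm)))
    out <- matrix(out, nrow = nrow(rpkm),
                  dimnames = list(rownames(rpkm), cats))
    out
}

#' Flag highly expressed genes per category
#'
#' A gene is highly expressed in a category when its value there is at
#' least 2-fold its own mean over all categories (inclusive threshold).
#' All-zero genes get no flags.
#'
#' @param merged genes x categories matrix from [mergeTissueCategories()].
#' @return Logical matrix of the same shape.
#' @export
flagHighlyExpressed <- function(merged) {
    m <- rowMeans(merged)
    flags <- merged >= 2 * m
    flags[m == 0, ] <- FALSE
    flags
}

#' Fraction of a gene set flagged per category
#'
#' @param flags logical matrix from [flagHighlyExpressed()].
#' @param gene_set character vector of gene ids (subset of the rows).
#' @return data.frame with columns `category`, `count`, `percent`
#'   (percent of `gene_set` flagged, rounded half-up to one decimal).
#' @export
categoryRatio <- function(flags, gene_set) {
    if (!length(gene_set)) stopf("empty gene set")
    if (!all(gene_set %in% rownames(flags)))
        stopf("gene set contains genes absent from the flag matrix")
    counts <- colSums(flags[gene_set, , drop = FALSE])
    data.frame(category = colnames(flags), count = as.integer(counts),
               percent = roundHalfUp1(100 * counts / length(gene_set)),
               row.names = NULL)
}

#' One-sided rank-sum test: brain columns vs the rest
#'
#' Mann-Whitney U (number of brain > other pairs, ties counted half) with
#' the tie-corrected normal approximation, one-sided alternative "brain
#' greater". An all-tied input carries no evidence: p = 0.5, flagged.
#'
#' @param values numeric vector of a gene's expression across tissues.
#' @param brain_idx indices (or logical mask) of the brain-group entries.
#' @return A list: `U`, `p`, `all_tied`.
#' @export
rankSumBrainVsOther <- function(values, brain_idx) {
    mask <- logical(length(values))
    mask[brain_idx] <- TRUE
    x <- values[mask]
    y <- values[!mask]
    if (length(x) < 2 || length(y) < 2)
        stopf("need at least 2 values per side")
    U <- sum(rank(c(x, y))[seq_along(x)]) - length(x) * (length(x) + 1) / 2
    if (length(unique(c(x, y))) == 1L)
        return(list(U = U, p = 0.5, all_tied = TRUE))
    p <- suppressWarnings(stats::wilcox.test(x, y, alternative = "greater",
                                             exact = FALSE,
                                             correct = FALSE)$p.value)
    list(U = U, p = p, all_tied = FALSE)
}

#' Phenotype enrichment: percent and fold over a database baseline
#'
#' @param k genes of the study set with the phenotype.
#' @param m genes of the study set present in the database.
#' @param K,M phenotype-positive and total genes of the database (a
#'   baseline fraction can be passed as `K` with `M = 1`).
#' @return A list: `percent` (= 100 k/m) and `fold` (= (k/m)/(K/M)), both
#'   rounded half-up to one decimal.
#' @examples
#' phenotypeFold(125, 245, 0.301, 1)  # 51.0 percent, 1.7-fold
#' @export
phenotypeFold <- function(k, m, K, M) {
    if (m == 0) stopf("m must be positive")
    stopifnot(k >= 0, k <= m, K > 0, K <= M)
    list(percent = roundHalfUp1(100 * k / m),
         fold = roundHalfUp1((k / m) / (K / M)))
}

deFlag <- function(tab) tab$padj < 0.05 & tab$fpkm > 1

#' DE-ratio elevation of a gene set, per tissue
#'
#' A gene is differentially expressed when `padj < 0.05` and `fpkm > 1`
#' (both strict). For every DE table the DE fraction among all genes and
#' among the PSG subset is compared.
#'
#' @param de_tables named list of data.frames with columns `gene`, `padj`,
#'   `fpkm` (one per tissue).
#' @param psg_set character vector of gene ids.
#' @return data.frame per tissue: `tissue`, `ratio_all`, `ratio_psg`,
#'   `delta_points` (percentage-point increase), `fold` (`NA` when no gene
#'   at all is DE).
#' @export
deRatioElevation <- function(de_tables, psg_set) {
    rows <- lapply(names(de_tables), function(tis) {
        tab <- de_tables[[tis]]
        in_psg <- tab$gene %in% psg_set
        if (!any(in_psg))
            stopf("no PSG present in the %s DE table", tis)
        de <- deFlag(tab)
        ratio_all <- mean(de)
        ratio_psg <- mean(de[in_psg])
        data.frame(tissue = tis, ratio_all = ratio_all,
                   ratio_psg = ratio_psg,
                   delta_points = 100 * (ratio_psg - ratio_all),
                   fold = if (ratio_all > 0) ratio_psg / ratio_all
                          else NA_real_)
    })
    do.call(rbind, rows)
}

#' Common differentially expressed genes of two tissues
#'
#' @param de_table_a,de_table_b DE data.frames (`gene`, `padj`, `fpkm`).
#' @return Sorted character vector of genes DE in both.
#' @export
commonDeGenes <- function(de_table_a, de_table_b) {
    sort(intersect(de_table_a$gene[deFlag(de_table_a)],
                   de_table_b$gene[deFlag(de_table_b)]))
}

#' Read a tissue-to-category mapping from YAML
#'
#' The file maps category names to member-tissue lists, e.g.
#' `brain: [cerebellum, cortex, frontal lobe]`; singleton tissues may be
#' given as scalar entries or omitted (then they map to themselves when
#' combined with [defaultTissueCategories()]).
#'
#' @param path YAML file path.
#' @return Named character vector (tissue -> category) as accepted by
#'   [mergeTissueCategories()].
#' @export
readCategoryMapping <- function(path) {
    y <- yaml::read_yaml(path)
    tissues <- unlist(y, use.names = FALSE)
    cats <- rep(names(y), lengths(y))
    stats::setNames(cats, tissues)
}
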