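## The top-level selection scan: windowed pi ratio, Fst and XP-CLR,
## top-fraction ranking, window-to-gene mapping, and the three-way PSG
## intersection.

#' Result of a selection scan
#'
#' @slot windows `GRanges` with per-window metadata columns `n_snps`,
#'   `pi_wild`, `pi_inbred`, `pi_ratio`, `fst`, `xpclr`, `trailing`,
#'   `masked`.
#' @slot topWindows list of integer index vectors (per statistic) into
#'   `windows`, in rank order.
#' @slot geneSets list of character vectors: genes overlapping the top
#'   windows of each statistic.
#' @slot psgs character, the sorted intersection of the three gene sets.
#' @slot venn list of Venn counts (set sizes, pairwise, triple).
#' @slot omega numeric, the drift scale used by the XP-CLR model.
#' @export
setClass("ScanResult", slots = c(
    windows = "GRanges", topWindows = "list", geneSets = "list",
    psgs = "character", venn = "list", omega = "numeric"))

setMethod("show", "ScanResult", function(object) {
    n_masked <- sum(mcols(object@windows)$masked)
    cat("ScanResult:", length(object@windows), "windows (",
        n_masked, "masked );", length(object@psgs), "PSGs\n")
    sizes <- vapply(object@geneSets, length, 0L)
    cat("top-window gene sets:",
        paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "), "\n")
})

#' @describeIn ScanResult-class the per-window statistics as a data.frame
#'   (0-based half-open `start`/`end`, TSV-report layout).
#' @param x,row.names,optional,... standard [base::as.data.frame()] arguments.
#' @export
setMethod("as.data.frame", "ScanResult",
    function(x, row.names = NULL, optional = FALSE, ...) {
        w <- x@windows
        data.frame(chrom = as.character(seqnames(w)),
                   start = GenomicRanges::start(w) - 1L,
                   end = GenomicRanges::end(w),
                   as.data.frame(mcols(w)),
                   row.names = row.names)
    })

#' Select the top-ranked windows of a statistic
#'
#' Picks `ceiling(fraction * n_unmasked)` windows in descending order of
#' the statistic. `NA` entries are masked and excluded from both ranking
#' and the count; `+Inf` sentinels rank first. Ties are broken
#' deterministically by (statistic, chrom, start).
#'
#' @param stat numeric per-window statistic (`NA` = masked).
#' @param windows the `GRanges` the statistic is aligned to.
#' @param fraction top fraction to select (default 0.05).
#' @return Integer indices of the selected windows, in rank order.
#' @export
selectTopWindows <- function(stat, windows, fraction = 0.05) {
    unmasked <- which(!is.na(stat))
    if (!length(unmasked)) {
        warnf("all windows masked; empty selection")
        return(integer())
    }
    count <- ceiling(fraction * length(unmasked))
    ord <- unmasked[order(-stat[unmasked],
                          as.integer(seqnames(windows))[unmasked],
                          GenomicRanges::start(windows)[unmasked])]
    ord[seq_len(min(count, length(ord)))]
}

#' Map selected windows to genes
#'
#' A gene is included iff its span overlaps any selected window by at
#' least 1 bp.
#'
#' @param windows `GRanges` of the selected windows.
#' @param genes A [GeneModelSet()].
#' @return Character vector of gene ids (annotation order).
#' @export
windowsToGenes <- function(windows, genes) {
    spans <- geneSpans(genes)
    geneIds(genes)[IRanges::overlapsAny(spans, windows)]
}

#' Intersect the three top-5% gene sets into PSGs
#'
#' @param genes_pi,genes_fst,genes_xpclr character vectors of gene ids from
#'   the pi-ratio, Fst and XP-CLR top windows.
#' @return A list: `psgs` (sorted intersection), `venn` (set sizes,
#'   pairwise overlaps and the triple overlap).
#' @export
intersectPsgs <- function(genes_pi, genes_fst, genes_xpclr) {
    psgs <- sort(intersect(intersect(genes_pi, genes_fst), genes_xpclr))
    venn <- list(
        n_pi = length(unique(genes_pi)),
        n_fst = length(unique(genes_fst)),
        n_xpclr = length(unique(genes_xpclr)),
        n_pi_fst = length(intersect(genes_pi, genes_fst)),
        n_pi_xpclr = length(intersect(genes_pi, genes_xpclr)),
        n_fst_xpclr = length(intersect(genes_fst, genes_xpclr)),
        n_all = length(psgs))
    list(psgs = psgs, venn = venn)
}

#' Run the three-statistic selection scan
#'
#' Applies the site filters, computes windowed pi for both groups, the pi
#' ratio, mean per-window Akey Fst and the XP-CLR score, ranks each
#' statistic, maps top windows to genes and intersects the three gene sets
#' into positively selected genes (PSGs). Trailing (short) windows and
#' windows with fewer than `min_snps` SNPs are masked from ranking.
#'
#' @param panel A [GenotypePanel()] containing both groups.
#' @param genes A [GeneModelSet()].
#' @param wild_group,inbred_group the two group labels; the inbred group is
#'   the object of selection.
#' @param window_size,step window geometry in bp.
#' @param top_fraction fraction of unmasked windows selected per statistic.
#' @param min_snps minimum SNPs for a window to be ranked.
#' @param max_missing,biallelic_only site filters, see [filterSites()].
#' @param xpclr_params An [XpclrParams()], or `NULL` to calibrate omega
#'   from the genome-wide mean positive Fst via [estimateOmega()].
#' @return A [ScanResult-class] object.
#' @export
selectionScan <- function(panel, genes,
                          wild_group = "wild",
                          inbred_group = "classical_inbred",
                          window_size = 40000, step = 20000,
                          top_fraction = 0.05, min_snps = 10L,
                          max_missing = 0.1, biallelic_only = TRUE,
                          xpclr_params = NULL) {
    panel <- filterSites(panel, biallelic_only = biallelic_only,
                         max_missing = max_missing)
    sites <- siteRanges(panel)
    lens <- seqlengths(sites)
    if (anyNA(lens)) {
        lens <- vapply(split(GenomicRanges::start(sites), seqnames(sites)),
                       max, 0)
    }
    windows <- makeScanWindows(lens, size = window_size, step = step)
    cw <- groupAlleleCounts(panel, wild_group)
    ci <- groupAlleleCounts(panel, inbred_group)
    hw <- siteHeterozygosity(cw$counts)$h
    hi <- siteHeterozygosity(ci$counts)$h
    pi_w <- windowize(hw, sites, windows, "sum_per_bp")
    pi_i <- windowize(hi, sites, windows, "sum_per_bp")
    fst_site <- akeyFst(cw$n_called, cw$freq_alt, ci$n_called, ci$freq_alt)
    fst_win <- windowize(fst_site, sites, windows, "mean")
    if (is.null(xpclr_params))
        xpclr_params <- XpclrParams(omega = estimateOmega(fst_site),
                                    min_snps = min_snps)
    m1 <- cw$counts[, 2L]
    m2 <- ci$counts[, 2L]
    xp <- xpclrWindowScores(sites, m1, cw$n_called, m2, ci$n_called,
                            windows, xpclr_params)
    trailing <- mcols(windows)$trailing
    masked <- trailing | pi_w$n_snps < min_snps
    stat_pi <- piRatio(pi_w$value, pi_i$value)
    stat_pi[masked] <- NA_real_
    stat_fst <- fst_win$value
    stat_fst[trailing | fst_win$n_snps < min_snps] <- NA_real_
    stat_xp <- xp$score
    stat_xp[trailing] <- NA_real_
    mcols(windows)$n_snps <- pi_w$n_snps
    mcols(windows)$pi_wild <- pi_w$value
    mcols(windows)$pi_inbred <- pi_i$value
    mcols(windows)$pi_ratio <- stat_pi
    mcols(windows)$fst <- stat_fst
    mcols(windows)$xpclr <- stat_xp
    mcols(windows)$masked <- masked
    top <- list(pi_ratio = selectTopWindows(stat_pi, windows, top_fraction),
                fst = selectTopWindows(stat_fst, windows, top_fraction),
                xpclr = selectTopWindows(stat_xp, windows, top_fraction))
    gsets <- lapply(top, function(idx) windowsToGenes(windows[idx], genes))
    ip <- intersectPsgs(gsets$pi_ratio, gsets$fst, gsets$xpclr)
    new("ScanResult", windows = windows, topWindows = top,
        geneSets = gsets, psgs = ip$psgs, venn = ip$venn,
        omega = xpclr_params@omega)
}
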