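## Windowed selection statistics: sliding windows, per-site unbiased
## heterozygosity, window aggregation, the pi ratio, and the ANOVA-based
## Fst estimator of Akey et al.

#' Sliding genome windows
#'
#' Windows of `size` bp advancing by `step` bp, anchored at 0 on every
#' chromosome (0-based half-open internally; returned as 1-based GRanges).
#' Start positions continue while `start + step <= chrom_length`, so every
#' interior bp is covered by exactly `size/step` windows; windows truncated
#' at the chromosome end are flagged `trailing` (and masked from ranking by
#' default downstream).
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param size window size in bp (default 40000).
#' @param step step size in bp (default 20000); must not exceed `size`.
#' @return `GRanges` of windows with a logical metadata column `trailing`.
#' @examples
#' makeScanWindows(c(chr1 = 1e5))  # 5 windows, the last one trailing
#' @export
makeScanWindows <- function(chrom_lengths, size = 40000, step = 20000) {
    if (step > size)
        stopf("step (%g) must not exceed window size (%g)", step, size)
    if (is.null(names(chrom_lengths)))
        stopf("chrom_lengths must be named by chromosome")
    out <- lapply(names(chrom_lengths), function(chrom) {
        len <- chrom_lengths[[chrom]]
        starts0 <- seq(0, max(0, len - step), by = step)
        starts0 <- starts0[starts0 == 0 | starts0 + step <= len]
        ends0 <- pmin(starts0 + size, len)
        GRanges(chrom, IRanges(starts0 + 1, ends0),
                trailing = (ends0 - starts0) < size)
    })
    win <- suppressWarnings(do.call(c, out))
    seqlevels(win) <- names(chrom_lengths)
    seqlengths(win) <- unlist(chrom_lengths)
    win
}

#' Per-site unbiased expected heterozygosity
#'
#' `h = n/(n-1) * (1 - sum(p_a^2))` over the called alleles of a group;
#' equals the mean pairwise difference between haplotypes at the site.
#' Sites with fewer than 2 called alleles contribute 0 and are flagged.
#'
#' @param counts allele-count matrix (sites x alleles), e.g. the `counts`
#'   element of [groupAlleleCounts()].
#' @return A list: `h` (numeric per site) and `low_n` (flag: n_called < 2).
#' @export
siteHeterozygosity <- function(counts) {
    n <- rowSums(counts)
    low <- n < 2
    sump2 <- rowSums((counts / ifelse(n == 0, NA_real_, n))^2)
    h <- ifelse(low, 0, n / (n - 1) * (1 - sump2))
    h[is.na(h)] <- 0
    list(h = h, low_n = low)
}

#' Aggregate per-site values into windows
#'
#' `mode = "sum_per_bp"` divides the window sum by the window length in bp
#' (the pi convention); `mode = "mean"` averages over sites with a defined
#' value (the window Fst convention; empty windows yield `NA`). Sites are
#' assigned by half-open convention: a site on the window start is included,
#' one on the end excluded — with 1-based GRanges windows this is the plain
#' overlap. Sites with `NA` values are not counted.
#'
#' @param values numeric per-site values (may contain `NA`).
#' @param sites `GRanges` of the sites, parallel to `values`.
#' @param windows `GRanges` from [makeScanWindows()].
#' @param mode `"sum_per_bp"` or `"mean"`.
#' @return A list: `value` (per window), `n_snps` (sites with non-`NA`
#'   value per window).
#' @export
windowize <- function(values, sites, windows,
                      mode = c("sum_per_bp", "mean")) {
    mode <- match.arg(mode)
    stopifnot(length(values) == length(sites))
    ok <- !is.na(values)
    hits <- GenomicRanges::findOverlaps(sites[ok], windows)
    wi <- S4Vectors::subjectHits(hits)
    v <- values[ok][S4Vectors::queryHits(hits)]
    n_snps <- tabulate(wi, nbins = length(windows))
    sums <- rep(0, length(windows))
    agg <- tapply(v, wi, sum)
    sums[as.integer(names(agg))] <- agg
    value <- switch(mode,
        sum_per_bp = sums / GenomicRanges::width(windows),
        mean = ifelse(n_snps > 0, sums / n_snps, NA_real_))
    list(value = value, n_snps = n_snps)
}

#' Window pi ratio with fixation handling
#'
#' `pi_wild / pi_inbred`; a window where the inbred panel retains no
#' diversity (`pi_inbred = 0`) but the wild group does is the strongest
#' possible signal and gets `+Inf`, ranking above every finite value. Both
#' zero yields `NA` (the window is masked for this statistic).
#'
#' @param pi_wild,pi_inbred non-negative per-window diversities.
#' @return Numeric vector of ratios (`Inf` / `NA` as described).
#' @export
piRatio <- function(pi_wild, pi_inbred) {
    if (any(pi_wild < 0, na.rm = TRUE) || any(pi_inbred < 0, na.rm = TRUE))
        stopf("negative diversity input")
    ifelse(pi_inbred > 0, pi_wild / pi_inbred,
           ifelse(pi_wild > 0, Inf, NA_real_))
}

#' Per-site Fst (Akey et al. ANOVA estimator)
#'
#' Two-population ANOVA estimator on allele counts: with `k = 2`
#' populations, `p_bar = (n1 p1 + n2 p2) / (n1 + n2)`,
#' `MSP = sum n_i (p_i - p_bar)^2 / (k - 1)`,
#' `MSG = sum n_i p_i (1 - p_i) / sum (n_i - 1)`,
#' `n_c = (sum n_i - sum n_i^2 / sum n_i) / (k - 1)`, and
#' `Fst = (MSP - MSG) / (MSP + (n_c - 1) MSG)`. The raw value is returned
#' and may be negative; sites monomorphic in both groups (`MSP = MSG = 0`)
#' are undefined (`NA`).
#'
#' @param n1,n2 called allele counts (chromosomes) per group; vectors.
#' @param p1,p2 allele frequencies per group (same allele in both).
#' @return Numeric vector of per-site Fst values.
#' @examples
#' akeyFst(10, 1, 10, 0)        # fixed difference: 1
#' akeyFst(10, 0.8, 10, 0.3)    # ~0.337
#' @export
akeyFst <- function(n1, p1, n2, p2) {
    ntot <- n1 + n2
    pbar <- (n1 * p1 + n2 * p2) / ntot
    msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2
    msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (ntot - 2)
    nc <- ntot - (n1^2 + n2^2) / ntot
    fst <- (msp - msg) / (msp + (nc - 1) * msg)
    fst[msp == 0 & msg == 0] <- NA_real_
    fst[n1 < 2 | n2 < 2] <- NA_real_
    fst
}

#' Calibrate the drift variance scale from genome-wide Fst
#'
#' `omega = Fbar / (1 - Fbar)` where `Fbar` is the mean of the positive
#' per-site Fst values, clamped to `[1e-3, 0.99]` before the transform.
#'
#' @param site_fst numeric per-site Fst values (`NA` allowed).
#' @return The drift scale omega.
#' @export
estimateOmega <- function(site_fst) {
    f <- site_fst[!is.na(site_fst) & site_fst > 0]
    if (length(site_fst[!is.na(site_fst)]) < 100)
        stopf("need >= 100 informative sites to calibrate omega (got %d)",
              sum(!is.na(site_fst)))
    fbar <- min(max(mean(f), 1e-3), 0.99)
    fbar / (1 - fbar)
}
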