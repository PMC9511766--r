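## Cross-population composite likelihood (XP-CLR style) sweep scan.
##
## Simplified variant of the Chen et al. composite likelihood: the sweep
## position is fixed at the window center, there is no LD-based SNP
## down-weighting, the frequency integration runs on a fixed grid, and the
## sweep scale is maximised over a log-spaced theta grid. Scores are
## comparable within a run, not to the original C implementation.
##
## Model per site (wild = reference population, classical inbred = object
## population, since selection acted on the inbred lineage):
##   neutral:  latent object frequency q ~ Normal(p1, omega p1 (1 - p1)),
##             truncated to (0,1) with out-of-range mass as point masses at
##             0 and 1; L0 = E_q[ Binom(m2 | n2, q) ].
##   selected: with escape probability c = 1 - exp(-d / theta) the site
##             escapes the sweep (neutral start p1); otherwise it hitchhikes
##             to fixation: mass p1 at 1, mass (1 - p1) at 0. Drift from a
##             boundary is degenerate, so
##             L1 = c L0 + (1 - c) (p1 [m2 = n2] + (1 - p1) [m2 = 0]).

## Per-site quantities that do not depend on theta or distance.
xpclrSiteCore <- function(m1, n1, m2, n2, omega, grid_size) {
    p1 <- pmin(pmax(m1 / n1, 1 / (2 * n1)), 1 - 1 / (2 * n1))
    sigma <- sqrt(omega * p1 * (1 - p1))
    P0 <- stats::pnorm((0 - p1) / sigma)
    P1 <- stats::pnorm((1 - p1) / sigma, lower.tail = FALSE)
    L0 <- P0 * (m2 == 0) + P1 * (m2 == n2)
    prev <- P0
    for (j in seq_len(grid_size)) {
        cur <- stats::pnorm((j / grid_size - p1) / sigma)
        q <- (j - 0.5) / grid_size
        L0 <- L0 + (cur - prev) * stats::dbinom(m2, n2, q)
        prev <- cur
    }
    K <- p1 * (m2 == n2) + (1 - p1) * (m2 == 0)
    list(p1 = p1, L0 = L0, K = K, logL0 = log(L0))
}

#' Site log-likelihoods of the neutral and selected XP-CLR models
#'
#' @param m1,n1 object of selection is contrasted against this reference
#'   group: ALT allele count and called allele count in the reference
#'   (wild) group.
#' @param m2,n2 ALT allele count and called allele count in the object
#'   (classical inbred) group.
#' @param omega drift variance scale (see [XpclrParams()]).
#' @param theta sweep length scale in bp.
#' @param distance_bp distance of the site from the putative sweep position.
#' @param grid_size frequency integration grid size.
#' @return A list with numeric vectors `logL0` and `logL1`.
#' @export
xpclrSiteLoglik <- function(m1, n1, m2, n2, omega, theta, distance_bp,
                            grid_size = 200L) {
    stopifnot(theta > 0)
    core <- xpclrSiteCore(m1, n1, m2, n2, omega, grid_size)
    cc <- 1 - exp(-distance_bp / theta)
    list(logL0 = core$logL0,
         logL1 = log(cc * core$L0 + (1 - cc) * core$K))
}

#' Windowed XP-CLR scores
#'
#' For each window the sweep position is fixed at the window center and the
#' composite log-likelihood ratio is maximised over the theta grid:
#' `CLR = max(0, 2 * max_theta sum_sites (logL1 - logL0))`. Windows with
#' fewer than `min_snps` usable sites are masked (`NA`). Sites yielding a
#' non-finite likelihood (e.g. exactly at the window center with an
#' unfixed object allele) are skipped, with one summary warning.
#'
#' @param sites `GRanges` of sites.
#' @param m1,n1,m2,n2 per-site allele counts as in [xpclrSiteLoglik()].
#' @param windows `GRanges` from [makeScanWindows()].
#' @param params An [XpclrParams()].
#' @return A list: `score` (per window, `NA` = masked), `n_snps`.
#' @export
xpclrWindowScores <- function(sites, m1, n1, m2, n2, windows,
                              params = XpclrParams()) {
    usable <- n1 >= 2 & n2 >= 1
    core <- xpclrSiteCore(m1[usable], n1[usable], m2[usable], n2[usable],
                          params@omega, params@freq_grid_size)
    pos <- GenomicRanges::start(sites)[usable]
    hits <- GenomicRanges::findOverlaps(sites[usable], windows)
    by_window <- split(S4Vectors::queryHits(hits),
                       S4Vectors::subjectHits(hits))
    centers <- (GenomicRanges::start(windows) - 1 +
                    GenomicRanges::end(windows)) / 2
    score <- rep(NA_real_, length(windows))
    n_snps <- rep(0L, length(windows))
    n_skipped <- 0L
    for (wname in names(by_window)) {
        w <- as.integer(wname)
        idx <- by_window[[wname]]
        n_snps[w] <- length(idx)
        if (length(idx) < params@min_snps) next
        d <- abs(pos[idx] - centers[w])
        L0 <- core$L0[idx]
        K <- core$K[idx]
        logL0 <- core$logL0[idx]
        best <- -Inf
        for (theta in params@theta_grid) {
            cc <- 1 - exp(-d / theta)
            diff <- log(cc * L0 + (1 - cc) * K) - logL0
            bad <- !is.finite(diff)
            if (any(bad)) n_skipped <- n_skipped + sum(bad)
            s <- sum(diff[!bad])
            if (s > best) best <- s
        }
        score[w] <- max(0, 2 * best)
    }
    if (n_skipped > 0)
        warnf("XP-CLR: %d non-finite site term(s) skipped", n_skipped)
    list(score = score, n_snps = n_snps)
}
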