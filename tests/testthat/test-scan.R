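test_that("sliding windows have the documented geometry", {
    w <- makeScanWindows(c(chr1 = 1e5))
    expect_equal(length(w), 5)
    expect_equal(GenomicRanges::start(w) - 1L, c(0, 1, 2, 3, 4) * 2e4)
    expect_equal(GenomicRanges::end(w), c(4, 6, 8, 10, 10) * 1e4)
    expect_equal(S4Vectors::mcols(w)$trailing, c(rep(FALSE, 4), TRUE))
    ## exactly one full window on a 40 kb chromosome
    w2 <- makeScanWindows(c(chr1 = 4e4))
    expect_equal(sum(!S4Vectors::mcols(w2)$trailing), 1)
    ## chromosome shorter than the window: a single trailing window
    w3 <- makeScanWindows(c(chr1 = 3e4))
    expect_equal(length(w3), 1)
    expect_true(S4Vectors::mcols(w3)$trailing)
    ## interior bp covered by exactly size/step windows
    probe <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(45000, 50000, 79999), width = 1))
    expect_equal(GenomicRanges::countOverlaps(probe, w), c(2L, 2L, 2L))
    expect_error(makeScanWindows(c(chr1 = 1e5), size = 1e4, step = 2e4),
                 "step")
})

test_that("site heterozygosity matches the formula and the pairwise oracle", {
    ## monomorphic
    expect_equal(siteHeterozygosity(cbind(10, 0))$h, 0)
    ## p = 0.5, n = 4 -> (4/3) * 0.5
    expect_equal(siteHeterozygosity(cbind(2, 2))$h, 2 / 3)
    ## brute force over all haplotype pairs, panels of <= 6 haplotypes
    set.seed(42)
    for (rep in 1:20) {
        haps <- sample(0:1, sample(2:6, 1), replace = TRUE)
        counts <- cbind(sum(haps == 0), sum(haps == 1))
        expect_equal(siteHeterozygosity(counts)$h, brute_site_pi(haps))
    }
    ## n_called < 2 flagged and contributing zero
    out <- siteHeterozygosity(cbind(1, 0))
    expect_equal(out$h, 0)
    expect_true(out$low_n)
})

test_that("window aggregation respects the half-open convention", {
    win <- makeScanWindows(c(chr1 = 8e4))  # [0,40k) [20k,60k) [40k,80k) [60k,80k)
    sites <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(1, 20001, 40001), width = 1))
    out <- windowize(c(2 / 3, 1, 1), sites, win, "sum_per_bp")
    ## 0-based site 20000 sits on window 2's start (included there) and
    ## inside window 1; 0-based 40000 is past window 1's half-open end
    expect_equal(out$n_snps, c(2L, 2L, 1L, 0L))
    expect_equal(out$value[1], (2 / 3 + 1) / 4e4)
    ## single site h = 2/3 in a 40 kb window: pi = 1.6667e-5
    one <- windowize(2 / 3, sites[1], win, "sum_per_bp")
    expect_equal(one$value[1], (2 / 3) / 4e4)
    ## empty windows: 0 under sum_per_bp, NA under mean
    expect_equal(one$value[3], 0)
    expect_true(is.na(windowize(2 / 3, sites[1], win, "mean")$value[3]))
})

test_that("pi ratio uses the +Inf sentinel and masks double zeroes", {
    expect_equal(piRatio(2e-4, 2e-4), 1)
    expect_equal(piRatio(2e-4, 5e-5), 4)
    expect_identical(piRatio(1e-4, 0), Inf)
    expect_true(is.na(piRatio(0, 0)))
    expect_error(piRatio(-1e-4, 1e-4), "negative")
})

test_that("Akey Fst reproduces independently evaluated cases", {
    ## values frozen from a hand evaluation of the ANOVA estimator
    expect_equal(akeyFst(10, 1, 10, 0), 1)
    expect_equal(akeyFst(10, 0.5, 10, 0.5), -1 / 9)
    expect_equal(akeyFst(10, 0.8, 10, 0.3), 0.3369175627, tolerance = 1e-9)
    expect_equal(akeyFst(40, 0.9, 20, 0.1), 0.7727033568, tolerance = 1e-9)
    expect_equal(akeyFst(6, 0.5, 4, 0.25), -0.1076923077, tolerance = 1e-9)
    ## monomorphic in both groups: undefined
    expect_true(is.na(akeyFst(10, 0, 10, 0)))
    ## bounded above by 1, attained only at fixed differences (MSG = 0)
    set.seed(1)
    f <- akeyFst(20, runif(200), 30, runif(200))
    expect_true(all(f <= 1 + 1e-12, na.rm = TRUE))
})

test_that("omega calibration follows the closed form", {
    expect_equal(estimateOmega(rep(0.5, 100)), 1)
    expect_equal(estimateOmega(rep(0.2, 100)), 0.25)
    expect_error(estimateOmega(rep(0.2, 50)), "100")
    fx <- small_fixture()
    cw <- groupAlleleCounts(filterSites(fx$panel), "wild")
    ci <- groupAlleleCounts(filterSites(fx$panel), "classical_inbred")
    om <- estimateOmega(akeyFst(cw$n_called, cw$freq_alt,
                                ci$n_called, ci$freq_alt))
    expect_gt(om, 0.05)
    expect_lt(om, 5)
})

test_that("top-window selection uses ceil counts and deterministic ties", {
    win <- makeScanWindows(c(chr1 = 2e4 * 201))  # 200 full + trailing
    stat <- rep(1, length(win))
    stat[length(win)] <- NA  # trailing masked
    sel <- selectTopWindows(stat, win, 0.05)
    expect_equal(length(sel), 10)           # ceil(0.05 * 200)
    expect_equal(sel, 1:10)                 # all-equal: coordinate order
    ## 41 unmasked -> ceil(2.05) = 3
    expect_equal(length(selectTopWindows(rep(1, 41), win[1:41], 0.05)), 3)
    ## +Inf sentinels rank first
    stat2 <- runif(length(win)); stat2[37] <- Inf
    expect_equal(selectTopWindows(stat2, win, 0.01)[1], 37L)
    expect_warning(sel0 <- selectTopWindows(rep(NA_real_, 3), win[1:3]),
                   "masked")
    expect_length(sel0, 0)
})

test_that("window-to-gene mapping uses 1 bp overlap and set semantics", {
    spans <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
        c(1000, 39000, 41000, 80000, 200000), width = 2000))
    names(spans) <- paste0("g", 1:5)
    genes <- GeneModelSet(spans)
    win <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
        c(1, 40001), c(40000, 80000)))
    ## g1 inside, g2 straddles, g3 in window 2, g4 1 bp overlap, g5 outside
    expect_equal(windowsToGenes(win, genes), c("g1", "g2", "g3", "g4"))
    expect_equal(windowsToGenes(win[1], genes), c("g1", "g2"))
})

test_that("PSG intersection and Venn counts are consistent", {
    out <- intersectPsgs(c("a", "b", "c"), c("b", "c", "d"), c("c", "b"))
    expect_equal(out$psgs, c("b", "c"))
    expect_equal(out$venn$n_all, 2)
    expect_equal(out$venn$n_pi_fst, 2)
    expect_equal(intersectPsgs("a", "b", "c")$psgs, character())
    same <- intersectPsgs(c("x", "y"), c("y", "x"), c("x", "y"))
    expect_equal(same$psgs, c("x", "y"))
})
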