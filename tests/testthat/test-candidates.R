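groups_wi <- function(nw, ni) rep(c("wild", "classical_inbred"),
                                  c(nw, ni))

test_that("the strict homozygosity rule behaves at its boundaries", {
    ## wild all het, inbred all hom-ref: pass
    gp <- toy_panel(matrix(c(rep("0/1", 3), rep("0/0", 3)), 1, 6),
                    groups_wi(3, 3))
    expect_true(strictCandidateRule(gp)$pass)
    ## one inbred heterozygote: fail
    gp2 <- toy_panel(matrix(c(rep("0/1", 3), "0/0", "0/0", "0/1"), 1, 6),
                     groups_wi(3, 3))
    out2 <- strictCandidateRule(gp2)
    expect_false(out2$pass)
    expect_equal(out2$reason, "inbred_not_homref")
    ## any missing genotype disqualifies
    gp3 <- toy_panel(matrix(c("0/1", "0/1", "./.", rep("0/0", 3)), 1, 6),
                     groups_wi(3, 3))
    out3 <- strictCandidateRule(gp3)
    expect_false(out3$pass)
    expect_equal(out3$reason, "missing")
    ## a wild hom-ref sample disqualifies
    gp4 <- toy_panel(matrix(c("0/0", "0/1", "0/1", rep("0/0", 3)), 1, 6),
                     groups_wi(3, 3))
    expect_equal(strictCandidateRule(gp4)$reason, "wild_homref")
})

test_that("an inbred panel not fully hom-ref fails the strict rule", {
    ## reference frequency 0.793 in the inbred group (23 hom-ref + 6
    ## hom-alt of 29 strains): the original rule cannot select such a site
    gt <- matrix(c(rep("1/1", 20), "0/1",              # wild: no hom-ref
                   rep("0/0", 23), rep("1/1", 6)), 1)
    gp <- toy_panel(gt, groups_wi(21, 29))
    ci <- groupAlleleCounts(gp, "classical_inbred")
    expect_equal(ci$freq_ref, 46 / 58, tolerance = 1e-12)  # ~0.793
    expect_false(strictCandidateRule(gp)$pass)
    ## while the relaxed rule admits it at the printed frequencies
    expect_true(relaxedCandidateRule(0.0417, 0.793))
})

test_that("the relaxed rule is strict at the factor boundary", {
    expect_true(relaxedCandidateRule(0.0417, 0.793))
    expect_false(relaxedCandidateRule(0.2, 1.0))   # 0.2 < 0.2 fails
    expect_true(relaxedCandidateRule(0, 0.3))
    expect_false(relaxedCandidateRule(0, 0))       # f_inbred = 0 fails
    expect_error(relaxedCandidateRule(1.2, 0.5), "frequencies")
    ## monotonicity: decreasing the factor never adds passes
    set.seed(4)
    fw <- runif(200); fi <- runif(200)
    prev <- rep(TRUE, 200)
    for (fac in c(0.5, 0.2, 0.1, 0.02)) {
        cur <- relaxedCandidateRule(fw, fi, fac)
        expect_true(all(cur <= prev))
        prev <- cur
    }
})

test_that("allelicity counts distinct observed alleles per group", {
    gp <- toy_panel(matrix(c("0/0", "0/0",   # single
                             "0/1", "0/0",   # bi
                             "0/1", "2/2",   # tri
                             "./.", "./."),  # undefined
                           4, 2, byrow = TRUE),
                    rep("wild", 2),
                    alt = list("G", "G", c("G", "T"), "G"))
    cls <- siteAllelicity(gp, "wild")
    expect_equal(as.character(cls), c("single", "bi", "tri", NA))
    ## adding samples never decreases the allelicity class
    gp_more <- toy_panel(matrix(c("0/0", "0/0", "0/1",
                                  "0/1", "0/0", "1/2",
                                  "0/1", "2/2", "0/0",
                                  "./.", "./.", "0/0"),
                                4, 3, byrow = TRUE),
                         rep("wild", 3),
                         alt = list("G", c("G", "T"), c("G", "T"), "G"))
    before <- as.integer(cls)
    after <- as.integer(siteAllelicity(gp_more, "wild"))
    comparable <- !is.na(before)
    expect_true(all(after[comparable] >= before[comparable]))
})

test_that("gene candidate scans enumerate engineered passes", {
    ## 10 sites in the gene; sites 1-3 engineered to pass the relaxed rule
    nw <- 5; ni <- 5
    gt <- matrix("0/1", 10, nw + ni)
    gt[1:3, 1:nw] <- "1/1"                 # wild ref freq 0
    gt[1:3, (nw + 1):(nw + ni)] <- "0/0"   # inbred ref freq 1
    gp <- toy_panel(gt, groups_wi(nw, ni), pos = seq(1100, 2000, by = 100))
    gene <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 2000))
    tab <- scanGeneCandidates(gp, gene)
    expect_equal(nrow(tab), 10)
    expect_equal(sum(tab$relaxed_pass), 3)
    expect_equal(which(tab$relaxed_pass), 1:3)
    expect_equal(attr(tab, "summary")$n_relaxed, 3)
    ## those sites also pass the strict rule here, and strict implies
    ## relaxed when wild genotypes are non-reference homozygotes
    expect_true(all(tab$relaxed_pass[tab$strict_pass]))
    ## a gene with no sites yields an empty table with a warning
    empty <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5e5, 6e5))
    expect_warning(tab0 <- scanGeneCandidates(gp, empty), "no sites")
    expect_equal(nrow(tab0), 0)
})
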