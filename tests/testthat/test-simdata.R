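test_that("wild simulation is deterministic and matches the analytic SFS", {
    cfg <- SweepSimConfig(n_chrom = 1, chrom_length_bp = 1e6, n_sites = 5000,
                          n_wild = 10, n_inbred = 2, n_founders = 2,
                          sweeps = data.frame(chrom = character(),
                                              center_bp = numeric(),
                                              half_width_bp = numeric()),
                          missing_rate = 0, n_genes = 5, seed = 11)
    w1 <- simulateWildPanel(cfg)
    w2 <- simulateWildPanel(cfg)
    expect_identical(alleles(w1), alleles(w2))
    f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
    writeGenotypeVcf(w1, f1); writeGenotypeVcf(w2, f2)
    expect_identical(readLines(f1), readLines(f2))
    ## observed mean heterozygosity vs closed-form SFS expectation
    h <- siteHeterozygosity(groupAlleleCounts(w1, "wild")$counts)$h
    expect_lt(abs(mean(h) / expectedSfsHeterozygosity(10, 1) - 1), 0.1)
})

test_that("a single wild sample still yields emitted sites", {
    cfg <- SweepSimConfig(n_chrom = 1, chrom_length_bp = 1e5, n_sites = 50,
                          n_wild = 1, n_inbred = 1, n_founders = 1,
                          sweeps = data.frame(chrom = character(),
                                              center_bp = numeric(),
                                              half_width_bp = numeric()),
                          missing_rate = 0, n_genes = 2, seed = 3)
    w <- simulateWildPanel(cfg)
    expect_equal(nSites(w), 50)
    expect_equal(nSamples(w), 1)
    hz <- siteHeterozygosity(groupAlleleCounts(w, "wild")$counts)
    expect_true(all(hz$low_n == (groupAlleleCounts(w, "wild")$n_called < 2)))
})

test_that("inbred panel is near-homozygous with depressed sweep diversity", {
    fx <- small_fixture()
    al <- alleles(fx$inbred)
    called <- !is.na(al$a1)
    expect_lt(mean(al$a1[called] != al$a2[called]), 0.01)
    ## windowed inbred diversity inside sweeps is below the outside level
    h <- siteHeterozygosity(
        groupAlleleCounts(fx$inbred, "classical_inbred")$counts)$h
    win <- fx$truth$windows
    pw <- windowize(h, siteRanges(fx$inbred), win, "sum_per_bp")$value
    inside <- fx$truth$sweep_windows
    outside <- setdiff(seq_along(win), fx$truth$sweep_region_windows)
    expect_lt(mean(pw[inside]), mean(pw[outside]))
})

test_that("the documented fixture loses essentially all core sweep diversity", {
    fx <- full_fixture()
    df <- as.data.frame(fx$scan)
    inside <- fx$truth$sweep_windows
    outside <- setdiff(which(!df$masked), fx$truth$sweep_region_windows)
    expect_lt(mean(df$pi_inbred[inside]),
              0.1 * mean(df$pi_inbred[outside]))
})

test_that("with all wild samples as founders and no sweeps, inbred allele frequencies track wild", {
    cfg <- SweepSimConfig(n_chrom = 1, chrom_length_bp = 5e5, n_sites = 3000,
                          n_wild = 10, n_inbred = 20, n_founders = 10,
                          sweeps = data.frame(chrom = character(),
                                              center_bp = numeric(),
                                              half_width_bp = numeric()),
                          missing_rate = 0, het_rate = 0, n_genes = 5,
                          seed = 5)
    w <- simulateWildPanel(cfg)
    inb <- deriveInbredPanel(w, cfg)$panel
    fw <- groupAlleleCounts(w, "wild")$freq_alt
    fi <- groupAlleleCounts(inb, "classical_inbred")$freq_alt
    expect_lt(mean(abs(fw - fi)), 0.15)
})

test_that("expression simulator responds to the brain effect and is deterministic", {
    genes <- sprintf("g%03d", 1:200)
    designated <- genes[1:50]
    e1 <- simulateExpressionData(genes, designated, brain_effect = 4,
                                 seed = 21)
    e2 <- simulateExpressionData(genes, designated, brain_effect = 4,
                                 seed = 21)
    expect_identical(e1, e2)
    flags <- flagHighlyExpressed(mergeTissueCategories(e1$rpkm, e1$mapping))
    expect_gte(mean(flags[designated, "brain"]), 0.9)
    ## null effect: brain category flag rate comparable to other categories
    e0 <- simulateExpressionData(genes, designated, brain_effect = 1,
                                 seed = 21)
    f0 <- flagHighlyExpressed(mergeTissueCategories(e0$rpkm, e0$mapping))
    rates <- colMeans(f0)
    expect_lt(abs(rates["brain"] - mean(rates)), 3 * stats::sd(rates))
    expect_error(simulateExpressionData(genes, brain_effect = 0),
                 "positive")
})

test_that("fixture bundle writes consistent, re-readable files", {
    dir <- tempfile("bundle")
    cfg <- small_config()
    paths <- writeFixtureBundle(dir, cfg)
    expect_true(all(file.exists(unlist(paths))))
    truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
    expect_equal(nrow(truth$sweeps), nrow(cfg@sweeps))
    ## BED intervals within chromosome bounds
    bed <- read.delim(paths$genes, header = FALSE)
    expect_true(all(bed[[2]] >= 0 & bed[[3]] <= cfg@chrom_length_bp))
    ## genes round-trip through the BED reader
    genes <- readGeneModelsBed(paths$genes)
    ref <- geneModelsFromConfig(cfg)
    expect_identical(geneIds(genes), geneIds(ref))
    expect_identical(unname(GenomicRanges::start(geneSpans(genes))),
                     unname(GenomicRanges::start(geneSpans(ref))))
    expect_identical(unname(lapply(geneExons(genes), GenomicRanges::start)),
                     unname(lapply(geneExons(ref), GenomicRanges::start)))
})
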