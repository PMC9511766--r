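test_that("tissue categories merge by arithmetic mean", {
    rpkm <- matrix(c(1, 2, 3, 7), 1,
                   dimnames = list("g1", c("CNS E11.5", "CNS E14",
                                           "CNS E18", "liver")))
    merged <- mergeTissueCategories(rpkm)
    expect_equal(merged["g1", "immature brain"], 2)
    expect_equal(merged["g1", "liver"], 7)  # singleton unchanged
    ## a 23-tissue header collapses to 17 categories under the default map
    tissues23 <- c("CNS E11.5", "CNS E14", "CNS E18", "cerebellum",
                   "cortex", "frontal lobe", "spleen", "thymus",
                   "genital fat pad", "subcutaneous fat pad",
                   "liver", "heart", "lung", "kidney", "bladder", "stomach",
                   "testis", "ovary", "placenta", "limb", "mammary gland",
                   "pancreas", "adrenal gland")
    m23 <- matrix(1, 2, 23, dimnames = list(c("a", "b"), tissues23))
    expect_equal(ncol(mergeTissueCategories(m23)), 17)
    expect_error(mergeTissueCategories(m23, mapping = c(liver = "liver")),
                 "unmapped")
})

test_that("the 2-fold high-expression rule is inclusive and bounded", {
    ## uniform gene: ratio 1 everywhere, never flagged
    uni <- matrix(5, 1, 17, dimnames = list("u", paste0("c", 1:17)))
    expect_false(any(flagHighlyExpressed(uni)))
    ## [10, 0, ..., 0]: only the first category (10 >= 2 * 10/17)
    spike <- matrix(c(10, rep(0, 16)), 1,
                    dimnames = list("s", paste0("c", 1:17)))
    expect_equal(which(flagHighlyExpressed(spike)), 1L)
    ## exactly 2x the mean is flagged ("at least 2-fold")
    v <- c(4, rep(1, 15), 15)  # mean = 2, first entry exactly 2x
    m <- matrix(v, 1, dimnames = list("e", paste0("c", 1:17)))
    expect_true(flagHighlyExpressed(m)[1, 1])
    ## all-zero gene: no flags
    z <- matrix(0, 1, 17, dimnames = list("z", paste0("c", 1:17)))
    expect_false(any(flagHighlyExpressed(z)))
    ## a gene can never be >= 2x its own mean in more than 8 categories
    set.seed(8)
    r <- matrix(rexp(100 * 17), 100, dimnames = list(NULL, paste0("c", 1:17)))
    expect_true(all(rowSums(flagHighlyExpressed(r)) <= 8))
})

test_that("category ratios reproduce the reported percent arithmetic", {
    flags <- matrix(FALSE, 286, 2,
                    dimnames = list(sprintf("g%03d", 1:286),
                                    c("immature brain", "brain")))
    flags[1:97, "immature brain"] <- TRUE
    flags[1:111, "brain"] <- TRUE
    genes <- rownames(flags)
    cr <- categoryRatio(flags, genes)
    expect_equal(cr$percent[cr$category == "immature brain"], 33.9)
    expect_equal(cr$percent[cr$category == "brain"], 38.8)
    ## invariant to gene ordering
    cr2 <- categoryRatio(flags, rev(genes))
    expect_equal(cr2$percent, cr$percent)
    expect_equal(categoryRatio(flags[1:5, , drop = FALSE] & FALSE,
                               genes[1:5])$percent, c(0, 0))
    expect_error(categoryRatio(flags, character()), "empty")
})

test_that("rank-sum U equals brute-force pair counting", {
    ## brain strictly greater: U maximal, small one-sided p
    out <- rankSumBrainVsOther(c(10, 11, 12, 1, 2, 3, 4), 1:3)
    expect_equal(out$U, 12)
    expect_lt(out$p, 0.05)
    ## mirror symmetry: identical value multisets give p = 0.5
    sym <- rankSumBrainVsOther(c(1, 2, 3, 1, 2, 3), 1:3)
    expect_equal(sym$p, 0.5, tolerance = 1e-12)
    ## all tied: flagged, no evidence
    tied <- rankSumBrainVsOther(rep(2, 8), 1:4)
    expect_true(tied$all_tied)
    expect_equal(tied$p, 0.5)
    ## exhaustive pair-count oracle on vectors of <= 20 values (with ties)
    set.seed(17)
    for (rep in 1:20) {
        nx <- sample(2:9, 1); ny <- sample(2:11, 1)
        vals <- round(runif(nx + ny, 0, 4), 1)
        out <- rankSumBrainVsOther(vals, seq_len(nx))
        expect_equal(out$U, brute_U(vals[seq_len(nx)], vals[-seq_len(nx)]))
    }
})

test_that("phenotype enrichment reproduces the printed arithmetic", {
    pf <- phenotypeFold(125, 245, 0.301, 1)
    expect_equal(pf$percent, 51.0)
    expect_equal(pf$fold, 1.7)
    expect_equal(phenotypeFold(30, 100, 30, 100)$fold, 1.0)
    expect_error(phenotypeFold(0, 0, 1, 2), "positive")
})

test_that("DE-ratio elevation uses strict thresholds and hand-checked toys", {
    ## 20 genes, 5 PSGs; 4 DE overall of which 2 in the PSG set
    genes <- sprintf("g%02d", 1:20)
    padj <- rep(0.5, 20); fpkm <- rep(10, 20)
    padj[c(1, 2, 6, 7)] <- 0.01
    padj[3] <- 0.05           # boundary: NOT DE (strict <)
    fpkm[7] <- 1              # boundary: NOT DE (strict >)
    tab <- data.frame(gene = genes, padj = padj, fpkm = fpkm)
    psgs <- genes[1:5]
    out <- deRatioElevation(list(hippocampus = tab), psgs)
    expect_equal(out$ratio_all, 3 / 20)
    expect_equal(out$ratio_psg, 2 / 5)
    expect_equal(out$delta_points, 100 * (0.4 - 0.15))
    expect_equal(out$fold, (2 / 5) / (3 / 20))
    ## no DE genes anywhere: delta 0, fold undefined
    none <- data.frame(gene = genes, padj = 0.9, fpkm = 10)
    out0 <- deRatioElevation(list(lung = none), psgs)
    expect_equal(out0$delta_points, 0)
    expect_true(is.na(out0$fold))
    expect_error(deRatioElevation(list(lung = none), "absent"), "lung")
})

test_that("common DE genes intersect flagged tables", {
    a <- data.frame(gene = c("x", "y", "z"), padj = c(0.01, 0.01, 0.5),
                    fpkm = c(5, 5, 5))
    b <- data.frame(gene = c("x", "y", "z"), padj = c(0.01, 0.5, 0.01),
                    fpkm = c(5, 5, 5))
    expect_equal(commonDeGenes(a, b), "x")
    expect_equal(commonDeGenes(a, a), c("x", "y"))
    none <- data.frame(gene = "w", padj = 0.01, fpkm = 5)
    expect_equal(commonDeGenes(a, none), character())
})

test_that("YAML category mappings load into the merge format", {
    path <- tempfile(fileext = ".yaml")
    writeLines(c("brain:", "  - cerebellum", "  - cortex",
                 "liver: [liver]"), path)
    map <- readCategoryMapping(path)
    expect_equal(unname(map[c("cerebellum", "cortex", "liver")]),
                 c("brain", "brain", "liver"))
})
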