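# Shared fixtures (built once per run) and brute-force oracles.

.fx <- new.env(parent = emptyenv())

small_config <- function()
    SweepSimConfig(n_chrom = 1, chrom_length_bp = 4e5, n_sites = 2000,
                   n_wild = 10, n_inbred = 10, n_founders = 4,
                   sweeps = data.frame(chrom = "chr1", center_bp = 2e5,
                                       half_width_bp = 5e4),
                   n_genes = 9, seed = 7)

small_fixture <- function() {
    if (is.null(.fx$small)) {
        cfg <- small_config()
        wild <- simulateWildPanel(cfg)
        inb <- deriveInbredPanel(wild, cfg)
        .fx$small <- list(config = cfg, wild = wild, inbred = inb$panel,
                          truth = inb$truth,
                          panel = combinePanels(wild, inb$panel),
                          genes = geneModelsFromConfig(cfg))
    }
    .fx$small
}

## The documented fixture plus its selection scan (the expensive part;
## shared between the recovery and XP-CLR tests).
full_fixture <- function() {
    if (is.null(.fx$full)) {
        cfg <- defaultFixtureConfig()
        wild <- simulateWildPanel(cfg)
        inb <- deriveInbredPanel(wild, cfg)
        panel <- combinePanels(wild, inb$panel)
        genes <- geneModelsFromConfig(cfg)
        scan <- selectionScan(panel, genes)
        .fx$full <- list(config = cfg, wild = wild, panel = panel,
                         genes = genes, truth = inb$truth, scan = scan)
    }
    .fx$full
}

## Build a panel from a character genotype matrix ("0/0", "0|1", "./."),
## sites x samples.
toy_panel <- function(gt, groups, chrom = "chr1", pos = NULL,
                      ref = NULL, alt = NULL) {
    gt <- as.matrix(gt)
    n <- nrow(gt)
    if (is.null(pos)) pos <- seq_len(n) * 100L
    if (is.null(ref)) ref <- rep("A", n)
    if (is.null(alt)) alt <- as.list(rep("G", n))
    parse1 <- function(k) {
        v <- vapply(strsplit(as.vector(gt), "[/|]"), `[`, "", k)
        v[v == "."] <- NA
        matrix(as.integer(v), n, ncol(gt))
    }
    a1 <- parse1(1); a2 <- parse1(2)
    if (is.null(colnames(gt)))
        colnames(a1) <- colnames(a2) <- sprintf("s%02d", seq_len(ncol(gt)))
    else colnames(a1) <- colnames(a2) <- colnames(gt)
    sites <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1),
                                    ref = ref,
                                    alt = IRanges::CharacterList(alt))
    GenotypePanel(a1, a2, sites, groups)
}

## Brute-force mean pairwise difference at one site over haplotypes.
brute_site_pi <- function(haps) {
    n <- length(haps)
    if (n < 2) return(0)
    tot <- 0; np <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        tot <- tot + (haps[i] != haps[j]); np <- np + 1
    }
    tot / np
}

## Brute-force Mann-Whitney U: pairs with x > y plus half the ties.
brute_U <- function(x, y) {
    u <- 0
    for (xi in x) for (yi in y)
        u <- u + (xi > yi) + 0.5 * (xi == yi)
    u
}
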