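## End-to-end orchestration: simulate (or accept) a panel, run the scan,
## the clustering check, the expression enrichment, the candidate rules
## and the qPCR arithmetic, and emit a machine-readable report.

#' Run the full domestication-scan pipeline
#'
#' Either simulates a study from a [SweepSimConfig()] (the default — the
#' documented fixture) or consumes a supplied panel/gene set. Stages:
#' site filtering, the three-statistic [selectionScan()], neighbor-joining
#' separation check, expression enrichment of the PSG set, DE-ratio
#' elevation, candidate-SNP rules over the first sweep gene, and the
#' 2^-ddCt fixtures. When simulation truth is available the report also
#' carries sweep-gene recall and the non-sweep false-positive fraction.
#' Deterministic given the configuration (including its seed).
#'
#' @param config A [SweepSimConfig()]; ignored when `panel` is supplied.
#' @param panel optional [GenotypePanel()] with both groups (then `genes`
#'   is required and no truth metrics are computed).
#' @param genes optional [GeneModelSet()].
#' @param window_size,step,top_fraction,min_snps scan parameters.
#' @param relaxed_factor factor of the relaxed candidate rule.
#' @param out_dir optional output directory; when given, the per-window
#'   TSV, PSG list, tree Newick and report JSON are written there.
#' @return A list of class `domestication_report` (window counts, top-set
#'   sizes, Venn counts, PSG list, recall/precision, clustering, enrichment
#'   ratios, candidate counts, qPCR summaries).
#' @export
runDomesticationScan <- function(config = defaultFixtureConfig(),
                                 panel = NULL, genes = NULL,
                                 window_size = 40000, step = 20000,
                                 top_fraction = 0.05, min_snps = 10L,
                                 relaxed_factor = 0.2, out_dir = NULL) {
    truth <- NULL
    if (is.null(panel)) {
        wild <- simulateWildPanel(config)
        inbred <- deriveInbredPanel(wild, config)
        panel <- combinePanels(wild, inbred$panel)
        truth <- inbred$truth
        if (is.null(genes)) genes <- geneModelsFromConfig(config)
    }
    if (is.null(genes)) stopf("genes are required with a supplied panel")

    scan <- selectionScan(panel, genes, window_size = window_size,
                          step = step, top_fraction = top_fraction,
                          min_snps = min_snps)
    w <- scan@windows
    report <- list(
        n_samples = nSamples(panel),
        n_sites_input = nSites(panel),
        n_windows = length(w),
        n_unmasked = sum(!mcols(w)$masked),
        top_set_sizes = vapply(scan@topWindows, length, 0L),
        venn = scan@venn,
        omega = scan@omega,
        psgs = scan@psgs,
        n_psgs = length(scan@psgs))

    if (!is.null(truth)) {
        sweep_genes <- truth$sweep_genes
        non_sweep <- setdiff(geneIds(genes), sweep_genes)
        report$sweep_genes <- sweep_genes
        report$sweep_gene_recall <-
            mean(sweep_genes %in% scan@psgs)
        report$nonsweep_psg_fraction <-
            length(setdiff(scan@psgs, sweep_genes)) /
            max(1L, length(non_sweep))
    }

    ## clustering check on the filtered panel
    fpanel <- filterSites(panel)
    dm <- pairwiseDistance(fpanel)
    tree <- neighborJoining(dm)
    inbred_ids <- names(sampleGroups(panel))[
        sampleGroups(panel) == "classical_inbred"]
    report$inbred_monophyletic <- isGroupMonophyletic(tree, inbred_ids)

    ## expression enrichment of the PSG set
    designated <- if (!is.null(truth)) truth$sweep_genes else scan@psgs
    expr <- simulateExpressionData(geneIds(genes), designated = designated,
                                   seed = config@seed + 2)
    merged <- mergeTissueCategories(expr$rpkm, expr$mapping)
    flags <- flagHighlyExpressed(merged)
    if (length(scan@psgs)) {
        cr <- categoryRatio(flags, scan@psgs)
        report$high_expression <- cr
        report$brain_high_percent <-
            cr$percent[cr$category == "brain"]
        report$immature_brain_high_percent <-
            cr$percent[cr$category == "immature brain"]
        brain_cats <- c("immature brain", "brain")
        rs <- vapply(scan@psgs, function(g)
            rankSumBrainVsOther(merged[g, ],
                                which(colnames(merged) %in% brain_cats))$p,
            0)
        report$n_brain_ranksum_significant <- sum(rs < 0.05)
        report$de_elevation <- deRatioElevation(expr$de_tables, scan@psgs)
        report$common_de_brain <- commonDeGenes(
            expr$de_tables$hippocampus, expr$de_tables$frontal_lobe)
    }
    ph <- expr$phenotypes
    modeled <- ph$has_model
    in_psg <- ph$gene %in% scan@psgs
    if (any(modeled & in_psg)) {
        pf <- phenotypeFold(sum(ph$abnormal_behavior & modeled & in_psg),
                            sum(modeled & in_psg),
                            max(1L, sum(ph$abnormal_behavior & modeled)),
                            sum(modeled))
        report$phenotype_percent <- pf$percent
        report$phenotype_fold <- pf$fold
    }

    ## candidate rules over the first sweep (or first PSG) gene
    cand_gene <- if (!is.null(truth) && length(truth$sweep_genes))
        truth$sweep_genes[[1]] else if (length(scan@psgs)) scan@psgs[[1]]
        else NULL
    if (!is.null(cand_gene)) {
        cand <- scanGeneCandidates(fpanel, genes, gene_id = cand_gene,
                                   factor = relaxed_factor)
        report$candidate_gene <- cand_gene
        report$candidate_summary <- attr(cand, "summary")
    }

    ## qPCR arithmetic on simulated Ct tables
    ct <- simulateCtTable(seed = config@seed + 3)
    dd <- ddctFold(ct)
    report$qpcr_treatment_mean_fold <-
        unname(attr(dd, "group_means")["treatment"])
    iso <- data.frame(sample = ct$sample, group = ct$group,
                      ct_isoform_a = ct$ct_target,
                      ct_isoform_b = ct$ct_reference)
    ir <- isoformRatio(iso)
    report$isoform_ratio_treatment <-
        unname(attr(ir, "group_means")["treatment"])

    class(report) <- "domestication_report"
    if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        utils::write.table(as.data.frame(scan),
                           file.path(out_dir, "window_stats.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        writeLines(scan@psgs, file.path(out_dir, "psgs.txt"))
        writeLines(tree$newick, file.path(out_dir, "tree.nwk"))
        rep_json <- report
        rep_json$high_expression <- NULL
        jsonlite::write_json(unclass(rep_json),
                             file.path(out_dir, "report.json"),
                             auto_unbox = TRUE, digits = NA,
                             dataframe = "columns", force = TRUE)
    }
    report
}

#' @export
print.domestication_report <- function(x, ...) {
    cat("Domestication scan report\n")
    cat(sprintf("  windows: %d (%d unmasked); PSGs: %d\n",
                x$n_windows, x$n_unmasked, x$n_psgs))
    if (!is.null(x$sweep_gene_recall))
        cat(sprintf("  sweep-gene recall: %.2f; non-sweep PSG fraction: %.3f\n",
                    x$sweep_gene_recall, x$nonsweep_psg_fraction))
    cat(sprintf("  inbred group monophyletic: %s\n",
                x$inbred_monophyletic))
    if (!is.null(x$brain_high_percent))
        cat(sprintf("  highly expressed in brain: %.1f%%; immature brain: %.1f%%\n",
                    x$brain_high_percent, x$immature_brain_high_percent))
    invisible(x)
}
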