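## Synthetic wild/inbred panels with planted selective sweeps.
##
## No coalescent machinery: per-site derived-allele frequencies are drawn
## i.i.d. from a neutral-SFS-weighted law (weight ~ 1/i^sfs_shape over allele
## counts i), and linkage enters only through the founder-mosaic construction
## of the inbred panel. That is deliberately desk-scale: it is sufficient to
## exercise windowed statistics and the sweep model, not to emulate real
## mouse demography.

#' Configuration of the synthetic wild/inbred study
#'
#' The defaults are the documented fixture on which the package's recovery
#' properties are assessed: 2 chromosomes of 2 Mb, 20,000 SNPs, 20 wild and
#' 20 inbred samples derived from 8 founders, 100 genes of 20 kb spaced every
#' 40 kb, and 3 planted sweeps of half-width 300 kb centered on gene
#' midpoints (the escape scale must be much wider than a 40 kb window for
#' the swept core to lose essentially all diversity).
#'
#' @slot n_chrom,chrom_length_bp,n_sites,n_wild,n_inbred,n_founders numeric
#'   panel dimensions; `n_founders <= n_wild` is required.
#' @slot sweeps data.frame with columns `chrom`, `center_bp`, `half_width_bp`;
#'   each sweep region `center +/- half_width` must lie within its chromosome.
#' @slot sfs_shape numeric, exponent of the neutral SFS weight `1/i^shape`.
#' @slot missing_rate numeric, per-genotype missingness injected into output.
#' @slot het_rate numeric, residual heterozygosity of the inbred panel.
#' @slot block_bp numeric, mean founder-mosaic block length (exponential).
#' @slot n_genes,gene_length_bp,gene_spacing_bp,gene_offset_bp numeric gene
#'   grid layout (genes split evenly across chromosomes).
#' @slot seed integer, master seed; all outputs are pure functions of the
#'   configuration including this seed.
#' @export
setClass("SweepSimConfig", slots = c(
    n_chrom = "numeric", chrom_length_bp = "numeric", n_sites = "numeric",
    n_wild = "numeric", n_inbred = "numeric", n_founders = "numeric",
    sweeps = "data.frame", sfs_shape = "numeric", missing_rate = "numeric",
    het_rate = "numeric", block_bp = "numeric", n_genes = "numeric",
    gene_length_bp = "numeric", gene_spacing_bp = "numeric",
    gene_offset_bp = "numeric", seed = "numeric"))

setValidity("SweepSimConfig", function(object) {
    msg <- character()
    counts <- c(object@n_chrom, object@chrom_length_bp, object@n_sites,
                object@n_wild, object@n_inbred, object@n_founders,
                object@n_genes)
    if (any(!is.finite(counts)) || any(counts < 1))
        msg <- c(msg, "all counts must be positive")
    if (object@n_founders > object@n_wild)
        msg <- c(msg, "n_founders must not exceed n_wild")
    sw <- object@sweeps
    if (nrow(sw)) {
        if (!all(c("chrom", "center_bp", "half_width_bp") %in% names(sw)))
            msg <- c(msg, "sweeps needs chrom/center_bp/half_width_bp columns")
        else {
            ok_chrom <- sw$chrom %in% simChromNames(object)
            inb <- sw$center_bp - sw$half_width_bp >= 0 &
                sw$center_bp + sw$half_width_bp <= object@chrom_length_bp
            if (!all(ok_chrom) || !all(inb))
                msg <- c(msg, "sweep regions must lie within chromosome bounds")
        }
    }
    if (object@missing_rate < 0 || object@missing_rate >= 1)
        msg <- c(msg, "missing_rate must be in [0, 1)")
    if (length(msg)) msg else TRUE
})

simChromNames <- function(config) paste0("chr", seq_len(config@n_chrom))

#' @rdname SweepSimConfig-class
#' @param n_chrom,chrom_length_bp,n_sites,n_wild,n_inbred,n_founders,sweeps,sfs_shape,missing_rate,het_rate,block_bp,n_genes,gene_length_bp,gene_spacing_bp,gene_offset_bp,seed see slot documentation.
#' @return A `SweepSimConfig`.
#' @export
SweepSimConfig <- function(n_chrom = 2, chrom_length_bp = 2e6,
                           n_sites = 20000, n_wild = 20, n_inbred = 20,
                           n_founders = 8,
                           sweeps = data.frame(
                               chrom = c("chr1", "chr1", "chr2"),
                               center_bp = c(5e5, 1.3e6, 9.8e5),
                               half_width_bp = c(3e5, 3e5, 3e5)),
                           sfs_shape = 1, missing_rate = 0.01,
                           het_rate = 0.002, block_bp = 1e5,
                           n_genes = 100, gene_length_bp = 2e4,
                           gene_spacing_bp = 4e4, gene_offset_bp = 1e4,
                           seed = 1729) {
    new("SweepSimConfig", n_chrom = n_chrom, chrom_length_bp = chrom_length_bp,
        n_sites = n_sites, n_wild = n_wild, n_inbred = n_inbred,
        n_founders = n_founders, sweeps = sweeps, sfs_shape = sfs_shape,
        missing_rate = missing_rate, het_rate = het_rate, block_bp = block_bp,
        n_genes = n_genes, gene_length_bp = gene_length_bp,
        gene_spacing_bp = gene_spacing_bp, gene_offset_bp = gene_offset_bp,
        seed = seed)
}

#' The documented fixture configuration
#'
#' @return The default `SweepSimConfig` (seed 1729).
#' @export
defaultFixtureConfig <- function() SweepSimConfig()

setMethod("show", "SweepSimConfig", function(object) {
    cat(sprintf(
        "SweepSimConfig: %d chrom x %g bp, %g SNPs, %g wild + %g inbred (%g founders), %d sweeps, seed %g\n",
        object@n_chrom, object@chrom_length_bp, object@n_sites, object@n_wild,
        object@n_inbred, object@n_founders, nrow(object@sweeps), object@seed))
})

#' Deterministic gene grid of a simulation configuration
#'
#' Genes are laid on a regular grid (`gene_offset_bp + i * gene_spacing_bp`,
#' 0-based starts), split evenly across chromosomes, each with three equal
#' exons at relative offsets 0, 2/5 and 4/5 of the gene length.
#'
#' @param config A [SweepSimConfig()].
#' @return A [GeneModelSet()].
#' @export
geneModelsFromConfig <- function(config) {
    per_chrom <- rep(floor(config@n_genes / config@n_chrom), config@n_chrom)
    extra <- config@n_genes - sum(per_chrom)
    if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1
    glen <- config@gene_length_bp
    exlen <- round(glen / 5)
    spans <- exs <- list()
    for (ci in seq_len(config@n_chrom)) {
        chrom <- simChromNames(config)[ci]
        start0 <- config@gene_offset_bp +
            config@gene_spacing_bp * (seq_len(per_chrom[ci]) - 1L)
        keep <- start0 + glen <= config@chrom_length_bp
        start0 <- start0[keep]
        ids <- sprintf("gene_%s_%03d", sub("chr", "c", chrom),
                       seq_along(start0))
        spans[[ci]] <- GRanges(chrom, IRanges(start0 + 1L, start0 + glen))
        names(spans[[ci]]) <- ids
        exs[[ci]] <- lapply(start0, function(s0) {
            off <- round(c(0, 2, 4) / 5 * glen)
            GRanges(chrom, IRanges(s0 + off + 1L, s0 + off + exlen))
        })
    }
    spans <- suppressWarnings(do.call(c, spans))
    exons <- GRangesList(do.call(c, exs))
    names(exons) <- names(spans)
    GeneModelSet(spans, exons)
}

## Draw per-site derived (ALT) allele frequencies from the SFS-weighted law:
## allele count i in 1..(2n-1) with weight 1/i^shape, frequency i/(2n).
sampleSfsFrequencies <- function(n_sites, n_diploid, shape) {
    i <- seq_len(2 * n_diploid - 1)
    w <- 1 / i^shape
    counts <- sample(i, n_sites, replace = TRUE, prob = w / sum(w))
    counts / (2 * n_diploid)
}

#' Expected per-site heterozygosity under the SFS-weighted frequency law
#'
#' Closed-form mean of `2 p (1 - p)` when `p = i / (2n)` with weights
#' proportional to `1/i^shape`; the analytic oracle for the wild simulator.
#'
#' @param n_diploid number of diploid samples.
#' @param shape SFS weight exponent.
#' @return Expected heterozygosity (numeric scalar).
#' @export
expectedSfsHeterozygosity <- function(n_diploid, shape = 1) {
    i <- seq_len(2 * n_diploid - 1)
    w <- 1 / i^shape
    p <- i / (2 * n_diploid)
    sum(w / sum(w) * 2 * p * (1 - p))
}

#' Simulate the diverse wild panel
#'
#' Sites are placed uniformly along each chromosome; the derived-allele
#' frequency of each site is drawn from the SFS-weighted law and diploid
#' genotypes are sampled binomially per sample. Missing genotypes are
#' injected at `missing_rate`. Deterministic given `config@seed`.
#'
#' @param config A [SweepSimConfig()].
#' @return A [GenotypePanel()] of wild samples; the generating ALT frequency
#'   of each site is kept in `mcols(siteRanges(x))$p_alt_true`.
#' @export
simulateWildPanel <- function(config) {
    validObject(config)
    withSeed(config@seed, {
        per_chrom <- rep(floor(config@n_sites / config@n_chrom),
                         config@n_chrom)
        per_chrom[1] <- per_chrom[1] + config@n_sites - sum(per_chrom)
        nts <- c("A", "C", "G", "T")
        site_list <- list()
        for (ci in seq_len(config@n_chrom)) {
            pos <- sort(sample.int(config@chrom_length_bp, per_chrom[ci]))
            site_list[[ci]] <- GRanges(simChromNames(config)[ci],
                                       IRanges(pos, width = 1))
        }
        sites <- suppressWarnings(do.call(c, site_list))
        seqlevels(sites) <- simChromNames(config)
        seqlengths(sites) <- rep(config@chrom_length_bp, config@n_chrom)
        n <- length(sites)
        ref <- sample(nts, n, replace = TRUE)
        alt <- vapply(ref, function(r) sample(setdiff(nts, r), 1), "")
        p <- sampleSfsFrequencies(n, config@n_wild, config@sfs_shape)
        mcols(sites)$ref <- ref
        mcols(sites)$alt <- CharacterList(as.list(unname(alt)))
        mcols(sites)$p_alt_true <- p
        nw <- config@n_wild
        a1 <- matrix(stats::rbinom(n * nw, 1L, rep(p, nw)), n, nw)
        a2 <- matrix(stats::rbinom(n * nw, 1L, rep(p, nw)), n, nw)
        if (config@missing_rate > 0) {
            miss <- matrix(stats::runif(n * nw) < config@missing_rate, n, nw)
            a1[miss] <- NA_integer_
            a2[miss] <- NA_integer_
        }
        colnames(a1) <- colnames(a2) <- sprintf("wild_%02d", seq_len(nw))
        GenotypePanel(a1, a2, sites, rep("wild", nw))
    })
}

## Founder id per site for one strain on one chromosome: exponential block
## lengths of mean block_bp, uniform founder choice per block.
mosaicFounders <- function(pos, chrom_len, n_founders, block_bp) {
    n_blocks <- max(2L, ceiling(chrom_len / block_bp * 4))
    breaks <- cumsum(stats::rexp(n_blocks, 1 / block_bp))
    while (max(breaks) < chrom_len) {
        breaks <- c(breaks, max(breaks) +
                        cumsum(stats::rexp(n_blocks, 1 / block_bp)))
    }
    founder_per_block <- sample.int(n_founders, length(breaks) + 1L,
                                    replace = TRUE)
    founder_per_block[findInterval(pos, breaks) + 1L]
}

#' Derive the classical-inbred panel from the wild panel
#'
#' Each inbred strain is a fully homozygous mosaic of `n_founders` founder
#' haplotypes (taken from wild samples, missing alleles imputed from the
#' generating frequency). Inside every planted sweep region all strains carry
#' one shared founder haplotype, except that each (site, strain) escapes the
#' sweep with probability `1 - exp(-d / half_width)` where `d` is the
#' distance from the sweep center — a distance-decaying hitchhiking
#' approximation. A small residual heterozygosity (`het_rate`) and missing
#' genotypes (`missing_rate`) are then injected.
#'
#' @param wild A wild [GenotypePanel()] from [simulateWildPanel()].
#' @param config The same [SweepSimConfig()].
#' @return A list with elements `panel` (inbred `GenotypePanel`) and `truth`
#'   (list: `sweeps`, `sweep_genes`, `sweep_windows` — windows containing a
#'   sweep center, `sweep_region_windows` — windows overlapping any sweep
#'   region, `p_alt_wild` — generating frequencies).
#' @export
deriveInbredPanel <- function(wild, config) {
    validObject(config)
    stopifnot(config@n_founders >= 1)
    sites <- siteRanges(wild)
    p_true <- mcols(sites)$p_alt_true
    if (is.null(p_true)) {
        cw <- groupAlleleCounts(wild, "wild")
        p_true <- cw$freq_alt
    }
    withSeed(config@seed + 1L, {
        n <- length(sites)
        ni <- config@n_inbred
        founder_idx <- sample.int(nSamples(wild), config@n_founders)
        founders <- wild@a1[, founder_idx, drop = FALSE]
        fmiss <- is.na(founders)
        if (any(fmiss)) {
            fill <- stats::rbinom(sum(fmiss), 1L,
                                  rep(p_true, config@n_founders)[fmiss])
            founders[fmiss] <- fill
        }
        chroms <- as.character(seqnames(sites))
        pos <- GenomicRanges::start(sites)
        geno <- matrix(NA_integer_, n, ni)
        for (s in seq_len(ni)) {
            for (chrom in unique(chroms)) {
                idx <- which(chroms == chrom)
                fid <- mosaicFounders(pos[idx], config@chrom_length_bp,
                                      config@n_founders, config@block_bp)
                geno[idx, s] <- founders[cbind(idx, fid)]
            }
        }
        sw <- config@sweeps
        for (k in seq_len(nrow(sw))) {
            sweep_founder <- sample.int(config@n_founders, 1L)
            idx <- which(chroms == sw$chrom[k] &
                             abs(pos - sw$center_bp[k]) <= sw$half_width_bp[k])
            if (!length(idx)) {
                warnf("sweep %d (%s:%g) spans no sites; recorded but empty",
                      k, sw$chrom[k], sw$center_bp[k])
                next
            }
            d <- abs(pos[idx] - sw$center_bp[k])
            esc <- 1 - exp(-d / sw$half_width_bp[k])
            keep_mosaic <- matrix(stats::runif(length(idx) * ni), length(idx),
                                  ni) < esc
            swept <- matrix(founders[idx, sweep_founder], length(idx), ni)
            block <- geno[idx, , drop = FALSE]
            block[!keep_mosaic] <- swept[!keep_mosaic]
            geno[idx, ] <- block
        }
        a1 <- a2 <- geno
        if (config@het_rate > 0) {
            het <- matrix(stats::runif(n * ni) < config@het_rate, n, ni)
            a2[het] <- stats::rbinom(sum(het), 1L,
                                     matrix(rep(p_true, ni), n, ni)[het])
        }
        if (config@missing_rate > 0) {
            miss <- matrix(stats::runif(n * ni) < config@missing_rate, n, ni)
            a1[miss] <- NA_integer_
            a2[miss] <- NA_integer_
        }
        colnames(a1) <- colnames(a2) <- sprintf("inbred_%02d", seq_len(ni))
        sites_out <- sites
        mcols(sites_out)$p_alt_true <- NULL
        panel <- GenotypePanel(a1, a2, sites_out,
                               rep("classical_inbred", ni))
        list(panel = panel, truth = simTruth(config, p_true))
    })
}

## The truth table: which windows and genes the generator actually swept.
simTruth <- function(config, p_alt_wild) {
    sw <- config@sweeps
    lens <- stats::setNames(rep(config@chrom_length_bp, config@n_chrom),
                            simChromNames(config))
    win <- makeScanWindows(lens)
    centers <- GRanges(sw$chrom, IRanges(sw$center_bp, width = 1))
    ## sweep regions are 0-based half-open [center - hw, center + hw), here
    ## in their 1-based GRanges form
    regions <- GRanges(sw$chrom,
                       IRanges(sw$center_bp - sw$half_width_bp + 1L,
                               sw$center_bp + sw$half_width_bp))
    genes <- geneModelsFromConfig(config)
    sweep_windows <- which(IRanges::overlapsAny(win, centers))
    ## the swept core: genes overlapping a window that contains a sweep
    ## center (the +/- half_width region is much wider, but only partially
    ## swept under the distance-decaying escape law)
    sweep_genes <- geneIds(genes)[IRanges::overlapsAny(
        geneSpans(genes), win[sweep_windows])]
    list(sweeps = sw,
         sweep_genes = sweep_genes,
         sweep_windows = sweep_windows,
         sweep_region_windows = which(IRanges::overlapsAny(win, regions)),
         windows = win,
         p_alt_wild = p_alt_wild)
}

## ---------------------------------------------------------------------------
## Expression / DE / phenotype / Ct fixtures
## ---------------------------------------------------------------------------

## The 17 tissue categories: six merged groups plus eleven singleton organs.
.category_members <- list(
    "immature brain" = c("CNS E11.5", "CNS E14", "CNS E18"),
    "brain" = c("cerebellum", "cortex", "frontal lobe"),
    "immature liver" = c("liver E14", "liver E14.5", "liver E18"),
    "bowel" = c("duodenum", "small intestine", "large intestine", "colon"),
    "immune system" = c("spleen", "thymus"),
    "fat" = c("genital fat pad", "subcutaneous fat pad"))

.singleton_tissues <- c("liver", "heart", "lung", "kidney", "bladder",
                        "stomach", "testis", "ovary", "placenta", "limb",
                        "mammary gland")

#' Default tissue-to-category mapping
#'
#' Embryonic CNS tissues merge into "immature brain"; adult cerebellum,
#' cortex and frontal lobe into "brain"; embryonic livers into "immature
#' liver"; gut segments into "bowel"; spleen and thymus into "immune
#' system"; the fat pads into "fat". Any other tissue is its own singleton
#' category, which yields the 17 standard categories on the full tissue set.
#'
#' @param tissues character vector of tissue column names.
#' @return Named character vector mapping each tissue to its category.
#' @export
defaultTissueCategories <- function(tissues = defaultTissues()) {
    map <- stats::setNames(tissues, tissues)
    for (cat in names(.category_members)) {
        hit <- tissues %in% .category_members[[cat]]
        map[hit] <- cat
    }
    map
}

#' @rdname defaultTissueCategories
#' @export
defaultTissues <- function()
    c(unlist(.category_members, use.names = FALSE), .singleton_tissues)

#' Tissue columns belonging to the immature brain / brain group
#' @return Character vector of the six brain-related tissue names.
#' @export
brainTissues <- function()
    c(.category_members[["immature brain"]], .category_members[["brain"]])

#' Simulate expression, differential-expression and phenotype fixtures
#'
#' RPKM is log-normal per gene x tissue; a designated gene subset is
#' multiplied by `brain_effect` in the six brain-related tissue columns.
#' DE tables (gene, padj, fpkm) are generated for six tissues with the
#' designated set enriched for DE calls in hippocampus and frontal lobe by
#' `de_enrich`; phenotype flags emulate a mouse-model database with baseline
#' abnormal-behavior rate `pheno_base` enriched among designated genes.
#'
#' @param genes character vector of gene ids.
#' @param designated subset of `genes` to be brain-enriched ("PSG-like").
#' @param brain_effect multiplicative brain expression effect (> 0).
#' @param de_enrich DE-rate enrichment of designated genes in brain tissues.
#' @param de_base baseline DE rate.
#' @param pheno_base baseline abnormal-phenotype rate among modeled genes.
#' @param pheno_enrich fold enrichment of that rate among designated genes.
#' @param seed integer seed.
#' @return List with `rpkm` (matrix genes x tissues), `mapping` (tissue ->
#'   category), `de_tables` (named list of data.frames gene/padj/fpkm),
#'   `phenotypes` (data.frame gene/has_model/abnormal_behavior).
#' @export
simulateExpressionData <- function(genes, designated = character(),
                                   brain_effect = 4, de_enrich = 2.5,
                                   de_base = 0.08, pheno_base = 0.301,
                                   pheno_enrich = 1.7, seed = 1) {
    if (brain_effect <= 0)
        stopf("brain_effect must be positive (got %g)", brain_effect)
    stopifnot(all(designated %in% genes))
    withSeed(seed, {
        tissues <- defaultTissues()
        ng <- length(genes)
        base <- stats::rlnorm(ng, meanlog = 2, sdlog = 1)
        rpkm <- matrix(stats::rlnorm(ng * length(tissues), meanlog = 0,
                                     sdlog = 0.5),
                       ng, length(tissues),
                       dimnames = list(genes, tissues)) * base
        bcols <- brainTissues()
        rpkm[designated, bcols] <- rpkm[designated, bcols] * brain_effect
        de_tissues <- c("hypothalamus", "hippocampus", "frontal_lobe",
                        "heart", "liver", "lung")
        de_tables <- lapply(de_tissues, function(tis) {
            rate <- rep(de_base, ng)
            if (tis %in% c("hippocampus", "frontal_lobe"))
                rate[genes %in% designated] <- min(1, de_base * de_enrich)
            is_de <- stats::runif(ng) < rate
            padj <- ifelse(is_de, stats::runif(ng, 0, 0.05),
                           stats::runif(ng, 0.05, 1))
            data.frame(gene = genes, padj = padj,
                       fpkm = stats::rlnorm(ng, meanlog = 1.5, sdlog = 1))
        })
        names(de_tables) <- de_tissues
        has_model <- stats::runif(ng) < 0.7
        rate <- rep(pheno_base, ng)
        rate[genes %in% designated] <- min(1, pheno_base * pheno_enrich)
        phen <- data.frame(gene = genes, has_model = has_model,
                           abnormal_behavior = has_model &
                               stats::runif(ng) < rate)
        list(rpkm = rpkm, mapping = defaultTissueCategories(tissues),
             de_tables = de_tables, phenotypes = phen)
    })
}

#' Simulate a qPCR Ct table
#'
#' Control and treatment groups, triplicate wells per sample for a target
#' and a reference gene; the treatment group's target is shifted by
#' `effect_log2` cycles (a positive shift means lower expression).
#'
#' @param n_per_group samples per group.
#' @param effect_log2 treatment shift of the target delta-Ct, in cycles.
#' @param ct_ref mean reference-gene Ct.
#' @param dct_base mean control delta-Ct (target minus reference).
#' @param noise_sd per-well Ct standard deviation.
#' @param seed integer seed.
#' @return data.frame with columns sample, group, replicate, ct_target,
#'   ct_reference.
#' @export
simulateCtTable <- function(n_per_group = 10, effect_log2 = 0.41,
                            ct_ref = 18, dct_base = 4, noise_sd = 0.15,
                            seed = 1) {
    withSeed(seed, {
        rows <- list()
        for (grp in c("control", "treatment")) {
            shift <- if (grp == "treatment") effect_log2 else 0
            for (s in seq_len(n_per_group)) {
                id <- sprintf("%s_%02d", grp, s)
                sample_dct <- dct_base + shift + stats::rnorm(1, 0, 0.2)
                for (r in 1:3) {
                    ctr <- ct_ref + stats::rnorm(1, 0, noise_sd)
                    rows[[length(rows) + 1L]] <- data.frame(
                        sample = id, group = grp, replicate = r,
                        ct_target = ctr + sample_dct +
                            stats::rnorm(1, 0, noise_sd),
                        ct_reference = ctr)
                }
            }
        }
        do.call(rbind, rows)
    })
}

#' Write the full fixture bundle to disk
#'
#' Writes the combined genotype panel as VCF 4.2 (GT only) plus a groups
#' TSV, the gene models as BED12, the expression matrix, DE and Ct tables
#' as TSV, and the truth table and configuration as JSON. All files are
#' plain text and round-trip through the package readers.
#'
#' @param dir output directory (created if needed).
#' @param config A [SweepSimConfig()].
#' @param expression_seed,ct_seed seeds for the expression and Ct fixtures.
#' @return Invisibly, a named list of the written file paths.
#' @export
writeFixtureBundle <- function(dir, config = defaultFixtureConfig(),
                               expression_seed = config@seed + 2,
                               ct_seed = config@seed + 3) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    wild <- simulateWildPanel(config)
    inbred <- deriveInbredPanel(wild, config)
    panel <- combinePanels(wild, inbred$panel)
    genes <- geneModelsFromConfig(config)
    expr <- simulateExpressionData(geneIds(genes),
                                   designated = inbred$truth$sweep_genes,
                                   seed = expression_seed)
    ct <- simulateCtTable(seed = ct_seed)
    paths <- list(
        vcf = file.path(dir, "genotypes.vcf"),
        groups = file.path(dir, "groups.tsv"),
        genes = file.path(dir, "genes.bed"),
        rpkm = file.path(dir, "expression.tsv"),
        ct = file.path(dir, "ct.tsv"),
        truth = file.path(dir, "truth.json"),
        config = file.path(dir, "config.json"))
    writeGenotypeVcf(panel, paths$vcf)
    grp <- data.frame(sample = sampleNames(panel),
                      group = as.character(sampleGroups(panel)))
    utils::write.table(grp, paths$groups, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeGeneModelsBed(genes, paths$genes)
    rpkm_df <- data.frame(gene = rownames(expr$rpkm), expr$rpkm,
                          check.names = FALSE)
    utils::write.table(rpkm_df, paths$rpkm, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    for (tis in names(expr$de_tables)) {
        p <- file.path(dir, sprintf("de_%s.tsv", tis))
        utils::write.table(expr$de_tables[[tis]], p, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        paths[[paste0("de_", tis)]] <- p
    }
    utils::write.table(ct, paths$ct, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    truth <- inbred$truth
    truth$windows <- data.frame(
        chrom = as.character(seqnames(truth$windows)),
        start0 = GenomicRanges::start(truth$windows) - 1L,
        end0 = GenomicRanges::end(truth$windows),
        trailing = mcols(truth$windows)$trailing)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
    cfg <- attributes(config)
    cfg <- lapply(slotNames(config), function(s) slot(config, s))
    names(cfg) <- slotNames(config)
    jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    invisible(paths)
}
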