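## Relative quantification of qPCR expression: 2^-ddCt fold changes and
## the isoform a/b ratio index.

#' 2^-ddCt fold change from a Ct table
#'
#' Replicate wells are averaged in Ct space per sample first; then
#' `dCt = ct_target - ct_reference`, `ddCt = dCt - mean(dCt of control
#' group)`, `fold = 2^-ddCt`. Centering on the arithmetic control mean in
#' dCt space makes the geometric mean of the control folds exactly 1.
#'
#' @param ct data.frame with columns `sample`, `group`, `ct_target`,
#'   `ct_reference` (one row per well; replicate rows allowed).
#' @param control the control group label (default `"control"`).
#' @return data.frame per sample: `sample`, `group`, `dct`, `ddct`,
#'   `fold`; per-group mean folds attached as attribute `"group_means"`.
#' @export
ddctFold <- function(ct, control = "control") {
    need <- c("sample", "group", "ct_target", "ct_reference")
    if (!all(need %in% names(ct)))
        stopf("ct table needs columns %s", paste(need, collapse = ", "))
    drop <- is.na(ct$ct_reference) | is.na(ct$ct_target)
    if (any(drop)) {
        warnf("%d well(s) with missing Ct excluded", sum(drop))
        ct <- ct[!drop, ]
    }
    cts <- c(ct$ct_target, ct$ct_reference)
    if (any(cts <= 0 | cts >= 45))
        stopf("Ct values must lie in (0, 45)")
    agg <- stats::aggregate(ct[, c("ct_target", "ct_reference")],
                            by = list(sample = ct$sample, group = ct$group),
                            FUN = mean)
    if (!any(agg$group == control))
        stopf("no sample in control group '%s'", control)
    dct <- agg$ct_target - agg$ct_reference
    ddct <- dct - mean(dct[agg$group == control])
    out <- data.frame(sample = agg$sample, group = agg$group, dct = dct,
                      ddct = ddct, fold = 2^(-ddct))
    out <- out[order(out$group, out$sample), ]
    rownames(out) <- NULL
    attr(out, "group_means") <- tapply(out$fold, out$group, mean)
    out
}

#' Isoform a/b ratio index
#'
#' Same arithmetic as [ddctFold()] with isoform a as the measured gene and
#' isoform b as the reference: the per-sample index is the a/b abundance
#' ratio relative to the control-group mean.
#'
#' @param ct data.frame with columns `sample`, `group`, `ct_isoform_a`,
#'   `ct_isoform_b`.
#' @param control the control group label.
#' @return As [ddctFold()], with the fold column being the ratio index.
#' @export
isoformRatio <- function(ct, control = "control") {
    need <- c("sample", "group", "ct_isoform_a", "ct_isoform_b")
    if (!all(need %in% names(ct)))
        stopf("ct table needs columns %s", paste(need, collapse = ", "))
    ct2 <- data.frame(sample = ct$sample, group = ct$group,
                      ct_target = ct$ct_isoform_a,
                      ct_reference = ct$ct_isoform_b)
    ddctFold(ct2, control = control)
}
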