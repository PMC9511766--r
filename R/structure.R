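## Distance-based clustering check: allele-sharing distances and a
## classical Saitou-Nei neighbor-joining tree, used to verify that the
## classical inbred panel separates from the wild group.

#' Pairwise allele-sharing distance matrix
#'
#' For two diploid genotypes at a bi-allelic site the shared-allele
#' fraction is 1 (identical), 0.5 (one allele in common, e.g. hom vs het)
#' or 0 (opposite homozygotes); the distance between two samples is the
#' mean of `1 - shared` over sites where both are called.
#'
#' @param panel A bi-allelic [GenotypePanel()] (apply [filterSites()] first).
#' @return A symmetric numeric matrix with zero diagonal, sample names as
#'   dimnames.
#' @export
pairwiseDistance <- function(panel) {
    if (nSamples(panel) < 2) stopf("need at least 2 samples")
    g <- panel@a1 + panel@a2   # dosage 0/1/2, NA = missing
    n <- ncol(g)
    ids <- colnames(g)
    d <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
            ok <- !is.na(g[, i]) & !is.na(g[, j])
            if (!any(ok))
                stopf("samples %s and %s share no co-called sites",
                      ids[i], ids[j])
            d[i, j] <- d[j, i] <- mean(abs(g[ok, i] - g[ok, j])) / 2
        }
    }
    d
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Classical agglomeration by Q-matrix minimisation with the standard
#' branch-length formulas. Ties in the Q minimisation are broken by the
#' smallest (i, j) index pair, making the output deterministic; negative
#' branch lengths are clamped to 0 with a warning.
#'
#' @param d symmetric distance matrix with dimnames (>= 3 taxa).
#' @return A list of class `nj_tree`: `newick` (tree text with branch
#'   lengths, unrooted with a trifurcating root node) and `clades` (list of
#'   tip-label sets, one per internal node of the rooted representation).
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' neighborJoining(d)$newick  # (A:1,B:1,C:3);
#' @export
neighborJoining <- function(d) {
    if (nrow(d) < 3) stopf("neighbor joining needs >= 3 taxa")
    stopifnot(isSymmetric(unname(d)), all(is.finite(d)))
    labels <- rownames(d)
    nwk <- labels
    tips <- as.list(labels)
    clades <- list()
    clamped <- 0L
    clamp <- function(x) {
        if (x < 0) clamped <<- clamped + 1L
        max(x, 0)
    }
    D <- unname(d)
    while (nrow(D) > 3) {
        r <- nrow(D)
        R <- rowSums(D)
        Q <- (r - 2) * D - outer(R, R, "+")
        diag(Q) <- Inf
        ## smallest (i, j), i < j, among the minima — deterministic tie rule
        hits <- which(Q == min(Q), arr.ind = TRUE)
        hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
        hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
        i <- hits[1, 1]; j <- hits[1, 2]
        bi <- clamp(D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2)))
        bj <- clamp(D[i, j] - D[i, j] / 2 - (R[i] - R[j]) / (2 * (r - 2)))
        new_nwk <- sprintf("(%s:%.10g,%s:%.10g)", nwk[i], bi, nwk[j], bj)
        new_tips <- c(tips[[i]], tips[[j]])
        clades[[length(clades) + 1L]] <- new_tips
        dk <- (D[i, -c(i, j)] + D[j, -c(i, j)] - D[i, j]) / 2
        D <- rbind(cbind(D[-c(i, j), -c(i, j), drop = FALSE], dk),
                   c(dk, 0))
        nwk <- c(nwk[-c(i, j)], new_nwk)
        tips <- c(tips[-c(i, j)], list(new_tips))
    }
    b1 <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
    b2 <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
    b3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
    newick <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                      nwk[1], b1, nwk[2], b2, nwk[3], b3)
    if (clamped > 0)
        warnf("%d negative branch length(s) clamped to 0", clamped)
    structure(list(newick = newick, clades = clades, tips = labels),
              class = "nj_tree")
}

#' @export
print.nj_tree <- function(x, ...) {
    cat("neighbor-joining tree over", length(x$tips), "taxa\n")
    if (nchar(x$newick) <= 200) cat(x$newick, "\n")
    invisible(x)
}

#' Does a tip set form a clade of the (unrooted) NJ tree?
#'
#' A group is monophyletic on an unrooted tree iff some edge bipartition
#' separates exactly the group from the rest; in the rooted representation
#' returned by [neighborJoining()] that means the group or its complement
#' equals some internal node's tip set (or the group is a single tip or
#' all-but-one tips).
#'
#' @param tree an `nj_tree` from [neighborJoining()].
#' @param group character vector of tip labels.
#' @return Logical scalar.
#' @export
isGroupMonophyletic <- function(tree, group) {
    group <- sort(unique(group))
    stopifnot(all(group %in% tree$tips))
    if (length(group) <= 1L || length(group) >= length(tree$tips) - 1L)
        return(TRUE)
    comp <- sort(setdiff(tree$tips, group))
    for (cl in tree$clades) {
        s <- sort(cl)
        if (identical(s, group) || identical(s, comp)) return(TRUE)
    }
    FALSE
}
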