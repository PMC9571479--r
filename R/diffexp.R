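#' Two-sided Wilcoxon Mann-Whitney rank-sum p-value
#'
#' Thin wrapper around [stats::wilcox.test()]: the exact permutation
#' distribution is used when the combined sample size is small
#' (`n1 + n2 <= exactMax`) and there are no ties; otherwise the normal
#' approximation with tie and continuity correction. Degenerate input where
#' all values are identical returns p = 1.
#'
#' @param x,y numeric group samples (each of size >= 2).
#' @param exactMax maximum combined size for the exact distribution.
#' @return two-sided p-value.
#' @export
wilcoxonRankSum <- function(x, y, exactMax = 20L) {
    stopifnot(length(x) >= 2L, length(y) >= 2L)
    if (length(unique(c(x, y))) == 1L) return(1)
    ties <- anyDuplicated(c(x, y)) > 0L
    useExact <- !ties && (length(x) + length(y)) <= exactMax
    suppressWarnings(
        stats::wilcox.test(x, y, alternative = "two.sided",
                           exact = useExact, correct = TRUE)$p.value)
}

#' Delta-delta-Ct differential expression between patients and controls
#'
#' Per assay, the group Ct means are compared:
#' `deltaDeltaCt = mean Ct(patients) - mean Ct(controls)` and
#' `foldChange = 2^-deltaDeltaCt` (lower Ct = higher expression). Assays with
#' fold change at least `fcMin` (up) or at most `1/fcMin` (down) and a
#' Wilcoxon rank-sum p-value below `alpha` are called differentially
#' expressed. Benjamini-Hochberg q-values are reported alongside but do not
#' enter the default call, mirroring standard practice for raw-p filtered
#' qPCR panels; set `useQValue = TRUE` to filter on q instead.
#'
#' @param nm a [NormalizedCtSet-class] (or imputed [CtSet-class]) whose
#'   `colData` group labels contain both classes with >= 2 samples each.
#' @param fcMin minimal fold change (and reciprocal) for a regulation call.
#' @param alpha significance cutoff.
#' @param useQValue filter on BH-adjusted q-values instead of raw p.
#' @return a `data.frame` of class `DiffExprTable` with columns `assay`,
#'   `meanCtPatient`, `meanCtControl`, `deltaDeltaCt`, `foldChange`,
#'   `pValue`, `qValue`, `regulation` (`up`/`down`/`none`), ordered by
#'   p-value.
#' @export
differentialExpression <- function(nm, fcMin = 2, alpha = 0.05,
                                   useQValue = FALSE) {
    ct <- ctValues(nm)
    grp <- sampleGroups(nm)
    pat <- which(grp == "patient")
    ctl <- which(grp == "control")
    if (length(pat) < 2L || length(ctl) < 2L)
        stop("both groups need >= 2 samples (patients: ", length(pat),
             ", controls: ", length(ctl), ")")
    meanPat <- rowMeans(ct[, pat, drop = FALSE])
    meanCtl <- rowMeans(ct[, ctl, drop = FALSE])
    ddct <- meanPat - meanCtl
    fc <- 2^(-ddct)
    p <- vapply(seq_len(nrow(ct)), function(i)
        wilcoxonRankSum(ct[i, pat], ct[i, ctl]), numeric(1L))
    q <- stats::p.adjust(p, method = "BH")
    sig <- if (useQValue) q < alpha else p < alpha
    regulation <- ifelse(sig & fc >= fcMin, "up",
                         ifelse(sig & fc <= 1 / fcMin, "down", "none"))
    out <- data.frame(assay = rownames(ct), meanCtPatient = meanPat,
                      meanCtControl = meanCtl, deltaDeltaCt = ddct,
                      foldChange = fc, pValue = p, qValue = q,
                      regulation = regulation, row.names = NULL,
                      stringsAsFactors = FALSE)
    out <- out[order(out$pValue), ]
    rownames(out) <- NULL
    class(out) <- c("DiffExprTable", "data.frame")
    out
}

#' Differentially expressed assay names from a DiffExprTable
#'
#' @param tab a [differentialExpression()] result.
#' @param direction `"both"`, `"up"` or `"down"`.
#' @export
deAssays <- function(tab, direction = c("both", "up", "down")) {
    direction <- match.arg(direction)
    keep <- if (direction == "both") tab$regulation != "none"
            else tab$regulation == direction
    tab$assay[keep]
}

#' Hierarchical clustering of samples on a set of assays
#'
#' Agglomerative clustering of samples (columns), by default on
#' 1 - Pearson correlation distance with average linkage, cut into `k` flat
#' clusters. Typically run on the differentially expressed assay set.
#'
#' @param nm a [NormalizedCtSet-class] or [CtSet-class].
#' @param assays character, assay subset (nonempty); default all assays.
#' @param k number of flat clusters.
#' @param distance `"correlation"` (1 - Pearson) or `"euclidean"`.
#' @param linkage agglomeration method for [stats::hclust()].
#' @return a list of class `ClusteringResult`: `tree` (hclust), `leafOrder`,
#'   `clusters` (named integer vector from [stats::cutree()]).
#' @export
hierarchicalClustering <- function(nm, assays = NULL, k = 2L,
                                   distance = c("correlation", "euclidean"),
                                   linkage = "average") {
    distance <- match.arg(distance)
    ct <- ctValues(nm)
    if (!is.null(assays)) {
        stopifnot(length(assays) > 0L)
        missing <- setdiff(assays, rownames(ct))
        if (length(missing))
            stop("assays absent: ", paste(missing, collapse = ", "))
        ct <- ct[assays, , drop = FALSE]
    }
    if (k > ncol(ct)) stop("k (", k, ") exceeds sample count (", ncol(ct), ")")
    d <- if (distance == "correlation")
        stats::as.dist(1 - stats::cor(ct))
    else stats::dist(t(ct))
    tree <- stats::hclust(d, method = linkage)
    res <- list(tree = tree, leafOrder = tree$labels[tree$order],
                clusters = stats::cutree(tree, k = k),
                distance = distance, linkage = linkage, k = k)
    class(res) <- "ClusteringResult"
    res
}

#' @export
print.ClusteringResult <- function(x, ...) {
    cat("ClusteringResult:", length(x$clusters), "samples,", x$k,
        "clusters (", x$distance, "distance,", x$linkage, "linkage)\n")
    print(table(x$clusters))
    invisible(x)
}
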