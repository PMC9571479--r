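#' Impute Undetermined reactions at a fixed Ct
#'
#' Reactions that never crossed the detection threshold carry no finite Ct;
#' the standard convention for array cards is to assign them the maximum
#' cycle number of the run (Ct = 40). The operation is idempotent and leaves
#' numeric entries untouched.
#'
#' @param x a [CtSet-class].
#' @param value Ct assigned to censored entries (default 40).
#' @return a [CtSet-class] with no censored entries; the number of imputed
#'   cells is recorded in `metadata(x)$imputed`.
#' @export
imputeUndetermined <- function(x, value = 40) {
    ct <- ctValues(x)
    n <- sum(is.na(ct))
    ct[is.na(ct)] <- value
    assay(x, "ct") <- ct
    metadata(x)$imputed <- n
    metadata(x)$imputeValue <- value
    x
}

#' Filter assays to the informative set
#'
#' An assay is informative when its Ct values lie at or below `ctMax`
#' (default 33; higher Ct means the species is effectively not expressed).
#' Policy `"all"` requires Ct <= ctMax in every sample ("detected in all
#' samples"); policy `"fraction"` requires Ct <= ctMax in at least a fraction
#' `q` of samples overall, or within at least one group when `perGroup` is
#' `TRUE`.
#'
#' @param x an imputed [CtSet-class] (no censored entries).
#' @param ctMax informativeness cutoff in cycles; the boundary value is
#'   informative (`Ct <= ctMax`).
#' @param policy `"all"` or `"fraction"`.
#' @param q minimum detected fraction for policy `"fraction"`.
#' @param perGroup with policy `"fraction"`, accept an assay detected in at
#'   least fraction `q` of at least one group.
#' @return a filtered [CtSet-class]; `metadata()$filter` records kept/dropped
#'   counts and the policy.
#' @export
filterInformative <- function(x, ctMax = 33, policy = c("all", "fraction"),
                              q = 0.75, perGroup = TRUE) {
    policy <- match.arg(policy)
    ct <- ctValues(x)
    if (anyNA(ct))
        stop("matrix contains Undetermined entries; run imputeUndetermined()",
             " first")
    det <- ct <= ctMax
    keep <- if (policy == "all") {
        rowSums(det) == ncol(ct)
    } else {
        overall <- rowMeans(det) >= q
        if (perGroup && !all(is.na(sampleGroups(x)))) {
            grp <- sampleGroups(x)
            byGroup <- vapply(levels(grp), function(g) {
                cols <- which(grp == g)
                if (!length(cols)) rep(FALSE, nrow(ct))
                else rowMeans(det[, cols, drop = FALSE]) >= q
            }, logical(nrow(ct)))
            overall | apply(byGroup, 1L, any)
        } else overall
    }
    if (!any(keep))
        warning("no assay passes the informativeness filter")
    out <- x[keep, ]
    metadata(out)$filter <- list(policy = policy, ctMax = ctMax, q = q,
                                 kept = sum(keep),
                                 dropped = sum(!keep),
                                 droppedAssays = rownames(x)[!keep])
    out
}

#' Hemolysis quality control from the miR-23a / miR-451 Ct difference
#'
#' miR-451 is strongly enriched in red blood cells while miR-23a is stable in
#' plasma, so `delta = Ct(miR-23a) - Ct(miR-451)` grows when a sample is
#' hemolyzed. Samples with `delta > deltaMax` fail QC; values in
#' `(deltaWarn, deltaMax]` are flagged as warnings but pass. A censored
#' marker Ct makes the delta undefined and the sample `"inconclusive"`.
#'
#' Run on the raw (pre-imputation) matrix so censored markers are detected.
#'
#' @param x a [CtSet-class].
#' @param markerA,markerB the plasma-stable and red-blood-cell marker assay
#'   names.
#' @param deltaMax failure threshold in cycles.
#' @param deltaWarn warning threshold in cycles.
#' @return `x` with `hemolysis_delta`, `hemolysis_flag`
#'   (`pass`/`warn`/`fail`/`inconclusive`) and `qc_pass` filled in
#'   `colData`; a per-sample summary is stored in `metadata()$hemolysisQc`.
#' @export
hemolysisQc <- function(x, markerA = "miR-23a", markerB = "miR-451",
                        deltaMax = 7, deltaWarn = 5) {
    if (!all(c(markerA, markerB) %in% rownames(x))) {
        warning("hemolysis markers not found (", markerA, ", ", markerB,
                "); QC skipped")
        return(x)
    }
    ct <- ctValues(x)
    delta <- ct[markerA, ] - ct[markerB, ]
    flag <- ifelse(is.na(delta), "inconclusive",
                   ifelse(delta > deltaMax, "fail",
                          ifelse(delta > deltaWarn, "warn", "pass")))
    colData(x)$hemolysis_delta <- as.numeric(delta)
    colData(x)$hemolysis_flag <- flag
    colData(x)$qc_pass <- flag != "fail"
    metadata(x)$hemolysisQc <- data.frame(
        sample_id = colnames(x), delta = as.numeric(delta), flag = flag,
        qc_pass = flag != "fail", row.names = NULL)
    if (any(flag == "fail"))
        warning(sum(flag == "fail"), " sample(s) fail hemolysis QC: ",
                paste(colnames(x)[flag == "fail"], collapse = ", "))
    x
}

#' Drop samples that failed quality control
#'
#' @param x a [CtSet-class] with `qc_pass` filled (see [hemolysisQc()]).
#' @return `x` restricted to passing samples.
#' @export
dropQcFailures <- function(x) {
    x[, colData(x)$qc_pass %in% TRUE]
}

#' Assemble a QC report
#'
#' Collects the per-sample hemolysis table, the informativeness filter
#' summary and the imputation count accumulated in `metadata()` along the
#' preprocessing chain.
#'
#' @param x a preprocessed [CtSet-class].
#' @return a list of class `QcReport`.
#' @export
qcReport <- function(x) {
    rep <- list(nAssays = nrow(x), nSamples = ncol(x),
                imputed = metadata(x)$imputed %||% NA_integer_,
                filter = metadata(x)$filter,
                hemolysis = metadata(x)$hemolysisQc)
    class(rep) <- "QcReport"
    rep
}

#' @export
print.QcReport <- function(x, ...) {
    cat("QcReport:", x$nAssays, "assays x", x$nSamples, "samples\n")
    cat("  imputed Undetermined entries:", x$imputed, "\n")
    if (!is.null(x$filter))
        cat("  informative filter (", x$filter$policy, "): kept ",
            x$filter$kept, ", dropped ", x$filter$dropped, "\n", sep = "")
    if (!is.null(x$hemolysis))
        cat("  hemolysis flags:",
            paste(names(table(x$hemolysis$flag)), table(x$hemolysis$flag),
                  sep = "=", collapse = ", "), "\n")
    invisible(x)
}
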