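#' Leave-one-out cross-validated class probabilities
#'
#' For each sample, refits an unpenalized logistic model on the remaining
#' n - 1 samples using the fixed signature assays (feature selection is not
#' redone inside the loop) and records the held-out sample's predicted
#' patient probability. Folds with perfect separation fall back to a
#' ridge-stabilized fit with a tiny penalty and are flagged.
#'
#' @param X numeric matrix, samples x assays.
#' @param y group labels (patient = positive class).
#' @param assays character, the signature assays to use.
#' @return named numeric vector of held-out probabilities, with attribute
#'   `"ridged"` (logical per fold).
#' @export
loocvProbabilities <- function(X, y, assays) {
    X <- as.matrix(X)
    y <- asBinaryLabels(y)
    n <- nrow(X)
    if (n < 4L) stop("LOOCV needs n >= 4")
    missing <- setdiff(assays, colnames(X))
    if (length(missing))
        stop("assays missing from X: ", paste(missing, collapse = ", "))
    Xs <- X[, assays, drop = FALSE]
    probs <- numeric(n)
    ridged <- logical(n)
    for (i in seq_len(n)) {
        ytr <- y[-i]
        if (length(unique(ytr)) < 2L)
            stop("training fold ", i, " lacks a class")
        fit <- stableLogisticFit(Xs[-i, , drop = FALSE], ytr)
        ridged[i] <- fit$ridged
        probs[i] <- predictLogistic(fit, Xs[i, , drop = FALSE])
    }
    names(probs) <- rownames(X)
    attr(probs, "ridged") <- ridged
    probs
}

#' ROC curve, AUC and DeLong confidence interval
#'
#' Operating points at every unique probability threshold, the trapezoidal
#' AUC (identical to the Mann-Whitney statistic with half credit for ties),
#' and a 95% CI by DeLong's variance method, all via the pROC package.
#'
#' @param probs predicted patient probabilities.
#' @param y labels (both classes required).
#' @return a list of class `RocCurve`: `points` (threshold, fpr, tpr),
#'   `auc`, `ci` (length 2).
#' @export
rocCurve <- function(probs, y) {
    y <- asBinaryLabels(y)
    if (length(unique(y)) < 2L) stop("both classes must be present")
    r <- pROC::roc(response = factor(y, levels = c(0, 1)),
                   predictor = as.numeric(probs),
                   levels = c("0", "1"), direction = "<", quiet = TRUE)
    auc <- as.numeric(pROC::auc(r))
    ci <- tryCatch({
        v <- suppressWarnings(pROC::ci.auc(r, method = "delong"))
        c(v[1L], v[3L])
    }, error = function(e) c(auc, auc))
    pts <- data.frame(threshold = r$thresholds,
                      fpr = 1 - r$specificities, tpr = r$sensitivities)
    pts <- pts[order(pts$fpr, pts$tpr), ]
    rownames(pts) <- NULL
    structure(list(points = pts, auc = auc, ci = ci, ciMethod = "delong"),
              class = "RocCurve")
}

# area under the precision-recall curve by trapezoidal integration over
# recall, with operating points at unique thresholds (ties pooled)
prPoints <- function(probs, y) {
    u <- sort(unique(probs), decreasing = TRUE)
    P <- sum(y == 1)
    tp <- vapply(u, function(t) sum(probs >= t & y == 1), numeric(1L))
    pred <- vapply(u, function(t) sum(probs >= t), numeric(1L))
    data.frame(threshold = u, recall = tp / P, precision = tp / pred)
}

prAucFrom <- function(pts) {
    rec <- c(0, pts$recall)
    prec <- c(pts$precision[1L], pts$precision)
    sum(diff(rec) * (utils::head(prec, -1L) + utils::tail(prec, -1L)) / 2)
}

#' Precision-recall curve, AUC and bootstrap confidence interval
#'
#' Precision-recall operating points at every unique threshold, area by
#' trapezoidal integration over recall (the curve is anchored at recall 0
#' with the precision of the most stringent threshold), and a 95% CI by
#' stratified bootstrap (resampling within each class).
#'
#' @param probs predicted patient probabilities.
#' @param y labels (at least one positive required).
#' @param bootReps bootstrap replicates for the CI (default 2000; 0 skips).
#' @param seed RNG seed for the bootstrap.
#' @return a list of class `PrCurve`: `points` (threshold, recall,
#'   precision), `auc`, `ci`.
#' @export
prCurve <- function(probs, y, bootReps = 2000L, seed = 1L) {
    y <- asBinaryLabels(y)
    if (sum(y == 1) == 0L) stop("at least one positive sample required")
    probs <- as.numeric(probs)
    pts <- prPoints(probs, y)
    auc <- prAucFrom(pts)
    ci <- c(NA_real_, NA_real_)
    if (bootReps > 0L) {
        pos <- which(y == 1)
        neg <- which(y == 0)
        ci <- withSeed(seed, {
            reps <- vapply(seq_len(bootReps), function(b) {
                idx <- c(sample(pos, length(pos), replace = TRUE),
                         sample(neg, length(neg), replace = TRUE))
                prAucFrom(prPoints(probs[idx], y[idx]))
            }, numeric(1L))
            as.numeric(stats::quantile(reps, c(0.025, 0.975)))
        })
    }
    structure(list(points = pts, auc = auc, ci = ci,
                   ciMethod = "stratified bootstrap", bootReps = bootReps),
              class = "PrCurve")
}

#' Select a decision threshold by the FPR-minimization protocol
#'
#' Candidate thresholds are the midpoints between adjacent unique
#' probabilities plus minus/plus infinity; prediction is positive at
#' `prob >= threshold`. The default rule first maximizes the true positive
#' rate, then minimizes the false positive rate among TPR-maximal
#' candidates, then prefers the larger threshold; on separable data this
#' gives TPR 1 at FPR 0. The literal rule (`"literal_min_fpr"`) minimizes
#' FPR outright (degenerate: it always admits the all-negative classifier)
#' and is provided for comparison.
#'
#' @param probs predicted probabilities.
#' @param y labels.
#' @param rule `"max_tpr_min_fpr"` (default) or `"literal_min_fpr"`.
#' @return the selected threshold (may be infinite).
#' @export
selectThresholdMinFpr <- function(probs, y,
                                  rule = c("max_tpr_min_fpr",
                                           "literal_min_fpr")) {
    rule <- match.arg(rule)
    y <- asBinaryLabels(y)
    probs <- as.numeric(probs)
    u <- sort(unique(probs))
    cand <- c(-Inf, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2, Inf)
    P <- sum(y == 1)
    N <- sum(y == 0)
    tpr <- vapply(cand, function(t) sum(probs >= t & y == 1) / max(P, 1L),
                  numeric(1L))
    fpr <- vapply(cand, function(t) sum(probs >= t & y == 0) / max(N, 1L),
                  numeric(1L))
    ord <- if (rule == "max_tpr_min_fpr")
        order(-tpr, fpr, -rank(cand))
    else order(fpr, -tpr, -rank(cand))
    cand[ord[1L]]
}

#' Confusion-matrix metrics at a threshold
#'
#' Predicts patient for `prob >= threshold` and reports accuracy,
#' sensitivity (TPR), specificity (TNR), positive prediction rate
#' (precision) and negative prediction rate (NPV). Rates with a zero
#' denominator are returned as `NA` and named in `undefined` rather than
#' propagated silently.
#'
#' @param probs predicted probabilities.
#' @param y labels.
#' @param threshold decision threshold.
#' @return a list of class `ConfusionMetrics`: `accuracy`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `counts` (tp, fp, tn, fn), `threshold`,
#'   `undefined`.
#' @export
confusionMetrics <- function(probs, y, threshold) {
    y <- asBinaryLabels(y)
    pred <- as.numeric(probs) >= threshold
    tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
    tn <- sum(!pred & y == 0); fn <- sum(!pred & y == 1)
    rate <- function(num, den) if (den == 0L) NA_real_ else num / den
    out <- list(accuracy = (tp + tn) / length(y),
                sensitivity = rate(tp, tp + fn),
                specificity = rate(tn, tn + fp),
                ppv = rate(tp, tp + fp),
                npv = rate(tn, tn + fn),
                counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
                threshold = threshold)
    out$undefined <- names(which(vapply(
        out[c("sensitivity", "specificity", "ppv", "npv")], is.na,
        logical(1L))))
    class(out) <- "ConfusionMetrics"
    out
}

#' @export
print.ConfusionMetrics <- function(x, ...) {
    fmt <- function(v) ifelse(is.na(v), "undefined", sprintf("%.3f", v))
    cat(sprintf(paste0("ConfusionMetrics @ %.3g: accuracy %s, sensitivity ",
                       "%s, specificity %s, PPV %s, NPV %s\n"), x$threshold,
                fmt(x$accuracy), fmt(x$sensitivity), fmt(x$specificity),
                fmt(x$ppv), fmt(x$npv)))
    invisible(x)
}

#' Assemble a full evaluation report from probabilities and labels
#'
#' Computes the ROC and PR curves, selects (or reuses) a decision threshold
#' and derives the confusion metrics.
#'
#' @param probs predicted probabilities (e.g. from [loocvProbabilities()] or
#'   [applySignature()]).
#' @param y labels.
#' @param threshold `NULL` to select by [selectThresholdMinFpr()], or a
#'   fixed value.
#' @param bootReps,seed passed to [prCurve()].
#' @return a list of class `EvalReport`: `probabilities`, `roc`, `pr`,
#'   `threshold`, `thresholdSource`, `metrics`.
#' @export
evalReport <- function(probs, y, threshold = NULL, bootReps = 2000L,
                       seed = 1L) {
    y <- asBinaryLabels(y)
    src <- if (is.null(threshold)) "min_fpr_protocol" else "fixed"
    if (is.null(threshold)) threshold <- selectThresholdMinFpr(probs, y)
    structure(list(probabilities = probs,
                   roc = rocCurve(probs, y),
                   pr = prCurve(probs, y, bootReps = bootReps, seed = seed),
                   threshold = threshold, thresholdSource = src,
                   metrics = confusionMetrics(probs, y, threshold)),
              class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
    cat(sprintf("EvalReport: AUC-ROC %.3f (%.3f, %.3f), AUC-PR %.3f\n",
                x$roc$auc, x$roc$ci[1L], x$roc$ci[2L], x$pr$auc))
    print(x$metrics)
    invisible(x)
}

#' Evaluate a fixed signature model on a new cohort
#'
#' Applies the trained model to new samples and reports the full metric
#' block. With `recalibrateThreshold = TRUE` (mirroring the use of an
#' ad hoc, cohort-specific threshold for cohorts whose composition differs
#' from the training cohort) the FPR-minimizing threshold is re-selected on
#' the new cohort; metrics at the model's stored threshold are reported
#' alongside when available.
#'
#' @param model a [SignatureModel-class].
#' @param X numeric matrix, samples x assays of the new cohort.
#' @param y labels of the new cohort.
#' @param recalibrateThreshold logical.
#' @param bootReps,seed passed to [prCurve()].
#' @return an `EvalReport`, with an extra `metricsAtModelThreshold` entry
#'   when both thresholds are available.
#' @export
evaluateOnCohort <- function(model, X, y, recalibrateThreshold = TRUE,
                             bootReps = 2000L, seed = 1L) {
    probs <- applySignature(model, X)
    y <- asBinaryLabels(y)
    thr <- if (recalibrateThreshold) NULL else {
        if (is.na(model@threshold))
            stop("model has no stored threshold; use recalibrateThreshold")
        model@threshold
    }
    rep <- evalReport(probs, y, threshold = thr, bootReps = bootReps,
                      seed = seed)
    if (recalibrateThreshold && !is.na(model@threshold))
        rep$metricsAtModelThreshold <-
            confusionMetrics(probs, y, model@threshold)
    rep
}
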