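asBinaryLabels <- function(y) {
    if (is.factor(y) || is.character(y)) {
        y <- as.character(y)
        bad <- setdiff(unique(y), c("patient", "control"))
        if (length(bad)) stop("unknown group labels: ",
                              paste(bad, collapse = ", "))
        as.numeric(y == "patient")
    } else as.numeric(y)
}

#' Fit an L1-penalized logistic path over candidate assays
#'
#' Maximizes the L1-penalized binomial log-likelihood along a log-spaced
#' penalty grid from lambda_max (the smallest penalty with all coefficients
#' zero) downward, via [glmnet::glmnet()] with internal feature
#' standardization. Candidate assays are typically the differentially
#' expressed set; the positive class is `patient`.
#'
#' @param X numeric matrix, samples x candidate assays (Ct values), with
#'   column names.
#' @param y group labels: `"patient"`/`"control"`, a factor, or 0/1 with
#'   patient = 1. Both classes must be present.
#' @param nLambda grid length.
#' @return a `LassoPath` list: `fit` (glmnet object), `X`, `y` (0/1),
#'   `lambda`, `dropped` (constant assays removed).
#' @export
fitLassoPath <- function(X, y, nLambda = 100L) {
    X <- as.matrix(X)
    if (is.null(colnames(X))) stop("X needs assay column names")
    y <- asBinaryLabels(y)
    if (length(unique(y)) < 2L) stop("both classes must be present in y")
    sds <- apply(X, 2L, stats::sd)
    dropped <- colnames(X)[sds == 0]
    if (length(dropped)) {
        warning("constant assay(s) dropped: ",
                paste(dropped, collapse = ", "))
        X <- X[, sds > 0, drop = FALSE]
    }
    if (ncol(X) < 2L)
        stop("need >= 2 non-constant candidate assays, got ", ncol(X))
    # do.call stores evaluated arguments in the call, so downstream
    # predict(..., exact = TRUE) can refit without this frame
    fit <- do.call(glmnet::glmnet,
                   list(x = X, y = y, family = "binomial",
                        nlambda = as.integer(nLambda), standardize = TRUE))
    structure(list(fit = fit, X = X, y = y, lambda = fit$lambda,
                   dropped = dropped),
              class = "LassoPath")
}

#' @export
print.LassoPath <- function(x, ...) {
    cat("LassoPath:", ncol(x$X), "candidate assays,", length(x$lambda),
        "penalties in [", format(min(x$lambda), digits = 3), ",",
        format(max(x$lambda), digits = 3), "]\n")
    invisible(x)
}

# the one-standard-error rule on a CV error curve
lambda1seRule <- function(lambda, cvm, cvsd) {
    i <- which.min(cvm)
    within <- cvm <= cvm[i] + cvsd[i]
    list(lambdaMin = lambda[i], lambda1se = max(lambda[within]))
}

#' Cross-validate the penalty and apply the one-standard-error rule
#'
#' Stratified k-fold cross-validation of the binomial deviance along the
#' fitted penalty grid. `lambda1se` is the largest penalty whose CV error is
#' within one standard error (across folds) of the minimum - the most
#' regularized model statistically indistinguishable from the best.
#'
#' @param path a [fitLassoPath()] result.
#' @param k number of folds (default 10).
#' @param seed integer fold seed; `NULL` draws folds from the current RNG
#'   stream (used internally by the bootstrap).
#' @return a `LassoCV` list: `lambda`, `cvm`, `cvsd`, `lambdaMin`,
#'   `lambda1se`, `foldid`, `k`, `seed`.
#' @export
selectLambda1se <- function(path, k = 10L, seed = 1L) {
    stopifnot(inherits(path, "LassoPath"), k >= 2L)
    y <- path$y
    n <- length(y)
    if (k > n) stop("k exceeds sample count")
    drawFolds <- function() {
        foldid <- integer(n)
        for (cls in unique(y)) {
            idx <- which(y == cls)
            foldid[idx] <- sample(rep_len(seq_len(k), length(idx)))
        }
        foldid
    }
    foldid <- if (is.null(seed)) drawFolds() else withSeed(seed, drawFolds())
    # stratified assignment guarantees every training fold keeps both
    # classes for k >= 2; a fold may still be empty if k > n
    if (any(tabulate(foldid, k) == n))
        stop("a fold contains every sample; reduce k")
    lambda <- path$lambda
    dev <- matrix(NA_real_, k, length(lambda))
    for (fold in seq_len(k)) {
        held <- foldid == fold
        if (!any(held)) next
        fitk <- glmnet::glmnet(path$X[!held, , drop = FALSE], y[!held],
                               family = "binomial", lambda = lambda,
                               standardize = TRUE)
        p <- stats::predict(fitk, path$X[held, , drop = FALSE], s = lambda,
                            type = "response")
        p <- pmin(pmax(p, 1e-5), 1 - 1e-5)
        yh <- y[held]
        dev[fold, ] <- colMeans(-2 * (yh * log(p) + (1 - yh) * log(1 - p)))
    }
    used <- !apply(dev, 1L, anyNA)
    cvm <- colMeans(dev[used, , drop = FALSE])
    cvsd <- apply(dev[used, , drop = FALSE], 2L, stats::sd) / sqrt(sum(used))
    sel <- lambda1seRule(lambda, cvm, cvsd)
    structure(list(lambda = lambda, cvm = cvm, cvsd = cvsd,
                   lambdaMin = sel$lambdaMin, lambda1se = sel$lambda1se,
                   foldid = foldid, k = k, seed = seed),
              class = "LassoCV")
}

#' @export
print.LassoCV <- function(x, ...) {
    cat(sprintf("LassoCV (%d-fold): lambda.min %.4g, lambda.1se %.4g\n",
                x$k, x$lambdaMin, x$lambda1se))
    invisible(x)
}

#' Extract the sparse signature at a chosen penalty
#'
#' Reads the coefficients at `lambda1se` (snapped to the nearest grid point)
#' and returns the assays with nonzero coefficients, ordered by decreasing
#' absolute standardized coefficient, as a [SignatureModel-class]. An empty
#' signature is a valid outcome and returned with a warning.
#'
#' @param path a [fitLassoPath()] result.
#' @param cv a [selectLambda1se()] result, or a numeric penalty.
#' @return a [SignatureModel-class].
#' @export
extractSignature <- function(path, cv) {
    stopifnot(inherits(path, "LassoPath"))
    lam <- if (inherits(cv, "LassoCV")) cv$lambda1se else as.numeric(cv)
    lam <- path$lambda[which.min(abs(path$lambda - lam))]
    beta <- stats::coef(path$fit, s = lam)
    a0 <- beta[1L]
    b <- stats::setNames(as.numeric(beta[-1L]), rownames(beta)[-1L])
    nz <- names(b)[b != 0]
    if (!length(nz)) warning("signature is empty at the selected penalty")
    center <- colMeans(path$X[, nz, drop = FALSE])
    scl <- apply(path$X[, nz, drop = FALSE], 2L, stats::sd)
    bStd <- b[nz] * scl
    ord <- nz[order(abs(bStd), decreasing = TRUE)]
    cvdf <- if (inherits(cv, "LassoCV"))
        data.frame(lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd)
    else data.frame(lambda = numeric(), cvm = numeric(), cvsd = numeric())
    new("SignatureModel",
        assays = ord,
        coefficients = bStd[ord],
        coefficientsRaw = b[ord],
        intercept = as.numeric(a0 + sum(b[nz] * center[nz])),
        interceptRaw = as.numeric(a0),
        lambdaGrid = path$lambda,
        lambdaMin = if (inherits(cv, "LassoCV")) cv$lambdaMin else lam,
        lambda1se = lam,
        cvError = cvdf,
        center = center[ord], scale = scl[ord],
        threshold = NA_real_,
        seed = if (inherits(cv, "LassoCV") && !is.null(cv$seed))
            as.integer(cv$seed) else NA_integer_)
}

#' Predict class probabilities from a signature model
#'
#' Evaluates `plogis(interceptRaw + sum(coefficientsRaw * Ct))` per sample;
#' the training standardization is folded into the raw-scale coefficients,
#' so raw Ct values are supplied directly.
#'
#' @param model a [SignatureModel-class].
#' @param X numeric matrix, samples x assays, containing every signature
#'   assay as a named column.
#' @return numeric vector of patient-class probabilities.
#' @export
applySignature <- function(model, X) {
    X <- as.matrix(X)
    missing <- setdiff(model@assays, colnames(X))
    if (length(missing))
        stop("signature assays missing from input: ",
             paste(missing, collapse = ", "))
    eta <- rep(model@interceptRaw, nrow(X)) +
        if (length(model@assays))
            as.numeric(X[, model@assays, drop = FALSE] %*%
                       model@coefficientsRaw[model@assays])
        else 0
    stats::setNames(as.numeric(stats::plogis(eta)), rownames(X))
}

#' Bootstrap stability of a selected signature
#'
#' Resamples the cohort with replacement `B` times; each resample is run
#' through the full selection (penalty path, stratified k-fold CV with the
#' one-standard-error rule, signature extraction). A resample counts as a
#' success when it recovers at least half of the original signature
#' (`|S_b intersect S| >= ceiling(|S| / 2)`). The stability p-value is
#' `1 - overlap_frequency`, so small p means a stable, well-supported
#' signature; the raw frequency is reported alongside.
#'
#' @param X,y as in [fitLassoPath()].
#' @param signature character vector of signature assays, or a
#'   [SignatureModel-class].
#' @param B number of bootstrap resamples (default 10000).
#' @param seed RNG seed.
#' @param nLambda,k passed to the per-resample path fit and CV.
#' @return a `StabilityResult` list: `nBootstrap`, `overlapCounts`,
#'   `overlapFrequency`, `pValue`, `signature`.
#' @export
bootstrapStability <- function(X, y, signature, B = 10000L, seed = 1L,
                               nLambda = 100L, k = 10L) {
    if (is(signature, "SignatureModel")) signature <- signatureAssays(signature)
    stopifnot(length(signature) > 0L)
    if (B < 100L) warning("B < 100 gives a low-resolution stability p-value")
    X <- as.matrix(X)
    y <- asBinaryLabels(y)
    n <- nrow(X)
    need <- ceiling(length(signature) / 2)
    overlap <- integer(B)
    withSeed(seed, {
        for (b in seq_len(B)) {
            repeat {
                idx <- sample.int(n, n, replace = TRUE)
                if (length(unique(y[idx])) == 2L) break
            }
            # glmnet emits small-class warnings on unlucky resamples;
            # failures of any kind count as a non-reproducing resample
            Sb <- tryCatch(suppressWarnings({
                path <- fitLassoPath(X[idx, , drop = FALSE], y[idx],
                                     nLambda = nLambda)
                cv <- selectLambda1se(path, k = min(k, sum(y[idx] == 1),
                                                    sum(y[idx] == 0)),
                                      seed = NULL)
                beta <- stats::coef(path$fit, s = cv$lambda1se)
                rownames(beta)[-1L][as.numeric(beta[-1L]) != 0]
            }), error = function(e) character())
            overlap[b] <- length(intersect(Sb, signature))
        }
    })
    freq <- mean(overlap >= need)
    structure(list(nBootstrap = B, overlapCounts = overlap,
                   overlapFrequency = freq, pValue = 1 - freq,
                   signature = signature, seed = seed),
              class = "StabilityResult")
}

#' @export
print.StabilityResult <- function(x, ...) {
    cat(sprintf(paste0("StabilityResult: %d resamples, overlap frequency ",
                       "%.3f, p = %.3g\n"),
                x$nBootstrap, x$overlapFrequency, x$pValue))
    invisible(x)
}

#' Random-signature null distribution of classification accuracy
#'
#' Draws `M` uniform random assay subsets of the signature's size, fits an
#' unpenalized logistic model on the training cohort for each, and scores
#' its accuracy on the test cohort at that model's own FPR-minimizing
#' threshold - the same protocol applied to the observed signature. The
#' p-value uses the add-one convention
#' `(1 + #\{acc_random >= acc_observed\}) / (M + 1)`.
#'
#' @param XTrain,yTrain training cohort (samples x assays, labels).
#' @param XTest,yTest test cohort.
#' @param size signature size to draw.
#' @param pool candidate assay names (default: all columns of `XTrain`).
#' @param M number of random models (default 1000).
#' @param seed RNG seed.
#' @param observedAccuracy accuracy of the observed signature under the same
#'   protocol.
#' @return a `RandomNullResult` list: `nModels`, `accuracies`,
#'   `observedAccuracy`, `pValue`.
#' @export
randomSignatureNull <- function(XTrain, yTrain, XTest, yTest, size,
                                pool = colnames(XTrain), M = 1000L,
                                seed = 1L, observedAccuracy) {
    stopifnot(size >= 1L, length(pool) >= size)
    XTrain <- as.matrix(XTrain)
    XTest <- as.matrix(XTest)
    yTrain <- asBinaryLabels(yTrain)
    yTest <- asBinaryLabels(yTest)
    acc <- numeric(M)
    ridged <- logical(M)
    withSeed(seed, {
        for (m in seq_len(M)) {
            assays <- sample(pool, size)
            fit <- stableLogisticFit(XTrain[, assays, drop = FALSE], yTrain)
            ridged[m] <- fit$ridged
            p <- predictLogistic(fit, XTest[, assays, drop = FALSE])
            thr <- selectThresholdMinFpr(p, yTest)
            acc[m] <- mean((p >= thr) == yTest)
        }
    })
    pv <- (1 + sum(acc >= observedAccuracy)) / (M + 1)
    structure(list(nModels = M, accuracies = acc,
                   observedAccuracy = observedAccuracy, pValue = pv,
                   nRidged = sum(ridged), seed = seed),
              class = "RandomNullResult")
}

#' @export
print.RandomNullResult <- function(x, ...) {
    cat(sprintf(paste0("RandomNullResult: observed accuracy %.3f vs %d ",
                       "random models (median %.3f), p = %.4g\n"),
                x$observedAccuracy, x$nModels, stats::median(x$accuracies),
                x$pValue))
    invisible(x)
}
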