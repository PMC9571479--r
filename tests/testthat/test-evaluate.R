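test_that("LOOCV probabilities equal brute-force per-fold refits", {
    set.seed(30)
    n <- 14
    X <- matrix(rnorm(n * 2, 26, 1), n, 2,
                dimnames = list(sprintf("s%02d", 1:n), c("a", "b")))
    y <- rep(c(1, 0), each = n / 2)
    X[, 1] <- X[, 1] - y  # mild, non-separating signal
    probs <- loocvProbabilities(X, y, c("a", "b"))
    expect_length(probs, n)
    expect_named(probs, rownames(X))
    oracle <- vapply(seq_len(n), function(i) {
        df <- data.frame(y = y[-i], X[-i, , drop = FALSE])
        fit <- stats::glm(y ~ a + b, data = df, family = binomial())
        stats::predict(fit, newdata = as.data.frame(X[i, , drop = FALSE]),
                       type = "response")
    }, numeric(1L))
    expect_equal(as.numeric(probs), unname(oracle), tolerance = 1e-8)
})

test_that("LOOCV on separable data puts every sample on the right side", {
    set.seed(31)
    n <- 16
    y <- rep(c(1, 0), each = n / 2)
    X <- matrix(rnorm(n * 2, 26, 0.5), n, 2,
                dimnames = list(NULL, c("a", "b")))
    X[, 1] <- X[, 1] - 6 * y
    probs <- loocvProbabilities(X, y, c("a", "b"))
    expect_true(all((probs > 0.5) == (y == 1)))
    expect_true(any(attr(probs, "ridged")))  # separation handled, flagged
    expect_error(loocvProbabilities(X[1:3, ], y[1:3], "a"), "n >= 4")
})

test_that("ROC AUC matches the pairwise Mann-Whitney oracle", {
    y <- c(1, 1, 1, 0, 0, 0)
    expect_equal(rocCurve(c(1, 1, 1, 0, 0, 0), y)$auc, 1)
    expect_equal(rocCurve(rep(0.4, 6), y)$auc, 0.5)
    probs <- c(0.9, 0.6, 0.4, 0.6, 0.3, 0.1)
    r <- rocCurve(probs, y)
    expect_equal(r$auc, pairwiseAuc(probs, y))
    set.seed(32)
    for (i in 1:20) {
        p2 <- round(runif(12), 1)  # rounding forces ties
        y2 <- rep(c(1, 0), 6)
        expect_equal(rocCurve(p2, y2)$auc, pairwiseAuc(p2, y2))
    }
    expect_error(rocCurve(probs, rep(1, 6)), "both classes")
})

test_that("ROC is invariant to monotone transforms; label flip maps to 1-AUC", {
    set.seed(33)
    probs <- runif(20)
    y <- rep(c(1, 0), 10)
    a <- rocCurve(probs, y)$auc
    expect_equal(rocCurve(plogis(5 * probs - 2), y)$auc, a)
    expect_equal(rocCurve(probs^3, y)$auc, a)
    expect_equal(rocCurve(probs, 1 - y)$auc, 1 - a)
})

test_that("DeLong CI contains the AUC and narrows with sample size", {
    makeData <- function(n, seed) {
        set.seed(seed)
        y <- rep(c(1, 0), n / 2)
        list(p = plogis(rnorm(n, 1.2 * y)), y = y)
    }
    small <- makeData(20, 34)
    big <- makeData(200, 35)
    rs <- rocCurve(small$p, small$y)
    rb <- rocCurve(big$p, big$y)
    expect_true(rs$ci[1] <= rs$auc && rs$auc <= rs$ci[2])
    expect_true(rb$ci[1] <= rb$auc && rb$auc <= rb$ci[2])
    expect_lt(diff(rb$ci), diff(rs$ci))
})

test_that("PR AUC matches exhaustive threshold enumeration", {
    y <- c(1, 1, 1, 0, 0, 0)
    expect_equal(prCurve(c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1), y,
                         bootReps = 0)$auc, 1)
    flat <- prCurve(rep(0.5, 6), y, bootReps = 0)
    expect_equal(flat$auc, 0.5)  # precision = prevalence everywhere

    probs <- c(0.9, 0.55, 0.4, 0.6, 0.3, 0.1)
    pr <- prCurve(probs, y, bootReps = 0)
    # independent oracle: walk thresholds, count, integrate
    thr <- sort(unique(probs), decreasing = TRUE)
    rec <- prec <- numeric(length(thr))
    for (i in seq_along(thr)) {
        pred <- probs >= thr[i]
        rec[i] <- sum(pred & y == 1) / sum(y == 1)
        prec[i] <- sum(pred & y == 1) / sum(pred)
    }
    rec <- c(0, rec); prec <- c(prec[1], prec)
    oracle <- sum(diff(rec) * (head(prec, -1) + tail(prec, -1)) / 2)
    expect_equal(pr$auc, oracle, tolerance = 1e-12)
    expect_error(prCurve(probs, rep(0, 6)), "positive")

    ci <- prCurve(probs, y, bootReps = 200, seed = 1)$ci
    expect_true(ci[1] <= pr$auc + 1e-9 && pr$auc <= ci[2] + 1e-9)
})

test_that("threshold selection maximizes TPR then minimizes FPR", {
    y <- c(0, 0, 1, 1)
    p <- c(0.1, 0.6, 0.4, 0.9)
    thr <- selectThresholdMinFpr(p, y)
    expect_gt(thr, 0.1); expect_lt(thr, 0.4)
    m <- confusionMetrics(p, y, thr)
    expect_equal(m$sensitivity, 1)
    expect_equal(m$specificity, 0.5)

    sep <- selectThresholdMinFpr(c(0.1, 0.2, 0.8, 0.9), y)
    ms <- confusionMetrics(c(0.1, 0.2, 0.8, 0.9), y, sep)
    expect_equal(ms$sensitivity, 1)
    expect_equal(ms$specificity, 1)

    same <- selectThresholdMinFpr(rep(0.7, 4), y)
    expect_true(same < 0.7)  # predict everything positive
    mSame <- confusionMetrics(rep(0.7, 4), y, same)
    expect_equal(mSame$sensitivity, 1)
    expect_equal(mSame$specificity, 0)

    # the literal rule is degenerate: it prefers FPR 0 at any cost
    lit <- selectThresholdMinFpr(rep(0.7, 4), y, rule = "literal_min_fpr")
    mLit <- confusionMetrics(rep(0.7, 4), y, lit)
    expect_equal(mLit$specificity, 1)
    expect_equal(mLit$sensitivity, 0)
})

test_that("confusion metrics match direct counts and flag zero denominators", {
    perfect <- confusionMetrics(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0), 0.5)
    expect_equal(perfect$accuracy, 1)
    expect_equal(unname(perfect$counts), c(2, 0, 2, 0))
    expect_length(perfect$undefined, 0L)

    none <- confusionMetrics(c(0.1, 0.2), c(1, 0), 0.5)
    expect_true(is.na(none$ppv))
    expect_true("ppv" %in% none$undefined)

    # external-cohort-like confusion pattern: 35 TP, 10 FP, 10 TN, 0 FN
    probs <- c(rep(0.9, 35), rep(0.9, 10), rep(0.1, 10))
    y <- c(rep(1, 35), rep(0, 20))
    m <- confusionMetrics(probs, y, 0.5)
    expect_equal(m$sensitivity, 1)
    expect_equal(m$specificity, 0.5)
    expect_equal(m$accuracy, 45 / 55, tolerance = 1e-9)
    expect_equal(m$ppv, 35 / 45, tolerance = 1e-9)
    expect_equal(m$npv, 1)
})

test_that("cohort evaluation is self-consistent and recalibration helps", {
    set.seed(36)
    n <- 30
    y <- rep(c(1, 0), each = 15)
    X <- matrix(rnorm(n * 3, 26, 1), n, 3,
                dimnames = list(NULL, c("a", "b", "noise")))
    X[, 1] <- X[, 1] - 2.5 * y
    path <- fitLassoPath(X, y)
    model <- extractSignature(path, 0.05)
    probs <- applySignature(model, X)
    rep1 <- evalReport(probs, y, bootReps = 100, seed = 1)
    model@threshold <- rep1$threshold
    rep2 <- evaluateOnCohort(model, X, y, recalibrateThreshold = FALSE,
                             bootReps = 100, seed = 1)
    expect_equal(rep2$metrics$accuracy, rep1$metrics$accuracy)
    expect_equal(rep2$roc$auc, rep1$roc$auc)

    # shifted cohort: the cohort-specific threshold can only do better
    X2 <- X; X2[, 1] <- X2[, 1] + 1.5
    rep3 <- evaluateOnCohort(model, X2, y, recalibrateThreshold = TRUE,
                             bootReps = 0)
    expect_gte(rep3$metrics$accuracy,
               rep3$metricsAtModelThreshold$accuracy)

    # label-permuted cohort: AUC hovers near chance
    set.seed(37)
    aucs <- vapply(1:5, function(i) {
        yp <- sample(rep(c(1, 0), each = 20))
        Xp <- matrix(rnorm(40 * 3, 26, 1), 40, 3,
                     dimnames = list(NULL, c("a", "b", "noise")))
        evaluateOnCohort(model, Xp, yp, bootReps = 0)$roc$auc
    }, numeric(1L))
    expect_true(all(abs(aucs - 0.5) < 0.2))
})
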