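makeXy <- function(n = 40, p = 10, seed = 1) {
    set.seed(seed)
    X <- matrix(rnorm(n * p, 26, 1.5), n, p)
    colnames(X) <- sprintf("miR-%03d", seq_len(p))
    rownames(X) <- sprintf("s%02d", seq_len(n))
    y <- rep(c(1, 0), length.out = n)
    list(X = X, y = y)
}

test_that("penalty saturation gives the intercept-only model", {
    d <- makeXy()
    path <- fitLassoPath(d$X, d$y)
    expect_warning(m <- extractSignature(path, max(path$lambda) * 2),
                   "empty")
    expect_length(signatureAssays(m), 0L)
    p <- applySignature(m, d$X)
    expect_true(all(abs(p - p[1]) < 1e-12))
})

test_that("a separating feature dominates the coefficients at small lambda", {
    set.seed(2)
    n <- 200
    y <- rep(c(1, 0), each = n / 2)
    X <- matrix(rnorm(n * 8, 26, 1), n, 8)
    X[, 1] <- 26 + ifelse(y == 1, -2, 2) + rnorm(n, 0, 0.3)
    colnames(X) <- sprintf("miR-%03d", 1:8)
    path <- fitLassoPath(X, y)
    m <- extractSignature(path, min(path$lambda))
    co <- signatureCoefficients(m, "standardized")
    expect_equal(names(which.max(abs(co))), "miR-001")
})

test_that("duplicated features leave fitted probabilities unchanged", {
    d <- makeXy(n = 60, p = 5, seed = 3)
    Xdup <- cbind(d$X, dup = d$X[, 1])
    colnames(Xdup)[6] <- "miR-001-dup"
    f1 <- fitLassoPath(d$X, d$y)
    f2 <- fitLassoPath(Xdup, d$y)
    s <- 0.05
    p1 <- as.numeric(predict(f1$fit, d$X, s = s, type = "response",
                             exact = TRUE, x = f1$X, y = f1$y))
    p2 <- as.numeric(predict(f2$fit, Xdup, s = s, type = "response",
                             exact = TRUE, x = f2$X, y = f2$y))
    expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("constant features are dropped and single-class labels rejected", {
    d <- makeXy()
    d$X[, 3] <- 27
    expect_warning(path <- fitLassoPath(d$X, d$y), "constant")
    expect_false("miR-003" %in% rownames(path$fit$beta))
    expect_error(fitLassoPath(d$X, rep(1, 40)), "both classes")
})

test_that("the one-standard-error rule follows its definition", {
    rule <- mirsig:::lambda1seRule
    r <- rule(c(1, 0.1, 0.01), c(0.5, 0.2, 0.3), c(0.1, 0.05, 0.05))
    expect_equal(r$lambdaMin, 0.1)
    expect_equal(r$lambda1se, 0.1)
    # monotone decreasing error with zero SE: 1se collapses onto min
    r2 <- rule(c(1, 0.1, 0.01), c(0.5, 0.4, 0.3), c(0, 0, 0))
    expect_equal(r2$lambda1se, r2$lambdaMin)
    expect_equal(r2$lambdaMin, 0.01)
})

test_that("CV folds and the selected penalty are seed-deterministic", {
    d <- makeXy(n = 40, p = 6, seed = 4)
    path <- fitLassoPath(d$X, d$y)
    a <- selectLambda1se(path, k = 10, seed = 7)
    b <- selectLambda1se(path, k = 10, seed = 7)
    expect_identical(a$foldid, b$foldid)
    expect_identical(a$lambda1se, b$lambda1se)
    c <- selectLambda1se(path, k = 10, seed = 8)
    expect_false(identical(a$foldid, c$foldid))
    # stratification: every fold has the same class split (20/20, k=10)
    expect_true(all(table(a$foldid, d$y) == 2))
})

test_that("CV mean deviance agrees with cv.glmnet on shared folds", {
    d <- makeXy(n = 40, p = 6, seed = 5)
    path <- fitLassoPath(d$X, d$y)
    mine <- selectLambda1se(path, k = 10, seed = 9)
    ref <- glmnet::cv.glmnet(d$X, d$y, family = "binomial",
                             lambda = path$lambda, foldid = mine$foldid,
                             type.measure = "deviance")
    shared <- intersect(round(log(mine$lambda), 10),
                        round(log(ref$lambda), 10))
    i <- match(shared, round(log(mine$lambda), 10))
    j <- match(shared, round(log(ref$lambda), 10))
    # equal fold sizes: fold-mean average equals observation average
    expect_equal(mine$cvm[i], ref$cvm[j], tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(mine$lambdaMin, as.numeric(ref$lambda.min))
})

test_that("signature extraction reports both coefficient scales", {
    cfg <- tinyConfig(seed = 17, nPatients = 16L, nControls = 22L)
    co <- simulateCohort(cfg)
    x <- filterInformative(imputeUndetermined(co$ctSet))
    nm <- normalizeGeometricMean(x)
    tab <- differentialExpression(nm)
    X <- t(ctValues(nm))[, deAssays(tab), drop = FALSE]
    y <- sampleGroups(nm)
    path <- fitLassoPath(X, y)
    cv <- selectLambda1se(path, seed = 1)
    m <- extractSignature(path, cv)
    expect_gte(length(signatureAssays(m)), 3L)
    expect_true(all(signatureAssays(m) %in% co$truth$assays))
    co1 <- signatureCoefficients(m, "raw")
    co2 <- signatureCoefficients(m, "standardized")
    expect_equal(unname(co2), unname(co1 * m@scale[names(co1)]))
    # ordering by decreasing |standardized coefficient|
    expect_true(all(diff(abs(co2)) <= 1e-12))
    # up-regulated planted assays (lower Ct in patients) get negative Ct
    # weights; the down-regulated one gets a positive weight
    expect_lt(co1[["miR-412-3p"]], 0)
    if ("miR-362-3p" %in% names(co1)) expect_gt(co1[["miR-362-3p"]], 0)
})

test_that("sparsity is monotone along the penalty path", {
    d <- makeXy(n = 50, p = 12, seed = 6)
    path <- fitLassoPath(d$X, d$y)
    expect_true(all(diff(path$fit$df) >= 0))  # lambda decreases along path
})

test_that("feature rescaling leaves fitted probabilities unchanged", {
    d <- makeXy(n = 50, p = 6, seed = 7)
    Xs <- d$X
    Xs[, 2] <- Xs[, 2] * 10
    f1 <- fitLassoPath(d$X, d$y)
    f2 <- fitLassoPath(Xs, d$y)
    s <- 0.05
    p1 <- as.numeric(predict(f1$fit, d$X, s = s, type = "response",
                             exact = TRUE, x = f1$X, y = f1$y))
    p2 <- as.numeric(predict(f2$fit, Xs, s = s, type = "response",
                             exact = TRUE, x = f2$X, y = f2$y))
    expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("applySignature matches a hand-computed logistic oracle", {
    m <- new("SignatureModel", assays = c("a", "b"),
             coefficients = c(a = -1.24, b = 4.03),
             coefficientsRaw = c(a = -1.24, b = 4.03),
             intercept = 0, interceptRaw = 0.5,
             lambdaGrid = 0.1, lambdaMin = 0.1, lambda1se = 0.1,
             cvError = data.frame(), center = c(a = 0, b = 0),
             scale = c(a = 1, b = 1))
    X <- matrix(c(0.2, -0.1, 1.4, 0, 0.5, -2), 3, 2,
                dimnames = list(c("s1", "s2", "s3"), c("a", "b")))
    eta <- 0.5 - 1.24 * X[, "a"] + 4.03 * X[, "b"]
    expect_equal(unname(applySignature(m, X)), unname(1 / (1 + exp(-eta))),
                 tolerance = 1e-12)
    expect_error(applySignature(m, X[, 1, drop = FALSE]), "missing.*b")

    nullM <- m
    nullM@coefficientsRaw[] <- 0
    nullM@interceptRaw <- 0
    expect_equal(unname(applySignature(nullM, X)), rep(0.5, 3))
})

test_that("bootstrap stability is certain on deterministic data", {
    set.seed(8)
    n <- 30
    y <- rep(c(1, 0), each = 15)
    X <- matrix(rnorm(n * 6, 0, 1), n, 6)
    X[, 1] <- ifelse(y == 1, 10, -10) + rnorm(n, 0, 0.1)
    X[, 2] <- ifelse(y == 1, -10, 10) + rnorm(n, 0, 0.1)
    colnames(X) <- sprintf("miR-%03d", 1:6)
    expect_warning(st <- bootstrapStability(X, y, c("miR-001", "miR-002"),
                                            B = 50, seed = 1),
                   "low-resolution")
    expect_equal(st$overlapFrequency, 1)
    expect_equal(st$pValue, 0)
    expect_length(st$overlapCounts, 50L)
})

test_that("random-signature null follows the add-one convention", {
    set.seed(9)
    n <- 40
    XTr <- matrix(rnorm(n * 12, 26, 1), n, 12,
                  dimnames = list(NULL, sprintf("miR-%03d", 1:12)))
    XTe <- matrix(rnorm(n * 12, 26, 1), n, 12,
                  dimnames = list(NULL, sprintf("miR-%03d", 1:12)))
    yTr <- rep(c(1, 0), each = n / 2)
    yTe <- rep(c(1, 0), each = n / 2)
    nul <- randomSignatureNull(XTr, yTr, XTe, yTe, size = 2, M = 100,
                               seed = 2, observedAccuracy = 1.0)
    expect_equal(nul$pValue, 1 / 101)

    # degenerate pool: every random model IS the observed model
    obsAssays <- c("miR-001", "miR-002")
    fit <- mirsig:::stableLogisticFit(XTr[, obsAssays], yTr)
    p <- mirsig:::predictLogistic(fit, XTe[, obsAssays])
    thr <- selectThresholdMinFpr(p, yTe)
    accObs <- mean((p >= thr) == yTe)
    nul2 <- randomSignatureNull(XTr, yTr, XTe, yTe, size = 2,
                                pool = obsAssays, M = 50, seed = 3,
                                observedAccuracy = accObs)
    expect_equal(nul2$pValue, 1)
})
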