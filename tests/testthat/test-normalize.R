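test_that("quantile normalization matches brute-force order-statistic means", {
    m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
    rownames(m) <- c("a", "b", "c")
    q <- normalizeQuantile(makeCtSet(m))
    expect_equal(unname(ctValues(q)),
                 cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))

    set.seed(1)
    m2 <- matrix(sample(seq(20, 34, by = 0.01), 7 * 4), 7, 4)
    q2 <- normalizeQuantile(makeCtSet(m2))
    expect_equal(unname(ctValues(q2)), unname(bruteQuantileNorm(m2)),
                 tolerance = 1e-12)
    # invariant: all samples share one multiset of values
    vals <- apply(ctValues(q2), 2L, sort)
    expect_true(all(abs(vals - vals[, 1]) < 1e-12))

    same <- makeCtSet(cbind(a = c(20, 25, 30), b = c(20, 25, 30)))
    expect_equal(ctValues(normalizeQuantile(same)), ctValues(same))

    single <- makeCtSet(matrix(c(20, 26), 1, 2))
    expect_equal(unname(ctValues(normalizeQuantile(single))),
                 matrix(23, 1, 2))
})

test_that("global-mean centering is exact and offset-invariant", {
    m <- cbind(s1 = c(20, 30), s2 = c(19, 27))
    g <- normalizeGeometricMean(makeCtSet(m))
    expect_equal(unname(ctValues(g)[, "s1"]), c(19, 29))

    balanced <- cbind(a = c(20, 30), b = c(22, 28))
    expect_equal(ctValues(normalizeGeometricMean(makeCtSet(balanced))),
                 ctValues(makeCtSet(balanced)))

    set.seed(2)
    base <- matrix(runif(40, 20, 33), 10, 4)
    shifted <- base
    shifted[, 2] <- shifted[, 2] + 2
    # per-sample offsets cancel up to one global constant (the grand mean
    # itself moves with the offset)
    a <- ctValues(normalizeGeometricMean(makeCtSet(base)))
    b <- ctValues(normalizeGeometricMean(makeCtSet(shifted)))
    d <- a - b
    expect_lt(max(abs(d - mean(d))), 1e-12)
})

test_that("delta-Ct normalization subtracts the control-assay mean", {
    m <- rbind(ctrl = c(18, 18), assay = c(25, 26))
    colnames(m) <- c("s1", "s2")
    d <- normalizeDeltaCt(makeCtSet(m), controlAssays = "ctrl")
    expect_equal(unname(ctValues(d)["assay", ]), c(7, 8))
    expect_equal(unname(ctValues(d)["ctrl", ]), c(0, 0))

    m2 <- rbind(c1 = c(18, 18), c2 = c(20, 20), assay = c(25, 25))
    colnames(m2) <- c("s1", "s2")
    d2 <- normalizeDeltaCt(makeCtSet(m2), controlAssays = c("c1", "c2"))
    expect_equal(unname(ctValues(d2)["assay", ]), c(6, 6))

    expect_error(normalizeDeltaCt(makeCtSet(m), controlAssays = "nope"),
                 "absent")
    expect_error(normalizeDeltaCt(makeCtSet(m)), "no control assays")
    sp <- makeCtSet(m, spikeins = "ctrl")
    expect_equal(ctValues(normalizeDeltaCt(sp)), ctValues(d))
})

test_that("rank-invariant set follows the rank-shift rule", {
    ref <- seq(20, 30, length.out = 100)
    # strictly monotone transform preserves every rank
    s <- 2 * ref + 5
    keep <- rankInvariantSet(s, ref)
    expect_setequal(keep, 6:95)

    # moving the smallest value to the top excludes it
    s2 <- ref
    s2[1] <- 40
    expect_false(1 %in% rankInvariantSet(s2, ref))

    # random permutation: set equals the brute-force rank comparison
    set.seed(3)
    s3 <- sample(ref)
    keep3 <- rankInvariantSet(s3, ref, maxRankShift = 0.05,
                              excludeExtreme = 0.05)
    rs <- rank(s3); rr <- rank(ref)
    brute <- which(abs(rs - rr) <= 5 & rr > 5 & rr <= 95)
    expect_identical(sort(keep3), sort(brute))

    expect_error(rankInvariantSet(1:5, 1:5), ">= 10")
})

test_that("scale rank-invariant normalization removes pure offsets exactly", {
    set.seed(4)
    baseline <- runif(60, 20, 33)
    offsets <- c(-1.5, 0, 0.7, 2, -0.3)
    truth <- matrix(baseline, 60, 5)
    obs <- sweep(truth, 2L, offsets, "+")
    x <- makeCtSet(obs)
    out <- ctValues(normalizeScaleRankInvariant(x))
    resid <- out - truth
    # recovered up to one global constant
    expect_lt(max(abs(resid - mean(resid))), 1e-9)
    expect_lt(sd(as.vector(resid)), 0.05)

    single <- makeCtSet(matrix(runif(12, 20, 30), 12, 1))
    expect_equal(ctValues(normalizeScaleRankInvariant(single)),
                 ctValues(single))
})

test_that("degenerate common set falls back to global-mean centering", {
    set.seed(5)
    # independent random columns destroy rank stability
    m <- matrix(runif(4 * 12, 20, 33), 12, 4)
    x <- makeCtSet(m)
    expect_warning(out <- normalizeScaleRankInvariant(x, maxRankShift = 0.0001),
                   "falling back")
    expect_equal(out@method, "geometric_mean")
    expect_equal(out@methodParams$fallbackFrom, "scale_rank_invariant")
    expect_equal(ctValues(out), ctValues(normalizeGeometricMean(x)))
})

test_that("norm rank-invariant recovers offsets and smooth biases", {
    set.seed(6)
    baseline <- sort(runif(80, 20, 33))
    truth <- matrix(baseline, 80, 5)

    # constant offset on one sample: recovered to < 0.1 cycles
    obs <- truth
    obs[, 3] <- obs[, 3] + 2
    out <- ctValues(normalizeNormRankInvariant(makeCtSet(obs)))
    expect_lt(max(abs(out[, 3] - rowMeans(out[, -3]))), 0.1)

    # exact fixed point: every sample equals the reference
    outSame <- ctValues(normalizeNormRankInvariant(makeCtSet(truth)))
    expect_equal(unname(outSame), unname(truth), tolerance = 1e-9)

    # smooth intensity-dependent bias: curve fit beats pure shifting
    ref <- rowMeans(truth)
    biased <- truth
    biased[, 2] <- biased[, 2] * 1.02 + 0.5
    xB <- makeCtSet(biased)
    residNorm <- ctValues(normalizeNormRankInvariant(xB))[, 2] - ref
    residScale <- ctValues(normalizeScaleRankInvariant(xB))[, 2] - ref
    expect_lt(sqrt(mean(residNorm^2)), sqrt(mean(residScale^2)))
})

test_that("normalization scores match closed forms", {
    const <- makeCtSet(matrix(25, 4, 3))
    sc <- scoreNormalization(const)
    expect_equal(sc$meanCV, 0)
    expect_equal(sc$meanSD, 0)

    two <- makeCtSet(matrix(c(24, 26), 1, 2))
    sc2 <- scoreNormalization(two)
    expect_equal(sc2$meanSD, sqrt(2))
    expect_equal(sc2$meanCV, sqrt(2) / 25)

    m <- matrix(c(24, 26, 30, 34), 2, 2)
    x2 <- scoreNormalization(makeCtSet(2 * m))
    x1 <- scoreNormalization(makeCtSet(m))
    expect_equal(x2$meanSD, 2 * x1$meanSD)
    expect_equal(x2$meanCV, x1$meanCV)

    # two-pass oracle
    set.seed(7)
    r <- matrix(rnorm(50, 25, 2), 10, 5)
    sc3 <- scoreNormalization(makeCtSet(r))
    expect_equal(sc3$meanSD, mean(apply(r, 1, sd)), tolerance = 1e-12)
    expect_equal(sc3$meanCV, mean(apply(r, 1, sd) / rowMeans(r)),
                 tolerance = 1e-12)

    zero <- makeCtSet(matrix(c(0, 0, 24, 26), 2, 2, byrow = TRUE))
    expect_warning(scoreNormalization(zero), "zero mean")
})

test_that("method selection ranks by CV, breaks ties by SD then order", {
    co <- simulateCohort(tinyConfig(seed = 10))
    x <- filterInformative(imputeUndetermined(co$ctSet))
    one <- selectNormalization(x, methods = "quantile")
    expect_equal(one$best@method, "quantile")
    expect_equal(nrow(one$scores), 1L)

    sel <- suppressWarnings(selectNormalization(x))
    expect_true(all(diff(sel$scores$meanCV) >= 0))
    expect_equal(sel$best@method, sel$scores$effectiveMethod[1])

    # offsets only: a rank-invariant method beats the unnormalized no-op
    set.seed(11)
    baseline <- runif(120, 20, 33)
    obs <- sweep(matrix(baseline, 120, 5) +
                     matrix(rnorm(600, 0, 0.1), 120, 5),
                 2L, c(-2, -1, 0, 1, 2), "+")
    xo <- makeCtSet(obs)
    ri <- normalizeScaleRankInvariant(xo)
    expect_equal(ri@method, "scale_rank_invariant")
    riCv <- scoreNormalization(ri)$meanCV
    rawCv <- scoreNormalization(xo)$meanCV
    expect_lt(riCv, rawCv)
})
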