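newNormalized <- function(x, ct, method, params = list()) {
    out <- new("NormalizedCtSet", x, method = method, methodParams = params)
    assay(out, "ct") <- ct
    out
}

.asCtSet <- function(x) {
    ct <- ctValues(x)
    if (anyNA(ct))
        stop("matrix contains Undetermined entries; run imputeUndetermined()",
             " first")
    ct
}

#' Quantile normalization
#'
#' Forces every sample to the same distribution: each sample's k-th order
#' statistic is replaced by the mean of all samples' k-th order statistics;
#' ties within a sample receive the mean of the replacement values they span
#' (via [limma::normalizeQuantiles()] with `ties = TRUE`).
#'
#' @param x an imputed [CtSet-class] with at least 2 samples.
#' @return a [NormalizedCtSet-class].
#' @family normalization methods
#' @export
normalizeQuantile <- function(x) {
    ct <- .asCtSet(x)
    if (ncol(ct) < 2L) stop("quantile normalization needs >= 2 samples")
    out <- if (nrow(ct) == 1L) {
        # single order statistic: every sample gets the grand mean
        matrix(mean(ct), 1L, ncol(ct))
    } else limma::normalizeQuantiles(ct, ties = TRUE)
    dimnames(out) <- dimnames(ct)
    newNormalized(x, out, "quantile")
}

#' Global-mean (geometric mean) normalization
#'
#' Geometric-mean scaling on the linear expression scale (`2^-Ct`) equals
#' arithmetic-mean centering on the Ct scale: each sample is shifted by
#' (grand mean Ct - its own mean Ct), so all samples end with the same mean.
#'
#' @inheritParams normalizeQuantile
#' @family normalization methods
#' @export
normalizeGeometricMean <- function(x) {
    ct <- .asCtSet(x)
    shifts <- mean(ct) - colMeans(ct)
    out <- sweep(ct, 2L, shifts, "+")
    newNormalized(x, out, "geometric_mean", list(shifts = shifts))
}

#' Delta-Ct normalization against control assays
#'
#' Subtracts, per sample, the mean Ct of a set of control assays (by default
#' the flagged spike-ins) from every Ct, yielding per-sample delta-Ct values.
#'
#' @inheritParams normalizeQuantile
#' @param controlAssays character, control assay names; defaults to the
#'   spike-in assays flagged in `rowData(x)$spikein`.
#' @family normalization methods
#' @export
normalizeDeltaCt <- function(x, controlAssays = NULL) {
    ct <- .asCtSet(x)
    if (is.null(controlAssays)) controlAssays <- rownames(x)[isSpikein(x)]
    if (!length(controlAssays))
        stop("no control assays given and no spike-ins flagged")
    missing <- setdiff(controlAssays, rownames(ct))
    if (length(missing))
        stop("control assays absent: ", paste(missing, collapse = ", "))
    ref <- colMeans(ct[controlAssays, , drop = FALSE])
    out <- sweep(ct, 2L, ref, "-")
    newNormalized(x, out, "delta_ct", list(controlAssays = controlAssays))
}

#' Rank-invariant assay set between a sample and a reference
#'
#' Returns the assays whose rank in the sample differs from their rank in
#' the reference by at most `maxRankShift * N` and whose reference rank lies
#' outside the extreme `excludeExtreme` tails. Rank-invariant assays anchor
#' the two rank-invariant normalization methods: their rank stability marks
#' them as unlikely to be differential or artefactual.
#'
#' @param sampleCts,referenceCts equal-length numeric vectors (>= 10 values);
#'   the reference is typically the per-assay mean Ct across samples.
#' @param maxRankShift maximum allowed rank shift, as a fraction of N.
#' @param excludeExtreme fraction of lowest and highest reference ranks
#'   excluded.
#' @param floor minimum usable set size; smaller sets are flagged degenerate
#'   via `attr(, "degenerate")`.
#' @return integer indices of the rank-invariant assays.
#' @export
rankInvariantSet <- function(sampleCts, referenceCts, maxRankShift = 0.05,
                             excludeExtreme = 0.05, floor = 5L) {
    n <- length(sampleCts)
    stopifnot(length(referenceCts) == n, n >= 10L)
    rs <- rank(sampleCts, ties.method = "average")
    rr <- rank(referenceCts, ties.method = "average")
    keep <- which(abs(rs - rr) <= maxRankShift * n &
                  rr > excludeExtreme * n & rr <= (1 - excludeExtreme) * n)
    attr(keep, "degenerate") <- length(keep) < floor
    keep
}

#' Scale rank-invariant normalization
#'
#' Computes the rank-invariant set of every sample against the pseudo-mean
#' reference, intersects them, and shifts each sample by (mean reference Ct -
#' mean sample Ct) over the common set. Falls back to
#' [normalizeGeometricMean()] with a warning when the common set is
#' degenerate.
#'
#' @inheritParams normalizeQuantile
#' @param maxRankShift,excludeExtreme,floor see [rankInvariantSet()].
#' @family normalization methods
#' @export
normalizeScaleRankInvariant <- function(x, maxRankShift = 0.05,
                                        excludeExtreme = 0.05, floor = 5L) {
    ct <- .asCtSet(x)
    if (ncol(ct) < 2L) {
        return(newNormalized(x, ct, "scale_rank_invariant",
                             list(note = "single sample; identity")))
    }
    ref <- rowMeans(ct)
    sets <- lapply(seq_len(ncol(ct)), function(j)
        rankInvariantSet(ct[, j], ref, maxRankShift, excludeExtreme, floor))
    common <- Reduce(intersect, sets)
    if (length(common) < floor) {
        warning("rank-invariant common set degenerate (", length(common),
                " assays); falling back to geometric-mean normalization")
        out <- normalizeGeometricMean(x)
        out@methodParams$fallbackFrom <- "scale_rank_invariant"
        return(out)
    }
    shifts <- mean(ref[common]) - colMeans(ct[common, , drop = FALSE])
    out <- sweep(ct, 2L, shifts, "+")
    newNormalized(x, out, "scale_rank_invariant",
                  list(commonSet = rownames(ct)[common], shifts = shifts))
}

# Piecewise-linear evaluation of a fitted (x, y) curve with linear
# extrapolation beyond the curve's range using the edge segment slopes.
curveTransform <- function(cx, cy, xout) {
    o <- order(cx)
    cx <- cx[o]; cy <- cy[o]
    if (anyDuplicated(cx)) {
        cy <- tapply(cy, cx, mean)
        cx <- as.numeric(names(cy))
        cy <- as.numeric(cy)
    }
    if (length(cx) < 2L) return(xout + (cy[1L] - cx[1L]))
    y <- stats::approx(cx, cy, xout = xout, rule = 1L, ties = "mean")$y
    k <- length(cx)
    sl1 <- (cy[2L] - cy[1L]) / (cx[2L] - cx[1L])
    slk <- (cy[k] - cy[k - 1L]) / (cx[k] - cx[k - 1L])
    low <- xout < cx[1L]
    high <- xout > cx[k]
    y[low] <- cy[1L] + sl1 * (xout[low] - cx[1L])
    y[high] <- cy[k] + slk * (xout[high] - cx[k])
    y
}

#' Norm rank-invariant normalization
#'
#' For each sample, fits a locally weighted smoothing curve (lowess) mapping
#' sample Ct to reference Ct over that sample's rank-invariant set, then
#' transforms all of the sample's Ct values through the fitted curve, with
#' linear extrapolation beyond the set's range. Unlike the scale variant this
#' removes smooth intensity-dependent distortions, not just global shifts.
#' Falls back to [normalizeScaleRankInvariant()] with a warning when a
#' sample's rank-invariant set is degenerate.
#'
#' @inheritParams normalizeScaleRankInvariant
#' @param f lowess smoother span.
#' @family normalization methods
#' @export
normalizeNormRankInvariant <- function(x, maxRankShift = 0.05,
                                       excludeExtreme = 0.05, floor = 5L,
                                       f = 2 / 3) {
    ct <- .asCtSet(x)
    if (ncol(ct) < 2L)
        return(newNormalized(x, ct, "norm_rank_invariant",
                             list(note = "single sample; identity")))
    ref <- rowMeans(ct)
    sets <- lapply(seq_len(ncol(ct)), function(j)
        rankInvariantSet(ct[, j], ref, maxRankShift, excludeExtreme, floor))
    if (any(vapply(sets, function(s) attr(s, "degenerate"), logical(1L)))) {
        warning("degenerate rank-invariant set; falling back to scale ",
                "rank-invariant normalization")
        out <- normalizeScaleRankInvariant(x, maxRankShift, excludeExtreme,
                                           floor)
        out@methodParams$fallbackFrom <- "norm_rank_invariant"
        return(out)
    }
    out <- ct
    for (j in seq_len(ncol(ct))) {
        s <- sets[[j]]
        lw <- stats::lowess(ct[s, j], ref[s], f = f)
        out[, j] <- curveTransform(lw$x, lw$y, ct[, j])
    }
    newNormalized(x, out, "norm_rank_invariant",
                  list(setSizes = lengths(sets), f = f))
}

#' Score a normalization by residual between-sample variability
#'
#' Per assay, the standard deviation across samples and the coefficient of
#' variation `CV = SD / |mean|` are computed on the (normalized) Ct scale and
#' averaged over assays (`by = "assay"`); `by = "pooled"` pools the per-assay
#' variances and divides by the grand mean instead. Lower is better: good
#' normalization removes technical between-sample spread.
#'
#' @param nm a [NormalizedCtSet-class] (or [CtSet-class]) with >= 2 samples.
#' @param by `"assay"` (default) or `"pooled"`.
#' @return a list of class `NormalizationScore` with `method`, `meanCV`,
#'   `meanSD`.
#' @export
scoreNormalization <- function(nm, by = c("assay", "pooled")) {
    by <- match.arg(by)
    ct <- ctValues(nm)
    if (ncol(ct) < 2L) stop("scoring needs >= 2 samples")
    sds <- apply(ct, 1L, stats::sd)
    means <- rowMeans(ct)
    zero <- abs(means) < .Machine$double.eps^0.5
    if (any(zero))
        warning(sum(zero), " assay(s) with zero mean excluded from CV")
    if (by == "assay") {
        meanSD <- mean(sds)
        meanCV <- mean((sds / abs(means))[!zero])
    } else {
        meanSD <- sqrt(mean(sds^2))
        meanCV <- meanSD / abs(mean(ct))
    }
    res <- list(method = if (is(nm, "NormalizedCtSet")) nm@method else "none",
                meanCV = meanCV, meanSD = meanSD, by = by)
    class(res) <- "NormalizationScore"
    res
}

#' @export
print.NormalizationScore <- function(x, ...) {
    cat(sprintf("NormalizationScore[%s]: mean CV %.4g, mean SD %.4g (%s)\n",
                x$method, x$meanCV, x$meanSD, x$by))
    invisible(x)
}

#' Run candidate normalizations and select the best by CV then SD
#'
#' Runs every requested method, scores each with [scoreNormalization()], and
#' returns the method with minimal mean CV; ties are broken by minimal mean
#' SD, then by the fixed method order quantile, scale_rank_invariant,
#' norm_rank_invariant, geometric_mean, delta_ct. Methods that cannot run
#' (e.g. delta-Ct without control assays) are skipped with a warning.
#'
#' @inheritParams normalizeQuantile
#' @param methods character subset of the five method names.
#' @param controlAssays passed to [normalizeDeltaCt()].
#' @param by scoring mode, see [scoreNormalization()].
#' @return list with `best` (a [NormalizedCtSet-class]) and `scores` (a
#'   data.frame, one row per method, ordered as ranked).
#' @export
selectNormalization <- function(x, methods = .normMethods,
                                controlAssays = NULL, by = "assay") {
    methods <- match.arg(methods, .normMethods, several.ok = TRUE)
    runners <- list(
        quantile = function() normalizeQuantile(x),
        scale_rank_invariant = function() normalizeScaleRankInvariant(x),
        norm_rank_invariant = function() normalizeNormRankInvariant(x),
        geometric_mean = function() normalizeGeometricMean(x),
        delta_ct = function() normalizeDeltaCt(x, controlAssays))
    fits <- list()
    rows <- list()
    for (m in methods) {
        fit <- tryCatch(runners[[m]](), error = function(e) {
            warning("normalization '", m, "' skipped: ", conditionMessage(e))
            NULL
        })
        if (is.null(fit)) next
        sc <- scoreNormalization(fit, by = by)
        fits[[m]] <- fit
        rows[[m]] <- data.frame(method = m, meanCV = sc$meanCV,
                                meanSD = sc$meanSD,
                                effectiveMethod = fit@method)
    }
    if (!length(fits)) stop("no normalization method could be run")
    scores <- do.call(rbind, rows)
    ord <- order(scores$meanCV, scores$meanSD,
                 match(scores$method, .normMethods))
    scores <- scores[ord, , drop = FALSE]
    rownames(scores) <- NULL
    list(best = fits[[scores$method[1L]]], scores = scores)
}
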