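`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-stage seed derivation from one global seed, so a stage can
# be rerun in isolation with the same stream. Kept inside 32-bit range.
deriveSeed <- function(seed, stage) {
    h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
    as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

# Logistic fit that survives perfect separation: ordinary glm first, and if it
# warns about fitted probabilities of 0/1 (or fails), a ridge-stabilized fit
# with a tiny L2 penalty. Returns intercept + named coefficients + flag.
stableLogisticFit <- function(X, y, ridgeLambda = 1e-4) {
    X <- as.matrix(X)
    y <- as.numeric(y)
    sep <- FALSE
    fit <- withCallingHandlers(
        stats::glm.fit(cbind(1, X), y, family = stats::binomial()),
        warning = function(w) {
            sep <<- TRUE
            invokeRestart("muffleWarning")
        })
    co <- fit$coefficients
    if (sep || anyNA(co)) {
        # glmnet warns about small class counts; the fallback is already
        # flagged via `ridged`
        gfit <- suppressWarnings(
            glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                           lambda = ridgeLambda, standardize = FALSE))
        co <- c(as.numeric(gfit$a0), as.numeric(gfit$beta))
        sep <- TRUE
    }
    list(intercept = co[1L],
         coefficients = stats::setNames(co[-1L], colnames(X)),
         ridged = sep)
}

predictLogistic <- function(fit, X) {
    X <- as.matrix(X)
    as.numeric(stats::plogis(fit$intercept +
                             X %*% fit$coefficients[colnames(X)]))
}
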