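#' Configuration for the full discovery-to-validation pipeline
#'
#' Bundles cohort sources with every stage's tuning parameters. Each cohort
#' is either a [simConfig()] (simulated at run time) or a list
#' `list(ctPath =, samplePath =, spikeins =)` of files on disk.
#'
#' @param discovery discovery-cohort source (required).
#' @param validation validation-cohort source, or `NULL` to stop after the
#'   discovery evaluation.
#' @param ctMax,informativePolicy,informativeQ informativeness filter (see
#'   [filterInformative()]).
#' @param normalization `"auto"` (CV/SD selection over all five methods) or
#'   one method name.
#' @param fcMin,alpha differential-expression thresholds.
#' @param cvFolds folds for the penalty cross-validation.
#' @param bootstrapB bootstrap-stability resamples (0 skips the stage).
#' @param nullM random-signature null models (0 skips the stage).
#' @param prBootReps bootstrap replicates for PR-curve CIs.
#' @param seed global seed; per-stage seeds are derived from it.
#' @param outDir directory for artifacts, or `NULL` to keep results in
#'   memory only.
#' @return a validated `PipelineConfig` list.
#' @export
pipelineConfig <- function(discovery, validation = NULL, ctMax = 33,
                           informativePolicy = "all", informativeQ = 0.75,
                           normalization = "auto", fcMin = 2, alpha = 0.05,
                           cvFolds = 10L, bootstrapB = 10000L,
                           nullM = 1000L, prBootReps = 2000L, seed = 1L,
                           outDir = NULL) {
    stopifnot(ctMax > 0, fcMin >= 1, alpha > 0, alpha <= 1, cvFolds >= 2,
              bootstrapB >= 0, nullM >= 0, prBootReps >= 0)
    if (!identical(normalization, "auto"))
        normalization <- match.arg(normalization, .normMethods)
    cfg <- list(discovery = discovery, validation = validation,
                ctMax = ctMax, informativePolicy = informativePolicy,
                informativeQ = informativeQ, normalization = normalization,
                fcMin = fcMin, alpha = alpha, cvFolds = as.integer(cvFolds),
                bootstrapB = as.integer(bootstrapB),
                nullM = as.integer(nullM),
                prBootReps = as.integer(prBootReps),
                seed = as.integer(seed), outDir = outDir)
    class(cfg) <- "PipelineConfig"
    cfg
}

loadCohort <- function(source, seedOverride = NULL) {
    if (inherits(source, "SimConfig")) {
        if (!is.null(seedOverride)) source$seed <- seedOverride
        simulateCohort(source)$ctSet
    } else if (inherits(source, "SyntheticCohort")) {
        source$ctSet
    } else if (is(source, "CtSet")) {
        source
    } else if (is.list(source) && !is.null(source$ctPath)) {
        sheet <- if (!is.null(source$samplePath))
            readSampleSheet(source$samplePath) else NULL
        readCtMatrix(source$ctPath, sampleData = sheet,
                     spikeins = source$spikeins %||% character())
    } else stop("cohort source must be a SimConfig, SyntheticCohort, CtSet ",
                "or list(ctPath=, samplePath=)")
}

preprocessCohort <- function(x, config) {
    x <- hemolysisQc(x)
    x <- dropQcFailures(x)
    x <- imputeUndetermined(x)
    filterInformative(x, ctMax = config$ctMax,
                      policy = config$informativePolicy,
                      q = config$informativeQ)
}

normalizeCohort <- function(x, config) {
    if (identical(config$normalization, "auto")) {
        sel <- selectNormalization(x)
        list(nm = sel$best, scores = sel$scores)
    } else {
        fn <- switch(config$normalization,
                     quantile = normalizeQuantile,
                     scale_rank_invariant = normalizeScaleRankInvariant,
                     norm_rank_invariant = normalizeNormRankInvariant,
                     geometric_mean = normalizeGeometricMean,
                     delta_ct = normalizeDeltaCt)
        list(nm = fn(x), scores = NULL)
    }
}

#' Run the full signature-discovery pipeline
#'
#' Executes, in order: cohort loading/simulation, hemolysis QC and sample
#' exclusion, Undetermined imputation, informativeness filtering,
#' normalization (method selection or fixed), delta-delta-Ct differential
#' expression, LASSO signature selection with stratified k-fold CV and the
#' one-standard-error rule, optional bootstrap stability, leave-one-out
#' cross-validated discovery evaluation with the FPR-minimizing threshold,
#' and - when a validation cohort is given - fixed-signature validation
#' with a recalibrated cohort-specific threshold plus the optional
#' random-signature null. Every stage records its seed and warnings in the
#' returned manifest; artifacts are written under `config$outDir` when set.
#'
#' @param config a [pipelineConfig()].
#' @return a `PipelineManifest` list: `config`, `stages` (per-stage records)
#'   and `results` (model, tables, reports).
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    manifest <- list(config = config, stages = list(), results = list())
    t0 <- proc.time()[["elapsed"]]
    addStage <- function(name, seed = NA_integer_, warnings = character(),
                         status = "done", note = NULL) {
        manifest$stages[[name]] <<- list(
            stage = name, seed = seed, status = status,
            warnings = warnings, note = note,
            elapsed = proc.time()[["elapsed"]] - t0)
    }
    collect <- function(expr) {
        warns <- character()
        val <- withCallingHandlers(expr, warning = function(w) {
            warns <<- c(warns, conditionMessage(w))
            invokeRestart("muffleWarning")
        })
        list(value = val, warnings = warns)
    }
    out <- if (!is.null(config$outDir)) {
        dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
        config$outDir
    } else NULL

    # --- discovery cohort -------------------------------------------------
    seedDisc <- deriveSeed(config$seed, "discovery")
    disc <- collect(loadCohort(config$discovery, seedOverride = if (
        inherits(config$discovery, "SimConfig")) seedDisc else NULL))
    addStage("load_discovery", seedDisc, disc$warnings)

    pp <- collect(preprocessCohort(disc$value, config))
    addStage("preprocess", warnings = pp$warnings,
             note = list(kept = nrow(pp$value),
                         samples = ncol(pp$value),
                         imputed = metadata(pp$value)$imputed))
    if (!is.null(out))
        writeCtMatrix(pp$value, file.path(out, "discovery_filtered.tsv"))

    nrm <- collect(normalizeCohort(pp$value, config))
    addStage("normalize", warnings = nrm$warnings,
             note = list(method = nrm$value$nm@method,
                         scores = nrm$value$scores))
    nm <- nrm$value$nm
    if (!is.null(out)) {
        writeCtMatrix(nm, file.path(out, "discovery_normalized.tsv"))
        if (!is.null(nrm$value$scores))
            utils::write.csv(nrm$value$scores,
                             file.path(out, "normalization_scores.csv"),
                             row.names = FALSE)
    }
    manifest$results$normalizationScores <- nrm$value$scores

    de <- collect(differentialExpression(nm, fcMin = config$fcMin,
                                         alpha = config$alpha))
    candidates <- deAssays(de$value)
    addStage("differential_expression", warnings = de$warnings,
             note = list(nDe = length(candidates)))
    manifest$results$diffExpr <- de$value
    if (!is.null(out))
        utils::write.csv(de$value, file.path(out, "diffexpr.csv"),
                         row.names = FALSE)

    X <- t(ctValues(nm))[, candidates, drop = FALSE]
    y <- sampleGroups(nm)
    seedCv <- deriveSeed(config$seed, "lasso_cv")
    if (length(candidates) < 2L) {
        addStage("signature", seedCv, status = "degenerate",
                 warnings = paste(length(candidates),
                                  "DE assays; LASSO not run"))
        model <- new("SignatureModel", assays = character(),
                     coefficients = numeric(), coefficientsRaw = numeric(),
                     intercept = 0, interceptRaw = 0,
                     lambdaGrid = numeric(), lambdaMin = NA_real_,
                     lambda1se = NA_real_,
                     cvError = data.frame(lambda = numeric(),
                                          cvm = numeric(),
                                          cvsd = numeric()),
                     center = numeric(), scale = numeric())
    } else {
        sig <- collect({
            path <- fitLassoPath(X, y)
            cv <- selectLambda1se(path, k = config$cvFolds, seed = seedCv)
            extractSignature(path, cv)
        })
        model <- sig$value
        addStage("signature", seedCv, sig$warnings,
                 note = list(assays = signatureAssays(model)))
    }

    # --- bootstrap stability ---------------------------------------------
    if (config$bootstrapB > 0L && length(signatureAssays(model))) {
        seedBoot <- deriveSeed(config$seed, "stability")
        st <- collect(bootstrapStability(X, y, model,
                                         B = config$bootstrapB,
                                         seed = seedBoot,
                                         k = config$cvFolds))
        addStage("stability", seedBoot, st$warnings,
                 note = list(pValue = st$value$pValue))
        manifest$results$stability <- st$value
    } else addStage("stability", status = "skipped")

    # --- discovery evaluation (LOOCV) ------------------------------------
    seedEval <- deriveSeed(config$seed, "evaluate_discovery")
    if (length(signatureAssays(model))) {
        ev <- collect({
            probs <- loocvProbabilities(X, y, signatureAssays(model))
            evalReport(probs, y, bootReps = config$prBootReps,
                       seed = seedEval)
        })
        model@threshold <- ev$value$threshold
        addStage("evaluate_discovery", seedEval, ev$warnings,
                 note = list(auc = ev$value$roc$auc,
                             accuracy = ev$value$metrics$accuracy))
        manifest$results$discoveryEval <- ev$value
    } else addStage("evaluate_discovery", status = "skipped",
                    warnings = "empty signature")
    manifest$results$model <- model
    if (!is.null(out)) writeSignatureModel(model, file.path(out,
                                                            "model.json"))

    # --- validation cohort ------------------------------------------------
    if (is.null(config$validation)) {
        addStage("validation", status = "skipped")
        addStage("random_null", status = "skipped")
    } else if (!length(signatureAssays(model))) {
        addStage("validation", status = "skipped",
                 warnings = "empty signature")
        addStage("random_null", status = "skipped")
    } else {
        seedVal <- deriveSeed(config$seed, "validation")
        val <- collect({
            v <- loadCohort(config$validation, seedOverride = if (
                inherits(config$validation, "SimConfig")) seedVal else NULL)
            v <- preprocessCohort(v, config)
            # the validation cohort is normalized independently with the
            # method chosen on discovery data
            cfgV <- config
            cfgV$normalization <- nm@method
            normalizeCohort(v, cfgV)$nm
        })
        vm <- val$value
        keep <- intersect(signatureAssays(model), rownames(vm))
        if (length(keep) < length(signatureAssays(model))) {
            addStage("validation", seedVal, status = "failed",
                     warnings = paste("signature assays lost in validation",
                                      "preprocessing"))
            addStage("random_null", status = "skipped")
        } else {
            XV <- t(ctValues(vm))
            yV <- sampleGroups(vm)
            evv <- collect(evaluateOnCohort(model, XV, yV,
                                            recalibrateThreshold = TRUE,
                                            bootReps = config$prBootReps,
                                            seed = deriveSeed(config$seed,
                                                              "pr_val")))
            addStage("validation", seedVal, c(val$warnings, evv$warnings),
                     note = list(auc = evv$value$roc$auc,
                                 accuracy = evv$value$metrics$accuracy))
            manifest$results$validationEval <- evv$value

            if (config$nullM > 0L) {
                seedNull <- deriveSeed(config$seed, "random_null")
                pool <- intersect(colnames(X), rownames(vm))
                nul <- collect(randomSignatureNull(
                    X[, pool, drop = FALSE], y,
                    XV[, pool, drop = FALSE], yV,
                    size = length(signatureAssays(model)), pool = pool,
                    M = config$nullM, seed = seedNull,
                    observedAccuracy = evv$value$metrics$accuracy))
                addStage("random_null", seedNull, nul$warnings,
                         note = list(pValue = nul$value$pValue))
                manifest$results$null <- nul$value
            } else addStage("random_null", status = "skipped")
        }
    }
    class(manifest) <- "PipelineManifest"
    if (!is.null(out))
        writeLines(makeReport(manifest), file.path(out, "report.txt"))
    manifest
}

fmtMetric <- function(v) {
    if (is.null(v) || length(v) == 0 || is.na(v)) "not run"
    else sprintf("%.2f", v)
}

#' Render a human-readable summary of a pipeline run
#'
#' One table per evaluated cohort with accuracy, sensitivity, specificity,
#' positive/negative prediction rates and the ROC/PR AUCs with CIs, plus
#' the stability and random-null p-values. Purely a formatting step: every
#' number comes from the stored manifest.
#'
#' @param manifest a [runPipeline()] result.
#' @return character vector of report lines.
#' @export
makeReport <- function(manifest) {
    stopifnot(inherits(manifest, "PipelineManifest"))
    res <- manifest$results
    lines <- c("microRNA signature pipeline report",
               paste0("seed: ", manifest$config$seed))
    model <- res$model
    if (!is.null(model)) {
        sig <- signatureAssays(model)
        lines <- c(lines, paste0("signature (", length(sig), " assays): ",
                                 if (length(sig))
                                     paste(sig, collapse = ", ") else "-"))
    }
    block <- function(label, ev) {
        if (is.null(ev)) return(character())
        m <- ev$metrics
        c(paste0("-- ", label, " --"),
          sprintf("  Accuracy                 %s", fmtMetric(m$accuracy)),
          sprintf("  Sensitivity              %s", fmtMetric(m$sensitivity)),
          sprintf("  Specificity              %s", fmtMetric(m$specificity)),
          sprintf("  Positive Prediction Rate %s", fmtMetric(m$ppv)),
          sprintf("  Negative Prediction Rate %s", fmtMetric(m$npv)),
          sprintf("  AUC ROC (95%% CI)         %s (%s, %s)",
                  fmtMetric(ev$roc$auc), fmtMetric(ev$roc$ci[1L]),
                  fmtMetric(ev$roc$ci[2L])),
          sprintf("  AUC PR (95%% CI)          %s (%s, %s)",
                  fmtMetric(ev$pr$auc), fmtMetric(ev$pr$ci[1L]),
                  fmtMetric(ev$pr$ci[2L])))
    }
    lines <- c(lines, block("discovery cohort", res$discoveryEval),
               block("validation cohort", res$validationEval))
    lines <- c(lines,
               paste0("stability p-value: ",
                      if (is.null(res$stability)) "not run"
                      else sprintf("%.4g", res$stability$pValue)),
               paste0("random-signature null p-value: ",
                      if (is.null(res$null)) "not run"
                      else sprintf("%.4g", res$null$pValue)))
    lines
}

#' @export
print.PipelineManifest <- function(x, ...) {
    cat("PipelineManifest with stages:\n")
    for (s in x$stages)
        cat(sprintf("  %-24s %s%s\n", s$stage, s$status,
                    if (length(s$warnings))
                        paste0(" [", length(s$warnings), " warning(s)]")
                    else ""))
    invisible(x)
}
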