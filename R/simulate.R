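#' Configuration for synthetic qPCR cohort simulation
#'
#' Defines the generative model for a synthetic RT-qPCR array cohort:
#' per-assay baseline Ct values, a small set of planted group-differential
#' assays, per-sample global Ct offsets (library/loading effects), Gaussian
#' measurement noise, right-censoring of weak signals as Undetermined,
#' offset-free spike-in assays, and optional hemolyzed samples detectable
#' from the miR-23a/miR-451 Ct difference.
#'
#' Effects are in delta-Ct cycles with positive = up-regulated in patients
#' (lower Ct, since expression is proportional to `2^-Ct`).
#'
#' @param nAssays total number of assays on the panel (default 754, the size
#'   of a TaqMan advanced human miRNA card pair).
#' @param nPatients,nControls group sizes (defaults 16 and 22).
#' @param signatureAssays named numeric vector: names are planted assay
#'   names, values their group effects in cycles.
#' @param baselineCtRange range of per-assay baseline Ct values (uniform).
#' @param signatureBaselineRange baseline range for the planted assays; kept
#'   inside the well-detected region so planted biomarkers are not censored
#'   away.
#' @param sampleOffsetSd SD (cycles) of the per-sample global Ct shift.
#' @param noiseSd SD (cycles) of per-measurement Gaussian noise.
#' @param censorInformativeAt Ct above which an assay counts as not expressed
#'   (used downstream by [filterInformative()]).
#' @param censorUndeterminedAt Ct above which a reaction is recorded as
#'   Undetermined.
#' @param nSpikeins number of spike-in assays (zero group effect, zero sample
#'   offset).
#' @param hemolysisFraction proportion of samples simulated as hemolyzed.
#' @param seed integer RNG seed.
#' @return a `SimConfig` list.
#' @export
simConfig <- function(nAssays = 754L, nPatients = 16L, nControls = 22L,
                      signatureAssays = c("miR-412-3p" = 3, "miR-507" = 3,
                                          "miR-1203" = 3, "miR-362-3p" = -3),
                      baselineCtRange = c(20, 33),
                      signatureBaselineRange = c(22, 27),
                      sampleOffsetSd = 0.5, noiseSd = 0.5,
                      censorInformativeAt = 33, censorUndeterminedAt = 40,
                      nSpikeins = 3L, hemolysisFraction = 0, seed = 1L) {
    cfg <- list(nAssays = as.integer(nAssays),
                nPatients = as.integer(nPatients),
                nControls = as.integer(nControls),
                signatureAssays = signatureAssays,
                baselineCtRange = as.numeric(baselineCtRange),
                signatureBaselineRange = as.numeric(signatureBaselineRange),
                sampleOffsetSd = as.numeric(sampleOffsetSd),
                noiseSd = as.numeric(noiseSd),
                censorInformativeAt = as.numeric(censorInformativeAt),
                censorUndeterminedAt = as.numeric(censorUndeterminedAt),
                nSpikeins = as.integer(nSpikeins),
                hemolysisFraction = as.numeric(hemolysisFraction),
                seed = as.integer(seed))
    class(cfg) <- "SimConfig"
    validateSimConfig(cfg)
    cfg
}

validateSimConfig <- function(cfg) {
    stopifnot(cfg$nAssays >= 0, cfg$nPatients >= 0, cfg$nControls >= 0,
              cfg$sampleOffsetSd >= 0, cfg$noiseSd >= 0, cfg$nSpikeins >= 0,
              cfg$hemolysisFraction >= 0, cfg$hemolysisFraction <= 1)
    if (cfg$censorInformativeAt >= cfg$censorUndeterminedAt)
        stop("censorInformativeAt must be < censorUndeterminedAt")
    if (anyDuplicated(names(cfg$signatureAssays)))
        stop("signature assay names must be unique")
    nFixed <- length(cfg$signatureAssays) + cfg$nSpikeins + 2L
    if (nFixed > cfg$nAssays)
        stop("signature + spike-in + marker assays exceed nAssays")
    invisible(cfg)
}

.spikeinNames <- c("ath-miR-159a", "cel-miR-254", "osa-miR-414")
.hemolysisMarkers <- c("miR-23a", "miR-451")

simAssayNames <- function(cfg) {
    planted <- names(cfg$signatureAssays)
    spikes <- if (cfg$nSpikeins <= 3L) .spikeinNames[seq_len(cfg$nSpikeins)]
              else c(.spikeinNames,
                     sprintf("spike-in-%02d", seq_len(cfg$nSpikeins - 3L)))
    fixed <- c(planted, spikes, .hemolysisMarkers)
    filler <- sprintf("miR-%04d", seq_len(cfg$nAssays - length(fixed)))
    list(all = c(fixed, filler), planted = planted, spikes = spikes)
}

#' Simulate a synthetic qPCR discovery cohort
#'
#' Generates `Ct[f, s] = baseline[f] - effect[f] * is_patient[s] + offset[s]
#' + noise`, with spike-in assays exempt from group effect and sample offset,
#' right-censoring above `censorUndeterminedAt` recorded as Undetermined, and
#' hemolyzed samples given a lowered miR-451 Ct so the miR-23a - miR-451
#' difference exceeds the hemolysis failure threshold. Output is
#' bit-identical for identical config (the seed is part of the config).
#'
#' @param config a [simConfig()] object.
#' @return a `SyntheticCohort`: list with elements `ctSet` (a
#'   [CtSet-class]) and `truth` (planted assays, effects, baselines,
#'   hemolyzed sample IDs).
#' @export
simulateCohort <- function(config) {
    validateSimConfig(config)
    nm <- simAssayNames(config)
    withSeed(config$seed, {
        baseline <- stats::setNames(
            stats::runif(config$nAssays, config$baselineCtRange[1L],
                         config$baselineCtRange[2L]), nm$all)
        if (length(nm$planted))
            baseline[nm$planted] <- stats::runif(
                length(nm$planted), config$signatureBaselineRange[1L],
                config$signatureBaselineRange[2L])
        if (length(nm$spikes))
            baseline[nm$spikes] <- stats::runif(
                length(nm$spikes), config$baselineCtRange[1L],
                config$baselineCtRange[1L] + 4)
        baseline[.hemolysisMarkers] <- stats::runif(2L, 24, 28)
        truth <- list(assays = nm$planted,
                      effects = config$signatureAssays,
                      baselines = baseline, spikeins = nm$spikes,
                      censorUndeterminedAt = config$censorUndeterminedAt)
        cohort <- simSamples(config, truth, cohortName = "discovery")
        cohort
    })
}

#' Simulate a validation cohort sharing a discovery cohort's truth
#'
#' New samples are drawn over the same assay universe with the same planted
#' assays and (optionally overridden) effects, but fresh per-sample offsets
#' and noise under the new config's seed.
#'
#' @param config a [simConfig()]; `nAssays` must match the truth's universe.
#' @param truth the `truth` element of a [simulateCohort()] result.
#' @param effects optional named numeric overriding the planted effects.
#' @return a `SyntheticCohort` (cohort tag `"validation"`).
#' @export
simulateValidationCohort <- function(config, truth, effects = NULL) {
    validateSimConfig(config)
    if (config$nAssays != length(truth$baselines))
        stop("assay universe mismatch: config has ", config$nAssays,
             " assays, truth has ", length(truth$baselines))
    if (!all(truth$assays %in% names(truth$baselines)))
        stop("truth assays not contained in the assay universe")
    if (!is.null(effects)) {
        if (!identical(sort(names(effects)), sort(names(truth$effects))))
            stop("effects override must cover exactly the planted assays")
        truth$effects <- effects[names(truth$effects)]
    }
    withSeed(config$seed, simSamples(config, truth,
                                     cohortName = "validation"))
}

# Shared sample generator: assumes RNG already seeded and truth fixed.
simSamples <- function(config, truth, cohortName) {
    nS <- config$nPatients + config$nControls
    assays <- names(truth$baselines)
    ids <- c(sprintf("P%02d", seq_len(config$nPatients)),
             sprintf("C%02d", seq_len(config$nControls)))
    group <- rep(c("patient", "control"),
                 c(config$nPatients, config$nControls))
    effect <- stats::setNames(numeric(length(assays)), assays)
    effect[truth$assays] <- truth$effects[truth$assays]
    isSpike <- assays %in% truth$spikeins
    offsets <- stats::rnorm(nS, 0, config$sampleOffsetSd)
    isPat <- as.numeric(group == "patient")
    ct <- truth$baselines - outer(effect, isPat) +
        outer(!isSpike, offsets) +
        matrix(stats::rnorm(length(assays) * nS, 0, config$noiseSd),
               length(assays), nS)
    dimnames(ct) <- list(assays, ids)
    nHem <- round(config$hemolysisFraction * nS)
    hemolyzed <- character()
    if (nHem > 0) {
        hemolyzed <- sample(ids, nHem)
        ok <- setdiff(ids, hemolyzed)
        # hemolysis releases red-blood-cell miR-451: shift its Ct down so
        # that Ct(miR-23a) - Ct(miR-451) lands above the failure threshold
        ct["miR-451", hemolyzed] <- ct["miR-23a", hemolyzed] -
            stats::runif(nHem, 7.5, 10)
        ct["miR-451", ok] <- ct["miR-23a", ok] -
            stats::runif(length(ok), 1, 4)
    }
    ct[ct > truth$censorUndeterminedAt] <- NA_real_
    sheet <- data.frame(sample_id = ids, group = group,
                        cohort = rep(cohortName, nS),
                        stringsAsFactors = FALSE)
    cohort <- list(ctSet = CtSet(ct, sampleData = sheet,
                                 spikeins = truth$spikeins),
                   truth = c(truth, list(hemolyzed = hemolyzed)))
    class(cohort) <- "SyntheticCohort"
    cohort
}

#' @export
print.SyntheticCohort <- function(x, ...) {
    cat("SyntheticCohort:", length(x$truth$assays), "planted assays (",
        paste(x$truth$assays, collapse = ", "), ")\n")
    show(x$ctSet)
    invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes the Ct matrix (tab-delimited, `"Undetermined"` tokens), the sample
#' sheet (CSV) and the planted truth (JSON) into a directory.
#'
#' @param cohort a `SyntheticCohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeCtMatrix(cohort$ctSet, file.path(dir, "ct_matrix.tsv"))
    writeSampleSheet(cohort$ctSet, file.path(dir, "sample_sheet.csv"))
    jsonlite::write_json(
        list(assays = cohort$truth$assays,
             effects = as.list(cohort$truth$effects),
             spikeins = cohort$truth$spikeins,
             hemolyzed = cohort$truth$hemolyzed),
        file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    invisible(dir)
}
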