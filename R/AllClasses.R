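#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- rowData
#'   rowData<- colData colData<-
#' @importFrom S4Vectors metadata metadata<- DataFrame
NULL

#' CtSet: a container for qPCR cycle-threshold matrices
#'
#' `CtSet` extends [SummarizedExperiment::SummarizedExperiment] with a single
#' assay `"ct"` holding cycle-threshold values (PCR cycles) for microRNA
#' assays (rows) by samples (columns). Reactions that never crossed the
#' detection threshold ("Undetermined" on TaqMan-style instruments) are stored
#' as `NA` until [imputeUndetermined()] assigns them a fixed Ct.
#'
#' Row metadata carries a logical `spikein` column flagging synthetic spike-in
#' assays; column metadata carries the sample sheet (`group`, `cohort`,
#' `hemolysis_delta`, `hemolysis_flag`, `qc_pass`).
#'
#' @slot .  inherits all slots from `SummarizedExperiment`.
#' @export
setClass("CtSet", contains = "SummarizedExperiment")

.validCtSet <- function(object) {
    msg <- character()
    if (!"ct" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'ct' is required")
    else {
        ct <- assay(object, "ct")
        if (!is.numeric(ct))
            msg <- c(msg, "assay 'ct' must be numeric (NA = Undetermined)")
        else {
            vals <- ct[!is.na(ct)]
            if (length(vals) && any(!is.finite(vals)))
                msg <- c(msg, "Ct values must be finite")
            # raw Ct is a cycle count; normalized scales (e.g. delta-Ct)
            # may go negative
            if (!is(object, "NormalizedCtSet") && length(vals) &&
                any(vals < 0))
                msg <- c(msg, "Ct values must be >= 0")
        }
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate assay names")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample IDs")
    if (length(msg)) msg else TRUE
}
setValidity("CtSet", .validCtSet)

#' Construct a CtSet
#'
#' @param ct numeric matrix of Ct values, assays in rows, samples in columns;
#'   `NA` encodes Undetermined reactions. Dimnames are required.
#' @param sampleData optional `data.frame`/`DataFrame` of per-sample
#'   annotation. Recognised columns: `group` (`"patient"`/`"control"`),
#'   `cohort`, `hemolysis_delta`, `qc_pass`. Either rownames or a
#'   `sample_id` column must match `colnames(ct)`.
#' @param spikeins character vector of assay names to flag as spike-ins.
#'
#' @return a [CtSet-class] object.
#' @examples
#' ct <- matrix(c(24, 25, NA, 30), 2, 2,
#'              dimnames = list(c("miR-a", "miR-b"), c("s1", "s2")))
#' CtSet(ct, sampleData = data.frame(sample_id = c("s1", "s2"),
#'                                   group = c("patient", "control")))
#' @export
CtSet <- function(ct, sampleData = NULL, spikeins = character()) {
    ct <- as.matrix(ct)
    storage.mode(ct) <- "double"
    if (is.null(rownames(ct)) || (ncol(ct) > 0 && is.null(colnames(ct))))
        stop("'ct' must have assay rownames and sample colnames")
    cd <- DataFrame(row.names = colnames(ct))
    cd$group <- factor(rep(NA_character_, ncol(ct)),
                       levels = c("control", "patient"))
    cd$cohort <- rep(NA_character_, ncol(ct))
    cd$hemolysis_delta <- rep(NA_real_, ncol(ct))
    cd$hemolysis_flag <- rep(NA_character_, ncol(ct))
    cd$qc_pass <- rep(TRUE, ncol(ct))
    if (!is.null(sampleData)) {
        sampleData <- as.data.frame(sampleData)
        if (!is.null(sampleData$sample_id))
            rownames(sampleData) <- sampleData$sample_id
        missing <- setdiff(colnames(ct), rownames(sampleData))
        if (length(missing))
            stop("sampleData lacks rows for samples: ",
                 paste(missing, collapse = ", "))
        sampleData <- sampleData[colnames(ct), , drop = FALSE]
        if (!is.null(sampleData$group))
            cd$group <- factor(as.character(sampleData$group),
                               levels = c("control", "patient"))
        for (col in c("cohort", "hemolysis_delta", "hemolysis_flag"))
            if (!is.null(sampleData[[col]])) cd[[col]] <- sampleData[[col]]
        if (!is.null(sampleData$qc_pass))
            cd$qc_pass <- as.logical(sampleData$qc_pass)
    }
    rd <- DataFrame(row.names = rownames(ct))
    rd$spikein <- rownames(ct) %in% spikeins
    new("CtSet", SummarizedExperiment(assays = list(ct = ct),
                                      rowData = rd, colData = cd))
}

#' NormalizedCtSet: a CtSet after normalization
#'
#' Adds the normalization method name and its parameters to a [CtSet-class].
#' The method is one of `"quantile"`, `"scale_rank_invariant"`,
#' `"norm_rank_invariant"`, `"geometric_mean"`, `"delta_ct"`.
#'
#' @slot method character, normalization method applied.
#' @slot methodParams list of parameters the method used (including any
#'   fallback taken).
#' @export
setClass("NormalizedCtSet", contains = "CtSet",
         representation(method = "character", methodParams = "list"))

.normMethods <- c("quantile", "scale_rank_invariant", "norm_rank_invariant",
                  "geometric_mean", "delta_ct")

setValidity("NormalizedCtSet", function(object) {
    if (length(object@method) != 1L || !object@method %in% .normMethods)
        paste("method must be one of:", paste(.normMethods, collapse = ", "))
    else TRUE
})

#' SignatureModel: a sparse logistic microRNA signature
#'
#' Holds the result of L1-penalized logistic signature selection: the assays
#' with nonzero coefficients at the one-standard-error penalty, the logistic
#' coefficients on both the standardized and the raw Ct scale, the penalty
#' grid and cross-validation summary, and (once evaluated) the decision
#' threshold. The positive class is `patient`; predicted probability is
#' `plogis(interceptRaw + sum(coefficientsRaw * ct))`.
#'
#' @slot assays character, signature assay names ordered by decreasing
#'   absolute standardized coefficient.
#' @slot coefficients named numeric, coefficients per standard deviation of
#'   the training Ct values.
#' @slot coefficientsRaw named numeric, coefficients per Ct cycle.
#' @slot intercept numeric, intercept on the standardized scale.
#' @slot interceptRaw numeric, intercept on the raw Ct scale.
#' @slot lambdaGrid numeric, the penalty path (decreasing).
#' @slot lambdaMin,lambda1se numeric, CV-minimal and one-SE penalties.
#' @slot cvError data.frame with columns `lambda`, `cvm`, `cvsd`.
#' @slot center,scale named numeric, training mean/SD per signature assay.
#' @slot threshold numeric, decision threshold on the probability scale
#'   (`NA` until set by evaluation).
#' @slot seed integer, CV fold seed.
#' @export
setClass("SignatureModel",
         representation(assays = "character", coefficients = "numeric",
                        coefficientsRaw = "numeric", intercept = "numeric",
                        interceptRaw = "numeric", lambdaGrid = "numeric",
                        lambdaMin = "numeric", lambda1se = "numeric",
                        cvError = "data.frame", center = "numeric",
                        scale = "numeric", threshold = "numeric",
                        seed = "integer"),
         prototype(threshold = NA_real_, seed = NA_integer_))

setValidity("SignatureModel", function(object) {
    msg <- character()
    if (!identical(object@assays, names(object@coefficientsRaw)))
        msg <- c(msg, "assays must equal names(coefficientsRaw)")
    if (length(object@coefficients) != length(object@coefficientsRaw))
        msg <- c(msg, "coefficient vectors differ in length")
    if (length(object@lambda1se) == 1 && length(object@lambdaMin) == 1 &&
        !is.na(object@lambda1se) && object@lambda1se < object@lambdaMin)
        msg <- c(msg, "lambda1se must be >= lambdaMin")
    if (length(msg)) msg else TRUE
})
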