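#' @describeIn CtSet-class Ct value matrix (`NA` = Undetermined).
#' @param x,object a `CtSet`.
#' @export
ctValues <- function(x) assay(x, "ct")

#' @describeIn CtSet-class per-sample group factor (`control`/`patient`).
#' @export
sampleGroups <- function(x) colData(x)$group

#' @describeIn CtSet-class logical, which assays are spike-ins.
#' @export
isSpikein <- function(x) {
    sp <- rowData(x)$spikein
    if (is.null(sp)) sp <- rep(FALSE, nrow(x))
    stats::setNames(as.logical(sp), rownames(x))
}

#' @describeIn CtSet-class number of Undetermined (censored) entries.
#' @export
nUndetermined <- function(x) sum(is.na(ctValues(x)))

#' @describeIn CtSet-class the sample sheet as a data.frame.
#' @export
sampleSheet <- function(x) {
    df <- as.data.frame(colData(x))
    df <- cbind(sample_id = rownames(df), df)
    rownames(df) <- NULL
    df
}

setMethod("show", "CtSet", function(object) {
    cat(class(object), "with", nrow(object), "assays x", ncol(object),
        "samples\n")
    grp <- table(sampleGroups(object), useNA = "no")
    if (sum(grp)) cat("  groups:",
                      paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
    cat("  undetermined entries:", nUndetermined(object), "\n")
    cat("  spike-ins:", sum(isSpikein(object)), "\n")
    if (is(object, "NormalizedCtSet"))
        cat("  normalized by:", object@method, "\n")
    invisible(NULL)
})

#' @describeIn NormalizedCtSet-class the normalization method used.
#' @param x a `NormalizedCtSet`.
#' @export
normMethod <- function(x) {
    stopifnot(is(x, "NormalizedCtSet"))
    x@method
}

#' @describeIn SignatureModel-class signature assay names.
#' @param x a `SignatureModel`.
#' @export
signatureAssays <- function(x) x@assays

#' @describeIn SignatureModel-class signature coefficients.
#' @param scale `"raw"` (per Ct cycle) or `"standardized"` (per training SD).
#' @export
signatureCoefficients <- function(x, scale = c("raw", "standardized")) {
    scale <- match.arg(scale)
    if (scale == "raw") x@coefficientsRaw else x@coefficients
}

setMethod("show", "SignatureModel", function(object) {
    cat("SignatureModel with", length(object@assays), "assays\n")
    if (length(object@assays)) {
        co <- object@coefficientsRaw
        for (a in object@assays)
            cat(sprintf("  %-14s %+.4f (raw Ct scale)\n", a, co[[a]]))
    }
    cat(sprintf("  intercept (raw): %.4f\n", object@interceptRaw))
    cat(sprintf("  lambda: min %.4g, 1se %.4g\n",
                object@lambdaMin, object@lambda1se))
    if (!is.na(object@threshold))
        cat(sprintf("  decision threshold: %.4f\n", object@threshold))
    invisible(NULL)
})
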