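#' Read a Ct matrix from tab-delimited text
#'
#' The expected dialect is that of TaqMan-style array exports: a header row of
#' sample IDs, a first column of assay names, and one Ct value per cell. The
#' token `"Undetermined"` (case-insensitive) marks reactions that never
#' crossed the detection threshold and is stored as the censored state (`NA`)
#' until [imputeUndetermined()].
#'
#' @param path path to the tab-delimited file.
#' @param sampleData optional sample sheet (see [CtSet()]).
#' @param spikeins assay names to flag as spike-ins.
#' @return a [CtSet-class].
#' @seealso [writeCtMatrix()], [readSampleSheet()]
#' @export
readCtMatrix <- function(path, sampleData = NULL, spikeins = character()) {
    if (!file.exists(path)) stop("file not found: ", path)
    raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             colClasses = "character")
    if (ncol(raw) < 1L) stop("no columns parsed from ", path)
    assays <- raw[[1L]]
    if (anyDuplicated(assays))
        stop("duplicate assay names: ",
             paste(unique(assays[duplicated(assays)]), collapse = ", "))
    samples <- colnames(raw)[-1L]
    if (anyDuplicated(samples))
        stop("duplicate sample IDs: ",
             paste(unique(samples[duplicated(samples)]), collapse = ", "))
    cells <- as.matrix(raw[, -1L, drop = FALSE])
    undet <- tolower(trimws(cells)) == "undetermined"
    num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
    bad <- which(!undet & is.na(num) & !is.na(cells), arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("non-numeric Ct value '%s' at assay '%s', sample '%s'",
                     cells[bad[1L, 1L], bad[1L, 2L]],
                     assays[bad[1L, 1L]], samples[bad[1L, 2L]]))
    num[undet] <- NA_real_
    dimnames(num) <- list(assays, samples)
    CtSet(num, sampleData = sampleData, spikeins = spikeins)
}

#' Write a Ct matrix as tab-delimited text
#'
#' Censored entries are written as the token `"Undetermined"`.
#'
#' @param x a [CtSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCtMatrix <- function(x, path) {
    ct <- ctValues(x)
    chr <- matrix(format(ct, trim = TRUE, digits = 15), nrow(ct), ncol(ct))
    chr[is.na(ct)] <- "Undetermined"
    df <- data.frame(assay = rownames(ct), chr, check.names = FALSE)
    colnames(df) <- c("assay", colnames(ct))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read / write a sample sheet (CSV)
#'
#' Columns: `sample_id`, `group` (`patient`/`control`), `cohort`, and
#' optionally QC columns.
#'
#' @param path CSV path.
#' @return `readSampleSheet`: a data.frame.
#' @export
readSampleSheet <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "group") %in% colnames(df)))
        stop("sample sheet needs 'sample_id' and 'group' columns")
    if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in sheet")
    df
}

#' @rdname readSampleSheet
#' @param x a [CtSet-class] or a data.frame as returned by [sampleSheet()].
#' @export
writeSampleSheet <- function(x, path) {
    df <- if (is(x, "CtSet")) sampleSheet(x) else as.data.frame(x)
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' Serialize a SignatureModel to JSON (and back)
#'
#' @param model a [SignatureModel-class].
#' @param path JSON path.
#' @export
writeSignatureModel <- function(model, path) {
    obj <- list(assays = model@assays,
                coefficients = as.list(model@coefficients),
                coefficientsRaw = as.list(model@coefficientsRaw),
                intercept = model@intercept,
                interceptRaw = model@interceptRaw,
                lambdaGrid = model@lambdaGrid,
                lambdaMin = model@lambdaMin, lambda1se = model@lambda1se,
                cvError = model@cvError,
                center = as.list(model@center), scale = as.list(model@scale),
                threshold = model@threshold, seed = model@seed)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
    invisible(path)
}

#' @rdname writeSignatureModel
#' @export
readSignatureModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    num <- function(v) {
        out <- unlist(v)
        if (is.null(out)) numeric() else
            stats::setNames(as.numeric(out), names(out))
    }
    new("SignatureModel", assays = as.character(obj$assays %||% character()),
        coefficients = num(obj$coefficients),
        coefficientsRaw = num(obj$coefficientsRaw),
        intercept = as.numeric(obj$intercept),
        interceptRaw = as.numeric(obj$interceptRaw),
        lambdaGrid = as.numeric(obj$lambdaGrid),
        lambdaMin = as.numeric(obj$lambdaMin),
        lambda1se = as.numeric(obj$lambda1se),
        cvError = as.data.frame(obj$cvError),
        center = num(obj$center), scale = num(obj$scale),
        threshold = if (is.null(obj$threshold)) NA_real_ else
            as.numeric(obj$threshold),
        seed = if (is.null(obj$seed)) NA_integer_ else as.integer(obj$seed))
}
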