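# shared fixtures: everything is generated in code, nothing on disk

suppressPackageStartupMessages({
    library(SummarizedExperiment)
})

emptySignature <- function() stats::setNames(numeric(0), character(0))

# small, fast cohort with the default planted signature
tinyConfig <- function(seed = 1L, nAssays = 80L, nPatients = 8L,
                       nControls = 10L, ...) {
    simConfig(nAssays = nAssays, nPatients = nPatients,
              nControls = nControls, seed = seed, ...)
}

makeCtSet <- function(mat, groups = NULL, spikeins = character()) {
    mat <- as.matrix(mat)
    if (is.null(rownames(mat)))
        rownames(mat) <- sprintf("miR-%03d", seq_len(nrow(mat)))
    if (is.null(colnames(mat)))
        colnames(mat) <- sprintf("S%02d", seq_len(ncol(mat)))
    sd <- NULL
    if (!is.null(groups))
        sd <- data.frame(sample_id = colnames(mat), group = groups)
    CtSet(mat, sampleData = sd, spikeins = spikeins)
}

# exhaustive two-sided Wilcoxon rank-sum p-value by enumerating every
# assignment of the pooled ranks to the first group (no ties assumed);
# two-sided tail convention matches the exact distribution: 2 * min(tails)
enumWilcoxP <- function(x, y) {
    z <- c(x, y)
    stopifnot(!anyDuplicated(z))
    r <- rank(z)
    n1 <- length(x)
    wObs <- sum(r[seq_len(n1)])
    combs <- utils::combn(length(z), n1)
    wAll <- apply(combs, 2L, function(i) sum(r[i]))
    min(1, 2 * min(mean(wAll <= wObs), mean(wAll >= wObs)))
}

# brute-force quantile normalization: column order statistics replaced by
# their across-column means (distinct values only)
bruteQuantileNorm <- function(m) {
    sorted <- apply(m, 2L, sort)
    target <- rowMeans(sorted)
    out <- m
    for (j in seq_len(ncol(m))) out[, j] <- target[rank(m[, j])]
    out
}

# pairwise Mann-Whitney AUC with half credit for ties
pairwiseAuc <- function(probs, y) {
    pos <- probs[y == 1]
    neg <- probs[y == 0]
    mean(outer(pos, neg, function(a, b)
        (a > b) + 0.5 * (a == b)))
}
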