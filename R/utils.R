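# Internal helpers shared across modules.

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv()))
                    rm(".Random.seed", envir = globalenv())
            } else {
                assign(".Random.seed", old, envir = globalenv())
            }
        })
        set.seed(as.integer(seed))
    }
    expr
}

# Derive a per-stage seed from a global one without coupling stages.
.stageSeed <- function(seed, offset) {
    if (is.null(seed)) return(NULL)
    (as.integer(seed) + 1000L * as.integer(offset)) %% .Machine$integer.max
}

# md5 of an arbitrary R object (used for stage caching).
.hashObject <- function(object) {
    f <- tempfile()
    on.exit(unlink(f))
    saveRDS(object, f, version = 2, compress = FALSE)
    unname(tools::md5sum(f))
}

.weightedMean <- function(x, w) sum(w * x) / sum(w)

.weightedSD <- function(x, w) {
    if (length(x) < 2) return(NA_real_)
    m <- .weightedMean(x, w)
    sqrt(sum(w * (x - m)^2) / sum(w) * length(x) / (length(x) - 1))
}

# Interval key in the 1-based GATK dialect, e.g. "chr1:101-200".
.intervalKey <- function(chrom, start0, end) {
    sprintf("%s:%d-%d", chrom, as.integer(start0) + 1L, as.integer(end))
}

.intervalsToGRanges <- function(intervals) {
    GenomicRanges::GRanges(
        seqnames = intervals$chrom,
        ranges = IRanges::IRanges(start = intervals$start + 1L,
                                  end = intervals$end)
    )
}

.isSexChrom <- function(chrom) {
    c2 <- sub("^chr", "", chrom)
    c2 %in% c("X", "Y")
}

.isAutosome <- function(chrom) !.isSexChrom(chrom)

# Gumbel-max sampling of one index per row from a matrix of (possibly heated)
# log-weights; -Inf rows fall back to the row maximum.
.sampleRows <- function(loglik) {
    g <- -log(-log(matrix(stats::runif(length(loglik)), nrow = nrow(loglik))))
    max.col(loglik + g, ties.method = "first")
}

.logSumExp <- function(x) {
    m <- max(x)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(x - m)))
}
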