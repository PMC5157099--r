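#' Run a simulated benchmarking cohort
#'
#' Simulates `n.samples` tumors under one of the canned designs -- exome-like
#' (2,000 targets at 100x) or panel-like (3,000 small targets at 400x) --
#' with purity drawn uniformly in 20-80% and target ploidy uniformly in 1-6,
#' runs the full tumor-only pipeline on each, and returns true versus
#' inferred maximum-likelihood purity and ploidy. This is the package's own
#' recovery benchmark; correlations of truth and estimate summarize it.
#'
#' @param design `"exome"` or `"panel"`.
#' @param n.samples Number of simulated tumors.
#' @param seed Global seed; per-sample seeds are derived deterministically.
#' @param purity.range,ploidy.range Sampling ranges of the truth.
#' @param config Pipeline configuration.
#' @param verbose Print one line per sample.
#' @return `data.frame` with columns `sample`, `seed`, `purity.true`,
#'   `ploidy.true`, `purity.est`, `ploidy.est`, `accuracy` (fraction of
#'   correct somatic/germline calls among fitted variants) and `flagged`.
#' @export
runBenchmark <- function(design = c("exome", "panel"), n.samples = 20L,
                         seed = 1L, purity.range = c(0.2, 0.8),
                         ploidy.range = c(1, 6),
                         config = defaultConfig(), verbose = FALSE) {
    design <- match.arg(design)
    out <- NULL
    for (i in seq_len(n.samples)) {
        s <- (as.integer(seed) * 1000L + i) %% .Machine$integer.max
        pp <- .withSeed(s, c(stats::runif(1, purity.range[1], purity.range[2]),
                             stats::runif(1, ploidy.range[1], ploidy.range[2])))
        sim <- simulateSample(design, purity = pp[1], target.ploidy = pp[2],
                              seed = s)
        res <- runPipeline(sim$tumor, sim$intervals,
                           normal.coverage = sim$reference,
                           variants = sim$variants, config = config,
                           seed = (s + 500L) %% .Machine$integer.max)
        acc <- NA_real_
        if (!is.null(res$variant.fit) && nrow(res$variant.fit$calls)) {
            calls <- res$variant.fit$calls
            key <- paste(sim$variants$chrom, sim$variants$pos)
            truth.g <- sim$variants$g.true[match(paste(calls$chrom,
                                                       calls$pos), key)]
            acc <- mean((truth.g == "somatic") == calls$ml.somatic,
                        na.rm = TRUE)
        }
        row <- data.frame(sample = i, seed = s,
                          purity.true = pp[1], ploidy.true = sim$truth$ploidy,
                          purity.est = res$best$purity,
                          ploidy.est = res$best$ploidy,
                          accuracy = acc,
                          flagged = length(res$flags) > 0)
        out <- rbind(out, row)
        if (verbose) {
            message(sprintf(
                "%s %2d: purity %.2f -> %.2f, ploidy %.2f -> %.2f",
                design, i, pp[1], res$best$purity, sim$truth$ploidy,
                res$best$ploidy))
        }
    }
    out
}
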