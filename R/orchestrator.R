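# Pipeline orchestration: glue the normalization, segmentation, fitting,
# SNV classification and curation stages with deterministic seeding,
# optional stage caching, and output writing.

.cached <- function(out.dir, enabled, stage, key.obj, fn) {
    if (!enabled || is.null(out.dir)) return(fn())
    cache.dir <- file.path(out.dir, "cache")
    dir.create(cache.dir, recursive = TRUE, showWarnings = FALSE)
    key <- .hashObject(key.obj)
    path <- file.path(cache.dir, paste0(stage, "-", key, ".rds"))
    if (file.exists(path)) return(readRDS(path))
    res <- fn()
    saveRDS(res, path)
    res
}

#' Run the full purity/ploidy and SNV-classification pipeline
#'
#' Executes GC normalization, reference selection, log-ratio computation,
#' weighted CBS with allelic-fraction refinement, the 2D purity/ploidy grid
#' search, heated Gibbs fitting of every local optimum, variant filtering
#' and posterior classification, ranking, bootstrap re-ranking and sample
#' flagging. Without variants the pipeline runs in copy-number-only mode;
#' with a SEG table the coverage and segmentation stages are skipped.
#'
#' @param tumor.coverage Per-target tumor coverage vector, or a coverage
#'   file path.
#' @param intervals Target intervals ([readIntervals()] output or a file
#'   path).
#' @param normal.coverage Matched or process-matched normal coverage
#'   (vector or file path); alternative to `normaldb`.
#' @param normaldb Pool-of-normals database ([createNormalDB()] output or an
#'   RDS path); used for best-normal selection, weights and the
#'   low-coverage mask.
#' @param variants Variant table ([readVariants()] output or a VCF path);
#'   `NULL` for copy-number-only mode.
#' @param seg Pre-segmented data ([readSegFile()] output or a SEG path);
#'   alternative entry point replacing coverage input.
#' @param sample.id Sample name used in outputs.
#' @param config Configuration from [defaultConfig()] / [readConfig()].
#' @param seed Integer seed; fans out to per-stage seeds.
#' @param out.dir Optional output directory; results, effective config and
#'   stage caches are written there.
#' @return Object of class `tumorcn_result`: ranked `solutions`, the `best`
#'   solution, its `segments` (with `C`, `K`, `loh`), `variant.fit`, `sex`,
#'   `gof`, `flags`, `candidates` from the grid search, and the effective
#'   `config`.
#' @export
runPipeline <- function(tumor.coverage = NULL, intervals = NULL,
                        normal.coverage = NULL, normaldb = NULL,
                        variants = NULL, seg = NULL,
                        sample.id = "sample",
                        config = defaultConfig(), seed = config$seed,
                        out.dir = NULL) {
    if (is.character(intervals)) intervals <- readIntervals(intervals)
    if (is.character(tumor.coverage)) {
        tumor.coverage <- readCoverage(tumor.coverage, intervals)
    }
    if (is.character(normal.coverage)) {
        normal.coverage <- readCoverage(normal.coverage, intervals)
    }
    if (is.character(normaldb)) normaldb <- readNormalDB(normaldb)
    if (is.character(variants)) variants <- readVariants(variants)
    if (is.character(seg)) seg <- readSegFile(seg)
    cfg <- config
    matched <- isTRUE(cfg$modes$matched)
    cache.on <- isTRUE(cfg$cache)
    sex <- "unknown"

    if (!is.null(seg)) {
        if (is.null(intervals)) stop("SEG entry point requires intervals")
        segments <- ingestSegmentation(seg, intervals)
    } else {
        if (is.null(tumor.coverage) || is.null(intervals)) {
            stop("tumor coverage and intervals are required")
        }
        if (length(tumor.coverage) != nrow(intervals)) {
            stop("tumor coverage and intervals disagree in length")
        }
        sex <- tryCatch(detectSex(tumor.coverage, intervals),
                        warning = function(w) "unknown")
        tumor.norm <- gcNormalize(tumor.coverage, intervals$gc.fraction,
                                  span = cfg$norm$gc.span,
                                  min.targets = cfg$norm$min.targets)
        if (!is.null(normaldb)) {
            sel <- selectBestNormal(tumor.norm, normaldb,
                                    max.coverage = cfg$norm$max.coverage)
            reference <- sel$reference
        } else if (!is.null(normal.coverage)) {
            if (length(normal.coverage) != nrow(intervals)) {
                stop("normal coverage and intervals disagree in length")
            }
            reference <- gcNormalize(normal.coverage, intervals$gc.fraction,
                                     span = cfg$norm$gc.span,
                                     min.targets = cfg$norm$min.targets)
        } else {
            stop("either normal.coverage or normaldb is required")
        }
        profile <- calculateLogRatios(tumor.norm, reference, intervals,
                                      db = normaldb, sex = sex)
        # sex rules: males exclude chrX and chrY from fitting, everyone
        # excludes chrY
        drop <- if (sex == "male") .isSexChrom(intervals$chrom) else
            sub("^chr", "", intervals$chrom) == "Y"
        profile$retained <- profile$retained & !drop
        het.snps <- if (!is.null(variants)) {
            selectHetSNPs(variants, intervals,
                          flank = cfg$segmentation$flank,
                          het.range = cfg$segmentation$het.range,
                          matched = matched)
        } else {
            data.frame(chrom = character(0), pos = integer(0), f = numeric(0))
        }
        segments <- .cached(out.dir, cache.on, "segmentation",
                            list(profile$lr, profile$weights,
                                 profile$retained, het.snps,
                                 cfg$segmentation, seed),
            function() {
                segs <- .withSeed(.stageSeed(seed, 5),
                    segmentCBS(profile,
                               alpha = cfg$segmentation$alpha,
                               nperm = cfg$segmentation$nperm,
                               min.width = cfg$segmentation$min.width))
                segs <- pruneBreakpoints(segs, het.snps,
                                         prune.p = cfg$segmentation$prune.p,
                                         t.p = cfg$segmentation$prune.t,
                                         min.snps = cfg$segmentation$prune.min.snps)
                segs <- splitCNLOH(segs, het.snps,
                                   alpha = cfg$segmentation$loh.alpha,
                                   min.snps = cfg$segmentation$loh.min.snps)
                mergeWard(segs, het.snps,
                          cut.factor = cfg$segmentation$ward.cut)
            })
    }
    if (is.null(variants)) {
        het.snps <- data.frame(chrom = character(0), pos = integer(0),
                               f = numeric(0))
    }

    candidates <- gridSearch(segments,
                             purity.grid = cfg$fit$purity.grid,
                             ploidy.grid = seq(cfg$fit$ploidy.min,
                                               cfg$fit$ploidy.max,
                                               by = cfg$fit$ploidy.step),
                             max.candidates = cfg$fit$max.candidates,
                             max.copy = cfg$fit$max.copy,
                             use.logsumexp = cfg$fit$use.logsumexp)
    solutions <- lapply(seq_len(nrow(candidates)), function(i) {
        fitSolution(segments, candidates$purity[i], candidates$ploidy[i],
                    seed = .stageSeed(seed, 10 + i),
                    max.copy = cfg$fit$max.copy,
                    purity.grid = cfg$fit$purity.grid,
                    shift.factor = cfg$fit$shift.factor,
                    retry.shift.factor = cfg$fit$retry.shift.factor,
                    discard.delta = cfg$fit$discard.delta,
                    max.sweeps = cfg$fit$max.sweeps,
                    stable.sweeps = cfg$fit$stable.sweeps)
    })

    variant.fits <- NULL
    run.flags <- character(0)
    if (!is.null(variants)) {
        filt <- filterVariants(variants,
                               high.purity = cfg$modes$high.purity,
                               hom.cutoff.normal = cfg$filter$hom.cutoff.normal,
                               hom.cutoff.tumor = cfg$filter$hom.cutoff.tumor,
                               bias.p = cfg$filter$bias.p,
                               pool.min.normals = cfg$filter$pool.min.normals,
                               pool.biased.frac = cfg$filter$pool.biased.frac)
        v.use <- filt$variants
        if (nrow(v.use) == 0) run.flags <- c(run.flags, "no variants")
        variant.fits <- vector("list", length(solutions))
        for (i in seq_along(solutions)) {
            if (isTRUE(solutions[[i]]$discarded)) next
            if (isTRUE(cfg$modes$post.optimize)) {
                po <- postOptimize(solutions[[i]], segments, v.use,
                                   matched = matched, priors = cfg$priors,
                                   high.purity = cfg$modes$high.purity,
                                   contamination = cfg$modes$contamination.states,
                                   purity.grid = cfg$fit$purity.grid)
                solutions[[i]] <- po$solution
                fit <- po$variant.fit
            } else {
                fit <- fitVariants(v.use, segments, solutions[[i]],
                                   matched = matched, priors = cfg$priors,
                                   high.purity = cfg$modes$high.purity,
                                   contamination = cfg$modes$contamination.states,
                                   flank = cfg$segmentation$flank)
            }
            variant.fits[[i]] <- fit
            solutions[[i]]$snv.loglik <- fit$snv.loglik
            solutions[[i]]$total.loglik <- solutions[[i]]$cn.loglik +
                fit$snv.loglik
            solutions[[i]]$variant.loglik <-
                if (nrow(fit$calls)) fit$calls$loglik.ml else numeric(0)
        }
        names(variant.fits) <- as.character(seq_along(solutions))
    }

    solutions <- rankSolutions(solutions,
                               haploid.adjust = cfg$modes$haploid.adjust,
                               low.purity = cfg$priors$low.purity)
    is.disc <- vapply(solutions, function(s) isTRUE(s$discarded), logical(1))
    if (!is.null(variants) && sum(!is.disc) >= 2) {
        bs <- bootstrapRank(solutions[!is.disc],
                            replicates = cfg$curation$bootstrap.n,
                            seed = .stageSeed(seed, 90),
                            top = cfg$curation$bootstrap.top,
                            min.variants = cfg$curation$bootstrap.min.variants,
                            ambiguous = cfg$curation$bootstrap.ambiguous)
        solutions <- c(bs$solutions, solutions[is.disc])
        run.flags <- c(run.flags, bs$flags)
    } else if (sum(!is.disc) == 1) {
        solutions[[which(!is.disc)]]$bootstrap.value <- 1
    }
    best <- solutions[[1]]
    best.fit <- NULL
    if (!is.null(variant.fits)) {
        # match the best solution back to its variant fit by candidate
        for (i in seq_along(variant.fits)) {
            if (!is.null(variant.fits[[i]]) &&
                isTRUE(all.equal(solutions[[1]]$candidate,
                                 c(purity = candidates$purity[i],
                                   ploidy = candidates$ploidy[i])))) {
                best.fit <- variant.fits[[i]]
                break
            }
        }
    }
    best.segments <- callLOH(segments, best, best.fit,
                             n.cap = cfg$priors$n.cap)
    gof <- if (!is.null(best.fit)) goodnessOfFit(best.fit) else NA_real_
    flags <- c(run.flags,
               flagSample(best, best.segments, best.fit, gof,
                          thresholds = cfg$curation))
    if (sex == "unknown") flags <- unique(c(flags, "SEX_UNKNOWN"))
    result <- structure(list(
        sample.id = sample.id,
        solutions = solutions,
        best = best,
        segments = best.segments,
        variant.fit = best.fit,
        candidates = candidates,
        sex = sex,
        gof = gof,
        flags = unique(flags),
        config = cfg,
        seed = seed
    ), class = "tumorcn_result")
    if (!is.null(out.dir)) {
        dir.create(out.dir, recursive = TRUE, showWarnings = FALSE)
        writeConfig(cfg, file.path(out.dir, paste0(sample.id, "_config.yaml")))
        writeOutputs(result, file.path(out.dir, sample.id))
    }
    result
}

#' @export
print.tumorcn_result <- function(x, ...) {
    cat(sprintf("tumorcn result for %s\n", x$sample.id))
    cat(sprintf("  purity %.2f, ploidy %.3f (rank 1 of %d solutions)\n",
                x$best$purity, x$best$ploidy, length(x$solutions)))
    if (!is.na(x$gof)) cat(sprintf("  goodness of fit: %.1f%%\n", x$gof))
    cat(sprintf("  flags: %s\n",
                if (length(x$flags)) paste(x$flags, collapse = ", ")
                else "none"))
    invisible(x)
}
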