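# Coverage normalization: GC correction, pool-of-normals database,
# best-normal selection, log-ratio computation and sex detection.

#' GC-normalize a coverage vector
#'
#' Divides coverage by a smooth loess trend of coverage on GC fraction
#' (fitted on targets with nonzero coverage) and rescales so the sample mean
#' is preserved. Zero-coverage targets stay at zero.
#'
#' @param coverage Per-target coverage vector.
#' @param gc.fraction Per-target GC fraction, aligned with `coverage`.
#' @param span Loess span (default 0.3).
#' @param min.targets Minimum number of nonzero targets required.
#' @return Normalized coverage vector.
#' @export
#' @examples
#' gc <- runif(500, 0.3, 0.7)
#' cov <- 100 * (1 + (gc - 0.5))
#' norm <- gcNormalize(cov, gc)
gcNormalize <- function(coverage, gc.fraction, span = 0.3,
                        min.targets = 100L) {
    stopifnot(length(coverage) == length(gc.fraction))
    nz <- which(coverage > 0 & !is.na(gc.fraction))
    if (length(nz) == 0) stop("all-zero coverage")
    if (length(nz) < min.targets) {
        stop("need at least ", min.targets, " targets with nonzero coverage")
    }
    fit <- stats::loess(coverage[nz] ~ gc.fraction[nz], span = span,
                        degree = 2, family = "symmetric",
                        control = stats::loess.control(surface = "direct"))
    trend <- stats::predict(fit, newdata = gc.fraction)
    trend[is.na(trend) | trend <= 0] <- stats::median(fit$fitted)
    out <- coverage / trend
    out[coverage == 0] <- 0
    # preserve the sample mean over targets used for the fit
    out * mean(coverage[nz]) / mean(out[nz])
}

#' Build a pool-of-normals database
#'
#' From GC-normalized coverage of at least two process-matched normal
#' samples, fits a PCA (first three components, per-target centered) for
#' best-normal selection, derives per-target segmentation weights from the
#' inverse standard deviation of coverage ratios against the pool median,
#' and marks targets whose median coverage falls below 20% of their
#' chromosome's median for exclusion. Coverage is capped at a maximum
#' (default 100x) before PCA so depth does not dominate the components.
#'
#' @param coverage.matrix Numeric matrix, targets x normal samples,
#'   GC-normalized.
#' @param intervals Target intervals from [readIntervals()].
#' @param max.coverage Cap applied (by rescaling samples that exceed it)
#'   before PCA.
#' @param weight.ceiling Maximum weight (relative to mean 1) before
#'   renormalization.
#' @param low.cov.frac Exclusion threshold as a fraction of the chromosome
#'   median coverage.
#' @param pca.components Number of principal components retained.
#' @return Object of class `tumorcn_normaldb`.
#' @export
createNormalDB <- function(coverage.matrix, intervals,
                           max.coverage = 100, weight.ceiling = 3,
                           low.cov.frac = 0.2, pca.components = 3L) {
    coverage.matrix <- as.matrix(coverage.matrix)
    if (ncol(coverage.matrix) < 2) {
        stop("need at least 2 normal samples to build a pool of normals")
    }
    stopifnot(nrow(coverage.matrix) == nrow(intervals))
    if (is.null(colnames(coverage.matrix))) {
        colnames(coverage.matrix) <- paste0("normal", seq_len(ncol(coverage.matrix)))
    }
    capped <- apply(coverage.matrix, 2, .capCoverage, max.coverage)
    k <- min(pca.components, ncol(capped) - 1L, nrow(capped))
    pca <- stats::prcomp(t(capped), center = TRUE, scale. = FALSE, rank. = k)
    # per-target coverage ratios of mean-scaled normals vs. the pool median
    scaled <- sweep(coverage.matrix, 2, colMeans(coverage.matrix), "/")
    med <- apply(scaled, 1, stats::median)
    ratio <- sweep(scaled, 1, ifelse(med > 0, med, NA_real_), "/")
    ratio.sd <- apply(ratio, 1, stats::sd)
    ratio.sd[is.na(ratio.sd)] <- Inf   # median-zero targets: no information
    weights <- .weightsFromSD(ratio.sd, weight.ceiling)
    median.coverage <- apply(coverage.matrix, 1, stats::median)
    chrom.median <- stats::ave(median.coverage, intervals$chrom,
                               FUN = stats::median)
    mask <- median.coverage < low.cov.frac * chrom.median
    structure(list(
        version = 1L,
        samples = colnames(coverage.matrix),
        coverage = coverage.matrix,
        capped = capped,
        median.coverage = median.coverage,
        ratio.sd = ratio.sd,
        pca = list(rotation = pca$rotation, center = pca$center,
                   projection = pca$x),
        weights = weights,
        mask = mask,
        intervals.key = .intervalKey(intervals$chrom, intervals$start,
                                     intervals$end)
    ), class = "tumorcn_normaldb")
}

# Samples are rescaled so their maximum equals the cap: coverage magnitude
# then cannot dominate the PCA and best-normal selection is invariant to a
# global scale factor on any sample.
.capCoverage <- function(x, max.coverage) {
    mx <- max(x)
    if (mx <= 0) stop("all-zero coverage")
    x * (max.coverage / mx)
}

.weightsFromSD <- function(ratio.sd, weight.ceiling) {
    if (all(!is.finite(ratio.sd)) || all(ratio.sd == 0, na.rm = TRUE)) {
        return(rep(1, length(ratio.sd)))
    }
    sd2 <- ratio.sd
    min.pos <- min(sd2[is.finite(sd2) & sd2 > 0])
    sd2[sd2 < min.pos] <- min.pos     # zero-SD targets get the best weight
    sd2[!is.finite(sd2)] <- max(sd2[is.finite(sd2)])
    w <- 1 / sd2
    w <- w / mean(w)
    w <- pmin(w, weight.ceiling)
    w / mean(w)
}

#' Save / load a pool-of-normals database
#'
#' The database is serialized as a single versioned archive.
#'
#' @param db A `tumorcn_normaldb` object.
#' @param path File path.
#' @return `path` (save) or the database (load).
#' @export
saveNormalDB <- function(db, path) {
    stopifnot(inherits(db, "tumorcn_normaldb"))
    saveRDS(db, path)
    invisible(path)
}

#' @rdname saveNormalDB
#' @export
readNormalDB <- function(path) {
    db <- readRDS(path)
    if (!inherits(db, "tumorcn_normaldb") || is.null(db$version)) {
        stop("not a tumorcn normal database: ", path)
    }
    db
}

#' Select the best process-matched normal(s) for a tumor
#'
#' Projects the (GC-normalized, coverage-capped) tumor onto the database's
#' stored principal components and returns the `n.best` normals with minimum
#' Euclidean distance. For `n.best > 1` the reference is the average of the
#' selected normals weighted inversely by distance.
#'
#' @param tumor.coverage GC-normalized tumor coverage vector.
#' @param db Database from [createNormalDB()].
#' @param n.best Number of normals to combine.
#' @param max.coverage Cap used for the projection (must match the DB).
#' @return List with `ids`, `distances` and `reference` (combined coverage).
#' @export
selectBestNormal <- function(tumor.coverage, db, n.best = 1L,
                             max.coverage = 100) {
    stopifnot(inherits(db, "tumorcn_normaldb"))
    if (length(db$samples) == 0) stop("empty normal database")
    capped <- .capCoverage(tumor.coverage, max.coverage)
    proj <- (capped - db$pca$center) %*% db$pca$rotation
    d <- sqrt(rowSums(sweep(db$pca$projection, 2, proj, "-")^2))
    ord <- order(d)
    take <- ord[seq_len(min(n.best, length(ord)))]
    if (length(take) == 1) {
        ref <- db$coverage[, take]
    } else {
        wts <- 1 / (d[take] + 1e-9)
        wts <- wts / sum(wts)
        ref <- as.numeric(db$coverage[, take, drop = FALSE] %*% wts)
    }
    list(ids = db$samples[take], distances = d[take], reference = ref)
}

#' Compute tumor/reference log-ratios
#'
#' Mean-centers both samples over the retained targets and returns per-target
#' log2 coverage ratios with segmentation weights attached. Targets masked in
#' the database (or with zero reference coverage) carry `NA`.
#'
#' @param tumor.coverage GC-normalized tumor coverage.
#' @param reference.coverage GC-normalized reference (best normal or pool
#'   average) coverage.
#' @param intervals Target intervals.
#' @param db Optional normal database providing `mask` and `weights`.
#' @param sex Optional sex call attached to the profile.
#' @return Object of class `tumorcn_lrprofile`: list with `lr`, `weights`,
#'   `retained`, `intervals`, `sex`.
#' @export
calculateLogRatios <- function(tumor.coverage, reference.coverage, intervals,
                               db = NULL, sex = "unknown") {
    stopifnot(length(tumor.coverage) == length(reference.coverage),
              length(tumor.coverage) == nrow(intervals))
    retained <- rep(TRUE, length(tumor.coverage))
    weights <- rep(1, length(tumor.coverage))
    if (!is.null(db)) {
        retained <- retained & !db$mask
        weights <- db$weights
    }
    zero.ref <- retained & reference.coverage <= 0
    if (any(zero.ref)) {
        message(sum(zero.ref), " target(s) with zero reference coverage masked")
        retained <- retained & !zero.ref
    }
    t.c <- tumor.coverage / mean(tumor.coverage[retained])
    r.c <- reference.coverage / mean(reference.coverage[retained])
    lr <- rep(NA_real_, length(tumor.coverage))
    lr[retained] <- log2(t.c[retained] / r.c[retained])
    structure(list(lr = lr, weights = weights, retained = retained,
                   intervals = intervals, sex = sex),
              class = "tumorcn_lrprofile")
}

#' Detect sample sex from sex-chromosome coverage
#'
#' Male: mean chrY coverage above 25% of the autosomal mean and chrX below
#' 75%. Female: chrY below 5% and chrX at or above 75%. Anything else (or
#' missing sex-chromosome targets) is `unknown`, treated downstream like
#' female for filtering, with a warning flag.
#'
#' @param coverage Per-target coverage.
#' @param intervals Target intervals.
#' @return One of `"male"`, `"female"`, `"unknown"`.
#' @export
detectSex <- function(coverage, intervals) {
    chrom <- sub("^chr", "", intervals$chrom)
    auto <- coverage[!chrom %in% c("X", "Y")]
    x <- coverage[chrom == "X"]
    y <- coverage[chrom == "Y"]
    if (!length(x) || !length(auto)) {
        warning("no sex-chromosome targets; sex unknown")
        return("unknown")
    }
    am <- mean(auto)
    xr <- mean(x) / am
    yr <- if (length(y)) mean(y) / am else NA_real_
    if (!is.na(yr) && yr > 0.25 && xr < 0.75) return("male")
    if (!is.na(yr) && yr < 0.05 && xr >= 0.75) return("female")
    if (is.na(yr)) {
        warning("no chrY targets; sex unknown")
        return("unknown")
    }
    warning("ambiguous sex-chromosome coverage; sex unknown")
    "unknown"
}
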