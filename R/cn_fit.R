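# Purity/ploidy fitting: per-segment Gaussian log-ratio likelihood,
# 2D grid search for local optima, and heated Gibbs assignment of integer
# copy numbers with log-ratio recalibration and purity refinement.

# Expected log-ratio of a segment with copy number C at purity p and tumor
# ploidy D (normal assumed diploid).
.lrMean <- function(p, C, D) {
    log2((p * C + 2 * (1 - p)) / (p * D + 2 * (1 - p)))
}

#' Segment log-likelihood under the purity/ploidy model
#'
#' Log-ratios in a segment are modeled as Gaussian around
#' `log2((p*C + 2(1-p)) / (p*D + 2(1-p)))` with the segment's per-target
#' standard deviation; the segment contributes its number of targets times
#' the log-density, so segments are weighted by target count rather than
#' base-pair size.
#'
#' @param r Segment mean log-ratio.
#' @param sd Per-target log-ratio standard deviation (> 0).
#' @param num.targets Number of targets in the segment.
#' @param purity Tumor purity in (0, 1].
#' @param C Integer copy number (>= 0).
#' @param ploidy Tumor ploidy D (> 0).
#' @return Log-likelihood contribution of the segment.
#' @export
#' @examples
#' segmentLogLik(0, 0.1, 50, purity = 1, C = 2, ploidy = 2)
segmentLogLik <- function(r, sd, num.targets, purity, C, ploidy) {
    if (any(C < 0)) stop("copy number C must be >= 0")
    stopifnot(purity > 0, purity <= 1, ploidy > 0, all(sd > 0))
    num.targets * stats::dnorm(r, .lrMean(purity, C, ploidy), sd, log = TRUE)
}

# log-density of the sub-clonal state: a segment goes sub-clonal only when
# every integer state fits worse than a 2-sd mismatch.
.subclonalLogLik <- function(sd, num.targets) {
    num.targets * (-log(sd * sqrt(2 * pi)) - 2)
}

# matrix of state log-likelihoods: segments x (C = 0..max.copy, SUBCLONAL)
.statesLogLik <- function(r, sd, nt, p, D, shift = 0, max.copy = 7L) {
    cc <- 0:max.copy
    m <- .lrMean(p, cc, D)
    ll <- vapply(seq_along(cc), function(k) {
        nt * stats::dnorm(r + shift, m[k], sd, log = TRUE)
    }, numeric(length(r)))
    ll <- matrix(ll, nrow = length(r))
    cbind(ll, .subclonalLogLik(sd, nt))
}

#' 2D grid search for purity/ploidy local optima
#'
#' Scores every grid point by the sum over segments of the best-fitting copy
#' state (including the sub-clonal state), treating ploidy as continuous,
#' and returns local optima of the score surface. Ridges of (numerically)
#' tied optima -- e.g. the purity continuum of a non-aberrant genome -- are
#' collapsed to a single representative at the highest purity.
#'
#' @param segments Segment table from the segmentation step.
#' @param purity.grid Purity values searched.
#' @param ploidy.grid Ploidy values searched.
#' @param max.candidates Maximum number of optima returned.
#' @param max.copy Highest integer copy state.
#' @param use.logsumexp Score with log-sum-exp over copy states instead of
#'   the maximum.
#' @return `data.frame` with `purity`, `ploidy`, `score`, ordered by score.
#' @export
gridSearch <- function(segments, purity.grid = seq(0.15, 0.95, by = 0.01),
                       ploidy.grid = seq(1, 6, by = 0.1),
                       max.candidates = 20L, max.copy = 7L,
                       use.logsumexp = FALSE) {
    stopifnot(nrow(segments) >= 1)
    r <- segments$seg.mean
    sd <- segments$sd
    nt <- segments$num.targets
    np <- length(purity.grid)
    nd <- length(ploidy.grid)
    score <- matrix(NA_real_, np, nd)
    for (a in seq_len(np)) {
        p <- purity.grid[a]
        for (b in seq_len(nd)) {
            ll <- .statesLogLik(r, sd, nt, p, ploidy.grid[b],
                                max.copy = max.copy)
            score[a, b] <- if (use.logsumexp) {
                sum(apply(ll, 1, .logSumExp))
            } else {
                sum(ll[cbind(seq_along(r), max.col(ll, ties.method = "first"))])
            }
        }
    }
    opt <- .localOptima(score)
    opt <- .collapseRidges(opt, score)
    if (nrow(opt) == 0) {   # plateau: fall back to the global maximum
        gm <- which(score >= max(score) - 1e-9, arr.ind = TRUE)
        gm <- gm[order(-gm[, 1]), , drop = FALSE]
        opt <- data.frame(i = gm[1, 1], j = gm[1, 2])
    }
    out <- data.frame(
        purity = purity.grid[opt$i],
        ploidy = ploidy.grid[opt$j],
        score = score[cbind(opt$i, opt$j)]
    )
    out <- out[order(-out$score, -out$purity), , drop = FALSE]
    rownames(out) <- NULL
    utils::head(out, max.candidates)
}

.localOptima <- function(score) {
    np <- nrow(score); nd <- ncol(score)
    hits <- NULL
    for (a in seq_len(np)) {
        for (b in seq_len(nd)) {
            v <- score[a, b]
            nb <- score[max(1, a - 1):min(np, a + 1),
                        max(1, b - 1):min(nd, b + 1)]
            if (v >= max(nb) - 1e-12 && v > min(nb)) {
                hits <- rbind(hits, c(a, b))
            }
        }
    }
    # pure plateau (constant surface): no informative optima
    if (is.null(hits)) return(data.frame(i = integer(0), j = integer(0)))
    data.frame(i = hits[, 1], j = hits[, 2])
}

.collapseRidges <- function(opt, score, tol = 1e-6) {
    n <- nrow(opt)
    if (n <= 1) return(opt)
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (a in seq_len(n - 1)) {
        for (b in (a + 1):n) {
            adj <- abs(opt$i[a] - opt$i[b]) <= 1 && abs(opt$j[a] - opt$j[b]) <= 1
            close <- abs(score[opt$i[a], opt$j[a]] -
                         score[opt$i[b], opt$j[b]]) < tol
            if (adj && close) parent[find(b)] <- find(a)
        }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    keep <- vapply(unique(comp), function(g) {
        rows <- which(comp == g)
        sc <- score[cbind(opt$i[rows], opt$j[rows])]
        best <- rows[sc >= max(sc) - 1e-12]
        best[which.max(opt$i[best])]   # highest-purity representative
    }, integer(1))
    opt[keep, , drop = FALSE]
}

# tumor ploidy implied by an assignment; sub-clonal segments contribute the
# continuous copy number implied by their (shifted) log-ratio.
.ploidyFromAssign <- function(assign, r.shifted, l, p, D.prev,
                              max.copy = 7L) {
    cc <- as.numeric(assign - 1L)
    sub <- assign == max.copy + 2L
    if (any(sub)) {
        implied <- (2^(r.shifted[sub]) * (p * D.prev + 2 * (1 - p)) -
                    2 * (1 - p)) / p
        cc[sub] <- pmin(pmax(implied, 0), 16)
    }
    sum(l * cc) / sum(l)
}

.assignLL <- function(r, sd, nt, assign, p, D, shift, max.copy = 7L) {
    ll <- numeric(length(r))
    int <- assign <= max.copy + 1L
    if (any(int)) {
        ll[int] <- nt[int] * stats::dnorm(
            r[int] + shift, .lrMean(p, assign[int] - 1, D), sd[int],
            log = TRUE)
    }
    if (any(!int)) ll[!int] <- .subclonalLogLik(sd[!int], nt[!int])
    sum(ll)
}

#' Fit one purity/ploidy candidate by heated Gibbs sampling
#'
#' Starting from a grid-search optimum, iterates (a) sampling each segment's
#' copy state from its heated posterior, (b) a Gibbs step for purity over
#' the 0.15-0.95 grid, and (c) a Gibbs step for a log-ratio recalibration
#' shift within `shift.factor` times the mean segment noise, recomputing
#' ploidy from the current assignment every sweep. The temperature anneals
#' from 4 to 1. After convergence (maximum-likelihood assignment stable for
#' `stable.sweeps` sweeps) a deterministic coordinate ascent polishes the
#' solution. If the converged ploidy is more than `discard.delta` away from
#' the candidate, one retry with the wider `retry.shift.factor`
#' recalibration range is attempted; a still-divergent solution is flagged
#' discarded.
#'
#' @param segments Segment table.
#' @param purity,ploidy Candidate from [gridSearch()].
#' @param seed Integer seed; identical seeds give identical solutions.
#' @param max.copy Highest integer copy state.
#' @param purity.grid Purity grid for the Gibbs step.
#' @param shift.factor Recalibration range in units of mean segment SD.
#' @param retry.shift.factor Range used for the retry.
#' @param discard.delta Maximum allowed |ploidy - candidate|.
#' @param max.sweeps,stable.sweeps Convergence controls.
#' @param fit.purity,fit.shift Disable the purity / shift updates (used by
#'   the enumeration cross-checks).
#' @return Object of class `tumorcn_solution`.
#' @export
fitSolution <- function(segments, purity, ploidy, seed = NULL,
                        max.copy = 7L,
                        purity.grid = seq(0.15, 0.95, by = 0.01),
                        shift.factor = 0.25, retry.shift.factor = 1.0,
                        discard.delta = 0.75, max.sweeps = 100L,
                        stable.sweeps = 3L,
                        fit.purity = TRUE, fit.shift = TRUE) {
    .withSeed(seed, {
        res <- .fitOnce(segments, purity, ploidy, max.copy, purity.grid,
                        shift.factor, max.sweeps, stable.sweeps,
                        fit.purity, fit.shift)
        if (abs(res$ploidy - ploidy) > discard.delta &&
            retry.shift.factor > shift.factor) {
            res <- .fitOnce(segments, purity, ploidy, max.copy, purity.grid,
                            retry.shift.factor, max.sweeps, stable.sweeps,
                            fit.purity, fit.shift)
        }
        res$discarded <- abs(res$ploidy - ploidy) > discard.delta
        res$candidate <- c(purity = purity, ploidy = ploidy)
        res$seed <- seed
        res
    })
}

.fitOnce <- function(segments, purity, ploidy, max.copy, purity.grid,
                     shift.factor, max.sweeps, stable.sweeps,
                     fit.purity, fit.shift) {
    r <- segments$seg.mean
    sdv <- segments$sd
    nt <- segments$num.targets
    l <- segments$size
    p <- purity
    D <- ploidy
    s <- 0
    max.shift <- shift.factor * mean(sdv)
    shift.grid <- seq(-max.shift, max.shift, length.out = 21L)
    ll <- .statesLogLik(r, sdv, nt, p, D, s, max.copy)
    assign <- max.col(ll, ties.method = "first")
    ml.prev <- assign
    stable <- 0L
    sweeps <- 0L
    for (k in seq_len(max.sweeps)) {
        sweeps <- k
        temp <- max(1, 4 * 0.9^(k - 1))
        D <- .ploidyFromAssign(assign, r + s, l, p, D, max.copy)
        ll <- .statesLogLik(r, sdv, nt, p, D, s, max.copy)
        assign <- .sampleRows(ll / temp)
        D <- .ploidyFromAssign(assign, r + s, l, p, D, max.copy)
        if (fit.purity) {
            pll <- vapply(purity.grid, function(pp)
                .assignLL(r, sdv, nt, assign, pp, D, s, max.copy), numeric(1))
            p <- purity.grid[.sampleRows(matrix(pll / temp, nrow = 1))]
        }
        if (fit.shift) {
            sll <- vapply(shift.grid, function(sh)
                .assignLL(r, sdv, nt, assign, p, D, sh, max.copy), numeric(1))
            s <- shift.grid[.sampleRows(matrix(sll / temp, nrow = 1))]
        }
        ml <- max.col(.statesLogLik(r, sdv, nt, p, D, s, max.copy),
                      ties.method = "first")
        if (identical(ml, ml.prev)) stable <- stable + 1L else stable <- 0L
        ml.prev <- ml
        if (stable >= stable.sweeps) break
    }
    # deterministic coordinate ascent to the local maximum
    for (it in seq_len(20L)) {
        ml <- max.col(.statesLogLik(r, sdv, nt, p, D, s, max.copy),
                      ties.method = "first")
        D.new <- .ploidyFromAssign(ml, r + s, l, p, D, max.copy)
        p.new <- p
        s.new <- s
        if (fit.purity) {
            pll <- vapply(purity.grid, function(pp)
                .assignLL(r, sdv, nt, ml, pp, D.new, s, max.copy), numeric(1))
            p.new <- purity.grid[which.max(pll)]
        }
        if (fit.shift) {
            sll <- vapply(shift.grid, function(sh)
                .assignLL(r, sdv, nt, ml, p.new, D.new, sh, max.copy),
                numeric(1))
            s.new <- shift.grid[which.max(sll)]
        }
        converged <- isTRUE(all.equal(c(D.new, p.new, s.new), c(D, p, s),
                                      tolerance = 1e-12))
        D <- D.new; p <- p.new; s <- s.new
        if (converged) break
    }
    ml <- max.col(.statesLogLik(r, sdv, nt, p, D, s, max.copy),
                  ties.method = "first")
    D <- .ploidyFromAssign(ml, r + s, l, p, D, max.copy)
    ll <- .statesLogLik(r, sdv, nt, p, D, s, max.copy)
    posterior <- t(apply(ll, 1, function(x) {
        e <- exp(x - max(x)); e / sum(e)
    }))
    colnames(posterior) <- c(as.character(0:max.copy), "SUBCLONAL")
    sub <- ml == max.copy + 2L
    C <- ifelse(sub, NA_integer_, ml - 1L)
    cn.loglik <- .assignLL(r, sdv, nt, ml, p, D, s, max.copy)
    structure(list(
        purity = p,
        ploidy = D,
        shift = s,
        C = C,
        subclonal = sub,
        assign = ml,
        posterior = posterior,
        cn.loglik = cn.loglik,
        snv.loglik = NA_real_,
        total.loglik = cn.loglik,
        gof = NA_real_,
        flags = character(0),
        bootstrap.value = NA_real_,
        rank = NA_integer_,
        discarded = FALSE,
        sweeps = sweeps
    ), class = "tumorcn_solution")
}

#' @export
print.tumorcn_solution <- function(x, ...) {
    cat(sprintf("tumorcn solution: purity %.2f, ploidy %.3f%s\n",
                x$purity, x$ploidy,
                if (isTRUE(x$discarded)) " (discarded)" else ""))
    cat(sprintf("  log-likelihood: CN %.2f, SNV %s, total %.2f\n",
                x$cn.loglik,
                if (is.na(x$snv.loglik)) "NA" else sprintf("%.2f", x$snv.loglik),
                x$total.loglik))
    invisible(x)
}

#' Build segments from externally segmented data
#'
#' Takes already-segmented copy-number data (SEG rows) plus an interval
#' file defining the target grid and produces the segment table used by the
#' fitting stage: each SEG row's target count is the number of overlapping
#' intervals, its size the genomic length, and its noise the provided `sd`
#' column or a global default.
#'
#' @param seg SEG table from [readSegFile()].
#' @param intervals Target intervals.
#' @param sd.default Per-target log-ratio standard deviation used when the
#'   SEG file has no `sd` column.
#' @return Segment table compatible with [gridSearch()] / [fitSolution()].
#' @export
ingestSegmentation <- function(seg, intervals, sd.default = 0.1) {
    gr.t <- .intervalsToGRanges(intervals)
    out <- NULL
    dropped <- 0L
    for (i in seq_len(nrow(seg))) {
        gr.s <- GenomicRanges::GRanges(
            seg$chrom[i], IRanges::IRanges(seg$start[i] + 1L, seg$end[i]))
        hits <- which(IRanges::overlapsAny(gr.t, gr.s))
        if (!length(hits)) {
            dropped <- dropped + 1L
            next
        }
        n <- length(hits)
        m <- seg$seg.mean[i]
        sdv <- if (!is.null(seg$sd)) seg$sd[i] else sd.default
        sdv <- max(sdv, 1e-4)
        out <- rbind(out, data.frame(
            chrom = seg$chrom[i],
            start = intervals$start[hits[1]],
            end = intervals$end[hits[n]],
            first.target = hits[1], last.target = hits[n],
            num.targets = n,
            size = seg$end[i] - seg$start[i],
            seg.mean = m, sd = sdv,
            sum.w = n, sum.wx = n * m, sum.wx2 = n * (m^2 + sdv^2),
            bp.p = NA_real_,
            stringsAsFactors = FALSE
        ))
    }
    if (dropped > 0) {
        warning(dropped, " SEG row(s) overlapping no target dropped")
    }
    if (is.null(out)) stop("no SEG rows overlap the target intervals")
    rownames(out) <- NULL
    attr(out, "intervals") <- intervals
    attr(out, "retained") <- rep(TRUE, nrow(intervals))
    out
}
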