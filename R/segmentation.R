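# Segmentation of the weighted log-ratio profile, with refinement of
# breakpoints by germline allelic fractions: SNP-based pruning of borderline
# breakpoints, copy-neutral LOH splitting, and Ward merging of segments with
# similar log-ratio and mirrored allelic fraction.

#' Select heterozygous germline SNPs for segmentation refinement
#'
#' Keeps dbSNP variants with allelic fraction inside `het.range` (in the
#' matched germline where available) that fall within a target or its
#' flanking region (default 50 bp).
#'
#' @param variants Variant table from [readVariants()].
#' @param intervals Target intervals.
#' @param flank Flank size in bp.
#' @param het.range Allelic-fraction window defining heterozygosity.
#' @param matched Restrict to variants called germline in the matched normal.
#' @return Subset of `variants` (columns `chrom`, `pos`, `f`, ...).
#' @export
selectHetSNPs <- function(variants, intervals, flank = 50L,
                          het.range = c(0.1, 0.9), matched = FALSE) {
    keep <- variants$in.dbsnp &
        variants$f >= het.range[1] & variants$f <= het.range[2]
    if (matched) {
        keep <- keep & variants$matched.status == "germline" &
            (is.na(variants$normal.f) |
             (variants$normal.f >= het.range[1] &
              variants$normal.f <= het.range[2]))
    }
    v <- variants[keep, , drop = FALSE]
    if (nrow(v) == 0) return(v)
    gr.v <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
    gr.t <- .intervalsToGRanges(intervals)
    gr.t <- GenomicRanges::resize(gr.t,
        width = GenomicRanges::width(gr.t) + 2L * flank, fix = "center")
    hit <- IRanges::overlapsAny(gr.v, gr.t)
    v[hit, , drop = FALSE]
}

#' Segment a log-ratio profile by weighted circular binary segmentation
#'
#' Recursively finds the arc maximizing the weighted two-sample statistic,
#' accepts breakpoints whose permutation p-value is at most `alpha`, and
#' returns segments tiling the retained targets of each chromosome. Each
#' segment carries the p-value of the breakpoint at its left boundary
#' (needed by [pruneBreakpoints()]), the weighted mean log-ratio and the
#' weighted per-target standard deviation of member log-ratios (floored at
#' 1e-4; segments too short to estimate it inherit a robust profile-wide
#' value).
#'
#' @param profile A `tumorcn_lrprofile` from [calculateLogRatios()].
#' @param alpha Permutation significance threshold for a breakpoint.
#' @param nperm Maximum number of permutations. Permutations stop early once
#'   the exceedance count guarantees p > `alpha`, or once a clean run bounds
#'   the p-value below the pruning threshold.
#' @param min.width Minimum targets per segment.
#' @return `data.frame` of segments with attributes `intervals` and
#'   `retained` carried along for the refinement steps.
#' @export
segmentCBS <- function(profile, alpha = 0.001, nperm = 10000L,
                       min.width = 2L) {
    iv <- profile$intervals
    ret <- which(profile$retained & !is.na(profile$lr))
    if (length(ret) < 2) stop("need at least 2 retained targets")
    accept.n <- as.integer(min(nperm, max(2000, ceiling(1 / alpha))))
    # robust profile-wide per-target noise, as fallback for short segments
    global.sd <- .robustTargetSD(profile$lr[ret])
    out <- NULL
    for (ch in unique(iv$chrom[ret])) {
        idx <- ret[iv$chrom[ret] == ch]
        x <- profile$lr[idx]
        w <- profile$weights[idx]
        cuts <- .cbsRecurse(x, w, alpha, nperm, min.width, accept.n)
        bounds <- c(0L, sort(cuts$after), length(x))
        p.of <- cuts$p[order(cuts$after)]
        for (k in seq_len(length(bounds) - 1L)) {
            lo <- bounds[k] + 1L
            hi <- bounds[k + 1L]
            rows <- idx[lo:hi]
            out <- rbind(out, .segmentRow(
                iv, rows, x[lo:hi], w[lo:hi],
                bp.p = if (k == 1) NA_real_ else p.of[k - 1L],
                global.sd = global.sd))
        }
    }
    rownames(out) <- NULL
    attr(out, "intervals") <- iv
    attr(out, "retained") <- profile$retained & !is.na(profile$lr)
    attr(out, "global.sd") <- global.sd
    out
}

.robustTargetSD <- function(x) {
    if (length(x) < 3) return(0.1)
    max(stats::median(abs(diff(x))) / (sqrt(2) * 0.6744898), 1e-4)
}

.segmentRow <- function(iv, rows, x, w, bp.p, global.sd) {
    sw <- sum(w)
    m <- sum(w * x) / sw
    n <- length(x)
    sdv <- if (n >= 3) .weightedSD(x, w) else NA_real_
    if (!is.finite(sdv) || is.na(sdv)) sdv <- global.sd
    data.frame(
        chrom = iv$chrom[rows[1]],
        start = iv$start[rows[1]],
        end = iv$end[rows[length(rows)]],
        first.target = rows[1],
        last.target = rows[length(rows)],
        num.targets = n,
        size = iv$end[rows[length(rows)]] - iv$start[rows[1]],
        seg.mean = m,
        sd = max(sdv, 1e-4),
        sum.w = sw,
        sum.wx = sum(w * x),
        sum.wx2 = sum(w * x^2),
        bp.p = bp.p,
        stringsAsFactors = FALSE
    )
}

.cbsRecurse <- function(x, w, alpha, nperm, min.width, accept.n) {
    out <- data.frame(after = integer(0), p = numeric(0))
    rec <- function(l, r) {
        n <- r - l + 1L
        if (n < 2L * min.width) return(invisible(NULL))
        res <- .cbs_split(x[l:r], w[l:r], as.integer(min.width),
                          as.integer(nperm), alpha, as.integer(accept.n))
        if (is.na(res$stat) || res$p > alpha) return(invisible(NULL))
        cuts <- integer(0)
        if (res$i > 0L) cuts <- c(cuts, l + res$i - 1L)
        if (res$j < n) cuts <- c(cuts, l + res$j - 1L)
        if (!length(cuts)) return(invisible(NULL))
        out <<- rbind(out, data.frame(after = cuts, p = res$p))
        bounds <- c(l - 1L, cuts, r)
        for (k in seq_len(length(bounds) - 1L)) {
            rec(bounds[k] + 1L, bounds[k + 1L])
        }
        invisible(NULL)
    }
    rec(1L, length(x))
    out
}

# per-segment member SNP mirrored allelic fractions
.segmentSNPIndex <- function(segments, het.snps) {
    lapply(seq_len(nrow(segments)), function(i) {
        which(het.snps$chrom == segments$chrom[i] &
              het.snps$pos - 1L >= segments$start[i] &
              het.snps$pos - 1L < segments$end[i])
    })
}

.mirrored <- function(f) pmin(f, 1 - f)

.mergeSegmentRows <- function(a, b) {
    sw <- a$sum.w + b$sum.w
    swx <- a$sum.wx + b$sum.wx
    swx2 <- a$sum.wx2 + b$sum.wx2
    n <- a$num.targets + b$num.targets
    m <- swx / sw
    v <- (swx2 / sw - m^2) * n / max(n - 1, 1)
    a$end <- b$end
    a$last.target <- b$last.target
    a$num.targets <- n
    a$size <- a$end - a$start
    a$seg.mean <- m
    a$sd <- max(sqrt(max(v, 0)), 1e-4)
    a$sum.w <- sw
    a$sum.wx <- swx
    a$sum.wx2 <- swx2
    a
}

#' Prune borderline breakpoints using germline allelic fractions
#'
#' Breakpoints of borderline significance (permutation p above `prune.p`)
#' are removed when the mirrored allelic fractions (`min(f, 1-f)`) of
#' heterozygous SNPs in the two flanking segments are not significantly
#' different (two-sided Welch t-test p above `t.p`), or when either flank
#' has fewer than `min.snps` SNPs (the test is then undefined and the
#' breakpoint is treated as unsupported). Breakpoints at or below `prune.p`
#' are always kept.
#'
#' @param segments Segment table from [segmentCBS()].
#' @param het.snps Heterozygous SNPs from [selectHetSNPs()].
#' @param prune.p Breakpoints with p-values above this are candidates for
#'   removal.
#' @param t.p Flanks with t-test p above this are merged.
#' @param min.snps Minimum SNPs per flank for the t-test.
#' @return Pruned segment table.
#' @export
pruneBreakpoints <- function(segments, het.snps, prune.p = 0.001,
                             t.p = 0.2, min.snps = 3L) {
    if (nrow(segments) < 2) return(segments)
    i <- 2L
    while (i <= nrow(segments)) {
        same.chrom <- segments$chrom[i] == segments$chrom[i - 1L]
        borderline <- !is.na(segments$bp.p[i]) && segments$bp.p[i] > prune.p
        if (same.chrom && borderline) {
            snp.idx <- .segmentSNPIndex(segments[c(i - 1L, i), , drop = FALSE],
                                        het.snps)
            fl <- .mirrored(het.snps$f[snp.idx[[1]]])
            fr <- .mirrored(het.snps$f[snp.idx[[2]]])
            merge <- if (length(fl) < min.snps || length(fr) < min.snps) {
                TRUE
            } else {
                # degenerate (constant) fractions: not significantly different
                p <- tryCatch(stats::t.test(fl, fr)$p.value,
                              error = function(e) 1)
                p > t.p
            }
            if (merge) {
                merged <- .mergeSegmentRows(segments[i - 1L, , drop = FALSE],
                                            segments[i, , drop = FALSE])
                attrs <- attributes(segments)
                segments <- rbind(segments[seq_len(i - 2L), , drop = FALSE],
                                  merged,
                                  segments[-seq_len(i), , drop = FALSE])
                rownames(segments) <- NULL
                for (a in c("intervals", "retained", "global.sd"))
                    attr(segments, a) <- attrs[[a]]
                next
            }
        }
        i <- i + 1L
    }
    segments
}

#' Split segments at copy-neutral LOH boundaries
#'
#' Within each segment, scans candidate split points at SNP boundaries
#' (leaving at least `min.snps` SNPs per side), picks the split minimizing
#' the pooled standard deviation of mirrored allelic fractions, and accepts
#' it if a two-sided Welch t-test between the sides reaches `alpha`.
#' Accepted halves are recursed into. Children keep the parent's mean
#' log-ratio (the split is copy-neutral in coverage).
#'
#' @param segments Segment table.
#' @param het.snps Heterozygous SNPs.
#' @param alpha Significance threshold for accepting a split.
#' @param min.snps Minimum SNPs per side.
#' @return Segment table with accepted splits applied.
#' @export
splitCNLOH <- function(segments, het.snps, alpha = 0.005, min.snps = 10L) {
    iv <- attr(segments, "intervals")
    retained <- attr(segments, "retained")
    if (is.null(iv)) stop("segments lack the intervals attribute")
    attrs <- attributes(segments)
    out <- NULL
    for (i in seq_len(nrow(segments))) {
        out <- rbind(out, .splitSegmentRec(segments[i, , drop = FALSE],
                                           het.snps, iv, retained,
                                           alpha, min.snps))
    }
    rownames(out) <- NULL
    for (a in c("intervals", "retained", "global.sd"))
        attr(out, a) <- attrs[[a]]
    out
}

.splitSegmentRec <- function(seg, het.snps, iv, retained, alpha, min.snps) {
    idx <- which(het.snps$chrom == seg$chrom &
                 het.snps$pos - 1L >= seg$start &
                 het.snps$pos - 1L < seg$end)
    m <- length(idx)
    if (m < 2L * min.snps) return(seg)
    ord <- idx[order(het.snps$pos[idx])]
    maf <- .mirrored(het.snps$f[ord])
    ks <- seq.int(min.snps, m - min.snps)
    pooled <- vapply(ks, function(k) {
        sl <- stats::var(maf[1:k])
        sr <- stats::var(maf[(k + 1):m])
        sqrt(((k - 1) * sl + (m - k - 1) * sr) / (m - 2))
    }, numeric(1))
    k <- ks[which.min(pooled)]
    p <- tryCatch(stats::t.test(maf[1:k], maf[(k + 1):m])$p.value,
                  error = function(e) 1)
    # Bonferroni over the scanned candidate splits: the split point was
    # chosen to minimize the pooled SD, so the nominal p is optimistic
    p <- min(1, p * length(ks))
    if (is.na(p) || p > alpha) return(seg)
    split.pos <- floor((het.snps$pos[ord[k]] + het.snps$pos[ord[k + 1]]) / 2)
    members <- seq.int(seg$first.target, seg$last.target)
    members <- members[retained[members]]
    left <- members[iv$end[members] <= split.pos]
    right <- setdiff(members, left)
    if (length(left) < 1L || length(right) < 1L) return(seg)
    mk <- function(rows) {
        child <- seg
        child$start <- iv$start[rows[1]]
        child$end <- iv$end[rows[length(rows)]]
        child$first.target <- rows[1]
        child$last.target <- rows[length(rows)]
        frac <- length(rows) / seg$num.targets
        child$num.targets <- length(rows)
        child$size <- child$end - child$start
        child$sum.w <- seg$sum.w * frac
        child$sum.wx <- seg$sum.wx * frac
        child$sum.wx2 <- seg$sum.wx2 * frac
        child$bp.p <- if (identical(rows[1], seg$first.target)) seg$bp.p
                      else 0   # SNP-supported breakpoint: never pruned
        child
    }
    rbind(.splitSegmentRec(mk(left), het.snps, iv, retained, alpha, min.snps),
          .splitSegmentRec(mk(right), het.snps, iv, retained, alpha, min.snps))
}

#' Merge segments with similar log-ratio and allelic fraction (Ward)
#'
#' Clusters segments in the 2D space of mean log-ratio and mean mirrored
#' allelic fraction (missing allelic means imputed at 0.5) by Ward's
#' hierarchical clustering, cuts the tree at `cut.factor * noise.scale`,
#' and normalizes segments within a cluster to the cluster's target-weighted
#' mean log-ratio. Genomic boundaries are unchanged.
#'
#' @param segments Segment table.
#' @param het.snps Heterozygous SNPs (may be empty).
#' @param noise.scale Scale of the cut; defaults to the mean per-segment
#'   log-ratio standard deviation.
#' @param cut.factor Tree cut height as a multiple of `noise.scale`.
#' @return Segment table with harmonized means.
#' @export
mergeWard <- function(segments, het.snps, noise.scale = NULL,
                      cut.factor = 0.5) {
    if (nrow(segments) < 2) return(segments)
    if (is.null(noise.scale)) noise.scale <- mean(segments$sd)
    snp.idx <- .segmentSNPIndex(segments, het.snps)
    maf <- vapply(snp.idx, function(ix) {
        if (length(ix)) mean(.mirrored(het.snps$f[ix])) else NA_real_
    }, numeric(1))
    maf[is.na(maf)] <- 0.5
    hc <- stats::hclust(stats::dist(cbind(segments$seg.mean, maf)),
                        method = "ward.D2")
    cl <- stats::cutree(hc, h = cut.factor * noise.scale)
    for (g in unique(cl)) {
        rows <- which(cl == g)
        if (length(rows) < 2) next
        m <- sum(segments$seg.mean[rows] * segments$num.targets[rows]) /
            sum(segments$num.targets[rows])
        segments$seg.mean[rows] <- m
    }
    segments
}
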