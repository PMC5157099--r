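# Weighted CBS, SNP-based breakpoint pruning, copy-neutral LOH splitting,
# and Ward merging.

test_that("a constant profile yields a single segment", {
    prof <- mkProfile(rep(0, 100))
    segs <- segmentCBS(prof, nperm = 2000L)
    expect_equal(nrow(segs), 1L)
    expect_equal(segs$num.targets, 100L)
    expect_equal(segs$seg.mean, 0)
})

test_that("a step of height 1 is found within 2 targets of the true breakpoint", {
    set.seed(11)
    lr <- c(rnorm(100, 0, 0.1), rnorm(100, 1, 0.1))
    segs <- segmentCBS(mkProfile(lr))
    expect_equal(nrow(segs), 2L)
    expect_lte(abs(segs$num.targets[1] - 100L), 2L)
    expect_lt(abs(segs$seg.mean[1]), 0.1)
    expect_gt(segs$seg.mean[2], 0.9)
    expect_true(all(segs$sd > 0))
})

test_that("down-weighted outlier targets do not create extra segments", {
    set.seed(12)
    lr <- c(rnorm(100, 0, 0.1), rnorm(100, 1, 0.1))
    out.idx <- c(10, 30, 50, 70, 90)
    lr[out.idx] <- 3
    w <- rep(1, 200)
    w[out.idx] <- 0.01
    segs <- segmentCBS(mkProfile(lr, weights = w))
    expect_equal(nrow(segs), 2L)
})

test_that("segments tile the retained targets without gaps or overlaps", {
    set.seed(13)
    lr <- c(rnorm(60, 0, 0.1), rnorm(60, 0.8, 0.1), rnorm(80, -0.5, 0.1))
    iv <- mkIntervals(200, chrom = c("chr1", "chr2"))
    segs <- segmentCBS(mkProfile(lr, intervals = iv))
    expect_equal(sum(segs$num.targets), 200L)
    for (ch in unique(segs$chrom)) {
        s <- segs[segs$chrom == ch, ]
        expect_equal(s$first.target[-1], s$last.target[-nrow(s)] + 1L)
    }
    # tiling preserved by downstream refinement with zero SNPs
    empty <- data.frame(chrom = character(0), pos = integer(0),
                        f = numeric(0))
    refined <- mergeWard(splitCNLOH(pruneBreakpoints(segs, empty), empty),
                         empty)
    expect_equal(sum(refined$num.targets), 200L)
})

test_that("borderline breakpoints with indistinguishable flanks are merged", {
    set.seed(14)
    iv <- mkIntervals(100)
    segs <- mkSegments("chr1", c(0L, 50000L), c(50000L, 100000L),
                       c(0.02, -0.02), num.targets = 50L,
                       bp.p = c(NA, 0.01), intervals = iv)
    snps <- data.frame(
        chrom = "chr1",
        pos = as.integer(seq(1000, 99000, length.out = 40)),
        f = rep(c(0.48, 0.52), 20))
    merged <- pruneBreakpoints(segs, snps)
    expect_equal(nrow(merged), 1L)
    expect_equal(merged$num.targets, 100L)
})

test_that("significant breakpoints are kept regardless of SNP support", {
    iv <- mkIntervals(100)
    segs <- mkSegments("chr1", c(0L, 50000L), c(50000L, 100000L),
                       c(0.02, -0.02), bp.p = c(NA, 1e-4), intervals = iv)
    empty <- data.frame(chrom = character(0), pos = integer(0),
                        f = numeric(0))
    expect_equal(nrow(pruneBreakpoints(segs, empty)), 2L)
})

test_that("breakpoints with clearly different flanking fractions survive pruning", {
    set.seed(15)
    iv <- mkIntervals(100)
    segs <- mkSegments("chr1", c(0L, 50000L), c(50000L, 100000L),
                       c(0.02, -0.02), bp.p = c(NA, 0.01), intervals = iv)
    snps <- data.frame(
        chrom = "chr1",
        pos = as.integer(c(seq(1000, 49000, length.out = 20),
                           seq(51000, 99000, length.out = 20))),
        f = c(rnorm(20, 0.5, 0.01), rnorm(20, 0.25, 0.01)))
    expect_equal(nrow(pruneBreakpoints(segs, snps)), 2L)
})

test_that("a too-sparse flank counts as unsupported and merges", {
    iv <- mkIntervals(100)
    segs <- mkSegments("chr1", c(0L, 50000L), c(50000L, 100000L),
                       c(0.02, -0.02), bp.p = c(NA, 0.01), intervals = iv)
    snps <- data.frame(chrom = "chr1", pos = c(1000L, 2000L, 60000L),
                       f = c(0.5, 0.5, 0.2))   # 2 SNPs left of the breakpoint
    expect_equal(nrow(pruneBreakpoints(segs, snps)), 1L)
})

test_that("copy-neutral LOH splitting finds the change point in mirrored fractions", {
    set.seed(16)
    iv <- mkIntervals(120)
    segs <- mkSegments("chr1", 0L, 120000L, 0, num.targets = 120L,
                       intervals = iv)
    pos <- as.integer(seq(1000, 119000, length.out = 60))
    f <- c(rnorm(30, 0.5, 0.03),
           ifelse(runif(30) < 0.5, rnorm(30, 0.2, 0.03),
                  rnorm(30, 0.8, 0.03)))
    snps <- data.frame(chrom = "chr1", pos = pos, f = f)
    out <- splitCNLOH(segs, snps)
    expect_equal(nrow(out), 2L)
    # split within 3 SNPs of the true change point (SNP 30)
    bp <- out$end[1]
    true.bp <- (pos[30] + pos[31]) / 2
    snp.gap <- diff(pos)[1]
    expect_lt(abs(bp - true.bp), 3 * snp.gap + 1000)
    # children keep the parent's mean (copy-neutral) and tile the parent
    expect_equal(out$seg.mean, c(0, 0))
    expect_equal(sum(out$num.targets), 120L)
})

test_that("uniform fractions and sparse segments are not split", {
    set.seed(17)
    iv <- mkIntervals(100)
    segs <- mkSegments("chr1", 0L, 100000L, 0, num.targets = 100L,
                       intervals = iv)
    snps <- data.frame(chrom = "chr1",
                       pos = as.integer(seq(1000, 99000, length.out = 40)),
                       f = rnorm(40, 0.5, 0.03))
    expect_equal(nrow(splitCNLOH(segs, snps)), 1L)
    # 12 SNPs with min.snps = 10 leaves no candidate split
    snps12 <- snps[1:12, ]
    snps12$f <- c(rep(0.5, 6), rep(0.2, 6))
    expect_equal(nrow(splitCNLOH(segs, snps12, min.snps = 10L)), 1L)
})

test_that("Ward merging harmonizes means of similar segments only", {
    iv <- mkIntervals(150)
    segs <- mkSegments("chr1", c(0L, 50000L, 100000L),
                       c(50000L, 100000L, 150000L),
                       c(0.01, -0.01, 1.0), sd = 0.1, num.targets = 50L,
                       intervals = iv)
    empty <- data.frame(chrom = character(0), pos = integer(0),
                        f = numeric(0))
    out <- mergeWard(segs, empty, noise.scale = 0.1)
    expect_equal(out$seg.mean[1], out$seg.mean[2])
    expect_equal(out$seg.mean[3], 1.0)
    expect_equal(nrow(out), 3L)   # boundaries unchanged
    # identical segments on different chromosomes share the merged mean
    segs2 <- mkSegments(c("chr1", "chr2"), c(0L, 0L), c(50000L, 50000L),
                        c(0.3, 0.3), intervals = iv)
    out2 <- mergeWard(segs2, empty, noise.scale = 0.1)
    expect_equal(out2$seg.mean[1], out2$seg.mean[2])
    # single segment untouched
    expect_equal(nrow(mergeWard(segs[1, ], empty, noise.scale = 0.1)), 1L)
})

test_that("segmentation recovers nearly all true breakpoints with few spurious ones", {
    set.seed(18)
    n.seg <- 20
    len <- rep(100, n.seg)
    means <- rep(c(0, 0.6), length.out = n.seg)   # >= 0.5 copy difference
    lr <- unlist(mapply(function(m, l) rnorm(l, m, 0.2), means, len,
                        SIMPLIFY = FALSE))
    iv <- mkIntervals(2000, chrom = paste0("chr", 1:4))
    segs <- segmentCBS(mkProfile(lr, intervals = iv))
    true.bp <- cumsum(len)[-n.seg]
    chrom.starts <- (0:3) * 500
    found.bp <- setdiff(segs$first.target - 1L, chrom.starts)
    true.bp <- setdiff(true.bp, chrom.starts)  # these coincide with
                                               # chromosome boundaries
    hit <- vapply(true.bp, function(b) any(abs(found.bp - b) <= 2),
                  logical(1))
    expect_gte(mean(hit), 0.95)
    spurious <- sum(vapply(found.bp, function(b)
        all(abs(true.bp - b) > 2), logical(1)))
    expect_lte(spurious, 2)   # <= 1 per 1000 targets
})
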