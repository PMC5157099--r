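# Purity/ploidy model: segment likelihood, grid search, heated Gibbs
# assignment of integer copy numbers, and the SEG entry point.

test_that("segment likelihood anchors match the model's closed forms", {
    # pure diploid: expected log-ratio 0, so r = 0 attains the maximum
    ll0 <- segmentLogLik(0, 0.1, 50, purity = 1, C = 2, ploidy = 2)
    expect_equal(ll0, 50 * dnorm(0, 0, 0.1, log = TRUE))
    expect_gt(ll0, segmentLogLik(0.05, 0.1, 50, 1, 2, 2))

    # p = 0.5, C = 4, D = 2: expected log-ratio log2(3/2)
    r.star <- log2(3 / 2)
    expect_equal(segmentLogLik(r.star, 0.1, 50, 0.5, 4, 2),
                 50 * dnorm(0, 0, 0.1, log = TRUE))

    # vanishing purity hides all tumor signal: every C fits r = 0 equally
    lls <- vapply(0:7, function(C)
        segmentLogLik(0, 0.1, 50, 1e-9, C, 2), numeric(1))
    expect_lt(diff(range(lls)), 1e-6)

    expect_error(segmentLogLik(0, 0.1, 50, 0.5, -1, 2), "C")
})

test_that("non-aberrant purity ridges collapse to one optimum each", {
    segs <- mkSegments("chr1", c(0L, 150000L), c(150000L, 300000L),
                       c(0, 0), sd = 0.05)
    opt <- gridSearch(segs)
    # a flat genome is aliased across integer ploidies; the purity ridge at
    # each must collapse to a single representative, including one at D = 2
    expect_true(any(abs(opt$ploidy - 2) < 1e-9))
    expect_equal(sum(abs(opt$ploidy - 2) < 1e-9), 1L)
    expect_true(all(table(opt$ploidy) == 1))
})

test_that("grid search recovers a constructed truth and its whole-genome-doubled alias", {
    set.seed(21)
    C <- rep(c(1, 2, 3, 2), 5)
    segs <- mkExactSegments(C, purity = 0.4, sd = 0.05)
    opt <- gridSearch(segs)
    truth.hit <- any(abs(opt$purity - 0.4) <= 0.05 &
                     abs(opt$ploidy - 2) <= 0.2)
    alias.hit <- any(opt$ploidy >= 3.5)
    expect_true(truth.hit)
    expect_true(alias.hit)
    expect_gte(nrow(opt), 2L)
})

test_that("grid search brackets a simulated truth among its local optima", {
    truth <- simulateGenome(n.segments = 40, n.targets = 2000, purity = 0.6,
                            target.ploidy = 3.0, seed = 22)
    segs <- mkExactSegments(truth$segments$C, purity = 0.6, sd = 0.05,
                            size = truth$segments$size)
    opt <- gridSearch(segs)
    expect_true(any(abs(opt$purity - 0.6) <= 0.05 &
                    abs(opt$ploidy - truth$ploidy) <= 0.2))
})

test_that("heated Gibbs recovers exact copy numbers and matches brute force", {
    p <- 0.7
    segs <- mkExactSegments(c(1, 2, 3), purity = p, sd = 0.05)
    D <- sum(segs$size * c(1, 2, 3)) / sum(segs$size)
    sol <- fitSolution(segs, p, D, seed = 1, fit.purity = FALSE,
                       fit.shift = FALSE)
    expect_equal(sol$C, c(1, 2, 3))
    expect_equal(sol$ploidy, D, tolerance = 1e-9)
    # brute-force enumeration over all 8^3 assignments (self-consistent D)
    grid <- as.matrix(expand.grid(0:7, 0:7, 0:7))
    ll <- apply(grid, 1, function(cc) {
        Dg <- sum(segs$size * cc) / sum(segs$size)
        if (Dg <= 0) return(-Inf)
        sum(segmentLogLik(segs$seg.mean, segs$sd, segs$num.targets,
                          p, cc, Dg))
    })
    expect_equal(sol$C, unname(grid[which.max(ll), ]))
})

test_that("a flat profile fits all-diploid with ploidy exactly 2", {
    segs <- mkSegments("chr1", c(0L, 150000L, 300000L),
                       c(150000L, 300000L, 450000L), c(0, 0, 0), sd = 0.05)
    sol <- fitSolution(segs, 0.7, 2.0, seed = 2)
    expect_equal(sol$C, c(2, 2, 2))
    expect_equal(sol$ploidy, 2.0, tolerance = 1e-9)
    expect_false(sol$discarded)
})

test_that("log-ratios far above the highest integer state go sub-clonal", {
    # a short focal amplification far above the C = 7 expectation
    segs <- mkSegments("chr1", c(0L, 150000L, 300000L, 450000L),
                       c(150000L, 300000L, 450000L, 451000L),
                       c(0, 0, 0, 3.5), sd = 0.05,
                       num.targets = c(50L, 50L, 50L, 1L))
    sol <- fitSolution(segs, 0.7, 2.0, seed = 3)
    expect_true(sol$subclonal[4])
    expect_true(is.na(sol$C[4]))
    expect_equal(sol$C[1:3], c(2, 2, 2))
})

test_that("copy-number posteriors are normalized and ploidy is consistent", {
    set.seed(23)
    segs <- mkExactSegments(c(1, 2, 4, 2, 3), purity = 0.5, sd = 0.05)
    D <- sum(segs$size * c(1, 2, 4, 2, 3)) / sum(segs$size)
    sol <- fitSolution(segs, 0.5, D, seed = 4)
    expect_equal(rowSums(sol$posterior), rep(1, 5), tolerance = 1e-9)
    cc <- ifelse(sol$subclonal, NA, sol$C)
    expect_equal(sum(segs$size * cc) / sum(segs$size), sol$ploidy,
                 tolerance = 1e-9)
    expect_equal(sol$total.loglik, sol$cn.loglik + 0 * sol$total.loglik +
                 ifelse(is.na(sol$snv.loglik), 0, sol$snv.loglik))
})

test_that("identical seeds reproduce identical solutions", {
    set.seed(24)
    segs <- mkExactSegments(c(1, 3, 2, 2), purity = 0.45, sd = 0.1)
    s1 <- fitSolution(segs, 0.45, 2.1, seed = 77)
    s2 <- fitSolution(segs, 0.45, 2.1, seed = 77)
    expect_identical(s1$C, s2$C)
    expect_identical(s1$purity, s2$purity)
    expect_identical(s1$posterior, s2$posterior)
})

test_that("solutions with uncorrectable log-ratio miscalibration are discarded", {
    # a right-shift far beyond the recalibration range drags the converged
    # ploidy away from the candidate
    segs <- mkExactSegments(c(1, 2, 3), purity = 0.9, sd = 0.05)
    segs$seg.mean <- segs$seg.mean + 0.8
    sol <- fitSolution(segs, 0.9, 2.0, seed = 5)
    expect_true(sol$discarded)
})

test_that("external SEG rows map onto the target grid", {
    iv <- mkIntervals(100, spacing = 1000L)
    seg <- data.frame(sample = "s", chrom = "chr1",
                      start = c(0L, 50000L, 500000L),
                      end = c(50000L, 99500L, 600000L),
                      num.targets = c(0L, 0L, 0L),
                      seg.mean = c(0.58, -0.3, 1.0))
    expect_warning(out <- ingestSegmentation(seg, iv), "dropped")
    expect_equal(nrow(out), 2L)
    expect_equal(out$num.targets[1], 50L)
    expect_equal(out$seg.mean[1], 0.58)
    expect_equal(out$sd, c(0.1, 0.1))
    seg$sd <- c(0.2, 0.3, 0.4)
    expect_warning(out2 <- ingestSegmentation(seg, iv), "dropped")
    expect_equal(out2$sd, c(0.2, 0.3))
})
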