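# Goodness of fit, bootstrap re-ranking, ranking and sample flags.

mkFit <- function(dev, n = 50) {
    f <- rep(0.5, n)
    structure(list(calls = data.frame(f = f, expected.af = f - dev,
                                      loglik.ml = rep(-1, n))),
              class = "tumorcn_variant_fit")
}

mkRankSolution <- function(cn, snv, purity = 0.6, ploidy = 2,
                           variant.loglik = NULL, discarded = FALSE) {
    structure(list(purity = purity, ploidy = ploidy, cn.loglik = cn,
                   snv.loglik = snv, total.loglik = cn + snv,
                   variant.loglik = variant.loglik,
                   subclonal = logical(0),
                   bootstrap.value = NA_real_, rank = NA_integer_,
                   discarded = discarded, flags = character(0)),
              class = "tumorcn_solution")
}

test_that("goodness of fit is anchored at deviations 0, 0.1 and 0.2", {
    expect_equal(goodnessOfFit(mkFit(0)), 100)
    expect_equal(goodnessOfFit(mkFit(0.1)), 50)
    expect_equal(goodnessOfFit(mkFit(0.2)), 0)
    expect_equal(goodnessOfFit(mkFit(0.3)), 0)    # floored, never negative
    expect_true(is.na(goodnessOfFit(list(calls = NULL))))
})

test_that("goodness of fit is monotone in the mean deviation", {
    devs <- seq(0, 0.25, by = 0.05)
    gofs <- vapply(devs, function(d) goodnessOfFit(mkFit(d)), numeric(1))
    expect_true(all(diff(gofs) <= 0))
    expect_true(all(gofs >= 0 & gofs <= 100))
})

test_that("a single solution gets bootstrap value 1 and survives", {
    s <- mkRankSolution(-10, -5, variant.loglik = rep(-1, 30))
    out <- bootstrapRank(list(s), seed = 1)
    expect_equal(out$solutions[[1]]$bootstrap.value, 1)
    expect_length(out$flags, 0)
})

test_that("a dominated solution is removed with bootstrap value 0", {
    n <- 30
    s1 <- mkRankSolution(-10, -30, variant.loglik = rep(-1, n))
    s2 <- mkRankSolution(-10, -3000, ploidy = 4,
                         variant.loglik = rep(-100, n))
    s3 <- mkRankSolution(-12, -32, ploidy = 3,
                         variant.loglik = rep(-32 / n, n))
    out <- bootstrapRank(list(s1, s2, s3), seed = 2)
    ploidies <- vapply(out$solutions, `[[`, numeric(1), "ploidy")
    expect_false(4 %in% ploidies)        # never in the top 2
    expect_equal(out$solutions[[1]]$bootstrap.value, 1)
    bv <- vapply(out$solutions, `[[`, numeric(1), "bootstrap.value")
    expect_lte(sum(bv), 1 + 1e-9)
})

test_that("near-identical solutions are both retained and flagged ambiguous", {
    set.seed(3)
    n <- 40
    base <- rnorm(n, -1, 0.5)
    base2 <- base[sample.int(n)]   # equal total, per-variant scores cross
    s1 <- mkRankSolution(-10, sum(base), variant.loglik = base)
    s2 <- mkRankSolution(-10, sum(base2), ploidy = 2.1,
                         variant.loglik = base2)
    out <- bootstrapRank(list(s1, s2), seed = 3)
    expect_length(out$solutions, 2L)
    expect_equal(out$flags, "ambiguous solutions")
})

test_that("too few variants skips the bootstrap with a flag", {
    s1 <- mkRankSolution(-10, -5, variant.loglik = rep(-1, 5))
    s2 <- mkRankSolution(-11, -6, variant.loglik = rep(-1.2, 5))
    out <- bootstrapRank(list(s1, s2), seed = 4)
    expect_equal(out$flags, "too few variants for bootstrap")
    expect_length(out$solutions, 2L)
})

test_that("ranking orders by total log-likelihood and skips discarded fits", {
    s1 <- mkRankSolution(-10, -5)
    s2 <- mkRankSolution(-10, -2, ploidy = 3)
    s3 <- mkRankSolution(-1, -1, ploidy = 5, discarded = TRUE)
    ranked <- rankSolutions(list(s1, s2, s3), haploid.adjust = FALSE)
    expect_equal(ranked[[1]]$ploidy, 3)
    expect_equal(ranked[[1]]$rank, 1L)
    expect_true(ranked[[3]]$discarded)
    expect_true(is.na(ranked[[3]]$rank))
    # removing one solution never reorders the rest
    ranked2 <- rankSolutions(list(s1, s2), haploid.adjust = FALSE)
    expect_equal(ranked2[[1]]$ploidy, 3)
})

test_that("low-purity haploid solutions lose their SNV advantage to diploids", {
    hap <- mkRankSolution(-10, -4, purity = 0.25, ploidy = 1.1)
    dip <- mkRankSolution(-10, -5, purity = 0.5, ploidy = 2.0)
    unadj <- rankSolutions(list(hap, dip), haploid.adjust = FALSE)
    expect_equal(unadj[[1]]$ploidy, 1.1)
    adj <- rankSolutions(list(hap, dip), haploid.adjust = TRUE)
    # with equalized priors the tie resolves by the capped score order
    expect_equal(adj[[1]]$ploidy, 2.0)
})

test_that("sample flags fire at their documented thresholds", {
    segs <- mkSegments("chr1", c(0L, 500000L), c(500000L, 1000000L),
                       c(0, 0), sd = 0.05)
    segs$C <- c(2L, 2L); segs$K <- c(1L, 1L); segs$loh <- c(FALSE, FALSE)
    clean <- mkRankSolution(-10, -5, purity = 1, ploidy = 2)
    clean$subclonal <- c(FALSE, FALSE)
    expect_equal(flagSample(clean, segs), "NON_ABERRANT")

    rare <- mkRankSolution(-10, -5, ploidy = 1.1)
    rare$subclonal <- c(FALSE, FALSE)
    segs.ab <- segs
    segs.ab$C <- c(1L, 2L); segs.ab$K <- c(0L, 1L)
    segs.ab$loh <- c(TRUE, FALSE)
    expect_true("RARE_PLOIDY" %in% flagSample(rare, segs.ab))

    noisy <- segs.ab
    noisy$sd <- 0.3
    expect_true("NOISY_SEGMENTATION" %in% flagSample(rare, noisy))

    loh <- segs.ab
    loh$loh <- c(TRUE, TRUE); loh$C <- c(1L, 3L); loh$K <- c(0L, 0L)
    expect_true("EXCESSIVE_LOH" %in%
                flagSample(mkRankSolution(-10, -5, ploidy = 2) |>
                           (\(s) { s$subclonal <- c(FALSE, FALSE); s })(),
                           loh))

    # 5% of dbSNP variants in contamination states
    calls <- data.frame(
        in.dbsnp = rep(TRUE, 100),
        ml.state = c(rep("CONTAMINATION_REF", 5), rep("GERMLINE_M1_C2", 95)),
        f = 0.5, expected.af = 0.5)
    fit <- structure(list(calls = calls), class = "tumorcn_variant_fit")
    sol <- mkRankSolution(-10, -5, ploidy = 2)
    sol$subclonal <- c(FALSE, FALSE)
    expect_true("CONTAMINATION" %in% flagSample(sol, segs.ab, fit))
    expect_true("LOW_GOF" %in% flagSample(sol, segs.ab, fit, gof = 50))
})
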