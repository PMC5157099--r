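# SNV likelihood model: expected fractions, Beta likelihood, multiplicity
# prior, somatic priors, per-variant posteriors and filtering.

test_that("expected allelic fractions match hand arithmetic", {
    expect_equal(expectedAF(1, 2, 1, 1), 0.5)
    expect_equal(expectedAF(0.65, 2, 1, 0), 0.325)
    expect_equal(expectedAF(0.7, 1, 1, 1), 1 / 1.3)
    expect_error(expectedAF(1, 0, 0, 0), "undefined")
    # the sub-clonal reading: a clonal heterozygous somatic variant at its
    # expectation has cellular fraction exactly 1
    f <- expectedAF(0.65, 2, 1, 0)
    expect_equal((f / 1) * (0.65 * 2 + 2 * 0.35) / 0.65, 1.0)
})

test_that("Beta likelihood matches the closed form and caps depth", {
    # n = 2, f = 0.5: Beta(2,2) density at 0.5 is 6 * 0.25 = 1.5
    expect_equal(afLogLik(0.5, 2, 0.5), log(1.5), tolerance = 1e-9)
    # the maximum over the expected fraction is at the observed fraction
    grid <- seq(0.01, 0.99, by = 0.01)
    ll <- afLogLik(0.3, 100, grid)
    expect_equal(grid[which.max(ll)], 0.3)
    # depths above the cap are computed at the cap
    expect_equal(afLogLik(0.4, 500, 0.35), afLogLik(0.4, 300, 0.35))
    expect_false(isTRUE(all.equal(afLogLik(0.4, 200, 0.35),
                                  afLogLik(0.4, 300, 0.35))))
})

test_that("the multiplicity prior reproduces its defining table and sums to 1", {
    # germline, C=2, K=1: allowed M=1; M=0 and M=2 share 1 - PK
    expect_equal(multiplicityPrior(1, 1, 2, 1), 0.999, tolerance = 1e-12)
    expect_equal(multiplicityPrior(0, 1, 2, 1), 0.0005, tolerance = 1e-12)
    expect_equal(multiplicityPrior(2, 1, 2, 1), 0.0005, tolerance = 1e-12)
    # impossible minor copy number
    expect_equal(multiplicityPrior(2, 2, 3, 1), 0)
    # somatic, C=2, K=1: M in {1/3, 1} allowed (K = C-K = 1), M=2 is not
    ms <- c(1 / 3, 1, 2)
    pr <- vapply(ms, multiplicityPrior, numeric(1), K = 1, C = 2, g = 0)
    expect_equal(pr, c(0.999 / 2, 0.999 / 2, 0.001))
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    # somatic, C=2, K=0: every support state allowed -> all mass, 1/3 each
    pr0 <- vapply(ms, multiplicityPrior, numeric(1), K = 0, C = 2, g = 0)
    expect_equal(pr0, rep(1 / 3, 3))
})

test_that("the multiplicity prior is normalized for every C, K, g", {
    for (C in 0:7) {
        for (K in 0:floor(C / 2)) {
            for (g in c(0, 1)) {
                support <- if (g == 1) 0:C else c(1 / 3, seq_len(C))
                total <- sum(vapply(support, multiplicityPrior, numeric(1),
                                    K = K, C = C, g = g))
                expect_equal(total, 1, tolerance = 1e-9,
                             label = sprintf("C=%d K=%d g=%d", C, K, g))
            }
        }
    }
})

test_that("somatic priors follow the database-evidence table", {
    expect_equal(somaticPrior(FALSE, 5), 0.95)
    expect_equal(somaticPrior(TRUE, 0), 0.0005)
    expect_equal(somaticPrior(TRUE, 5), 0.01)
    expect_equal(somaticPrior(FALSE, 0), 0.5)
    expect_equal(somaticPrior(FALSE, 0, "somatic", matched = TRUE), 0.999)
    expect_equal(somaticPrior(TRUE, 0, "germline", matched = TRUE), 0.0001)
})

test_that("contamination-state expectations match hand arithmetic", {
    caf <- contaminationAF(0.6, 2, 0.01)
    expect_equal(caf[["ref"]], 0.99, tolerance = 1e-12)
    expect_equal(caf[["alt"]], 0.005, tolerance = 1e-12)
})

# independent enumeration oracle for the posterior of one variant in a
# segment with a known copy-number posterior
oraclePosterior <- function(f, n, pC, p, prior.somatic, PK = 0.999,
                            n.cap = 300) {
    n <- min(n, n.cap)
    states <- list()
    for (C in 0:7) {
        for (K in 0:floor(C / 2)) {
            for (g in c(1, 0)) {
                support <- if (g == 1) 0:C else c(1 / 3, seq_len(C))
                for (M in support) {
                    ef <- (p * M + g * (1 - p)) / (p * C + 2 * (1 - p))
                    w <- pC[C + 1] * (1 / (C + 1)) *
                        multiplicityPrior(M, K, C, g, PK) *
                        (if (g == 0) prior.somatic else 1 - prior.somatic)
                    lik <- dbeta(ef, n * f + 1, n * (1 - f) + 1)
                    states[[length(states) + 1]] <-
                        data.frame(C = C, K = K, M = M, g = g, w = w * lik)
                }
            }
        }
    }
    st <- do.call(rbind, states)
    st$w <- st$w / sum(st$w)
    st
}

test_that("variant posteriors match the exhaustive enumeration oracle", {
    segs <- mkSegments("chr1", 0L, 100000L, 0, num.targets = 100L)
    for (case in list(list(f = 0.33, n = 200, db = FALSE, somatic = TRUE),
                      list(f = 0.50, n = 200, db = TRUE, somatic = FALSE))) {
        sol <- mkSolution(2L, 0.65, segs)
        v <- mkVariant(case$f, case$n, in.dbsnp = case$db)
        fit <- fitVariants(v, segs, sol, contamination = FALSE)
        pr <- somaticPrior(case$db, 0L)
        pC <- sol$posterior[1, 1:8] / sum(sol$posterior[1, 1:8])
        oracle <- oraclePosterior(case$f, case$n, pC, 0.65, pr)
        p.som <- sum(oracle$w[oracle$g == 0])
        expect_equal(fit$calls$posterior.somatic, p.som, tolerance = 1e-6)
        expect_equal(fit$calls$ml.somatic, case$somatic)
        agg <- aggregate(w ~ C + M + g, oracle, sum)
        best <- agg[which.max(agg$w), ]
        expect_equal(fit$calls$ml.C, best$C)
        expect_equal(fit$calls$ml.M, best$M)
    }
})

test_that("a clonal somatic variant at its expectation has cellular fraction 1", {
    segs <- mkSegments("chr1", 0L, 100000L, 0, num.targets = 100L)
    sol <- mkSolution(2L, 0.65, segs)
    v <- mkVariant(0.325, 200)
    fit <- fitVariants(v, segs, sol)
    expect_true(fit$calls$ml.somatic)
    expect_equal(fit$calls$ml.M, 1)
    expect_equal(fit$calls$h.raw, 1.0, tolerance = 0.05)
})

test_that("posteriors are normalized under every state configuration", {
    segs <- mkSegments("chr1", 0L, 100000L, 0, num.targets = 100L)
    sol <- mkSolution(3L, 0.5, segs)
    vs <- rbind(mkVariant(0.25, 120, in.dbsnp = TRUE),
                mkVariant(0.5, 80, pos = 600L),
                mkVariant(0.98, 150, pos = 700L, in.dbsnp = TRUE),
                mkVariant(0.07, 90, pos = 800L, cosmic.count = 4L))
    for (cont in c(TRUE, FALSE)) {
        for (hp in c(TRUE, FALSE)) {
            fit <- fitVariants(vs, segs, sol, contamination = cont,
                               high.purity = hp)
            expect_equal(unname(rowSums(fit$posterior)), rep(1, 4),
                         tolerance = 1e-9)
        }
    }
})

test_that("dbSNP variants with near-1 fractions can be called contamination", {
    segs <- mkSegments("chr1", 0L, 100000L, 0, num.targets = 100L)
    sol <- mkSolution(2L, 0.6, segs)
    v <- mkVariant(0.99, 300, in.dbsnp = TRUE)
    fit <- fitVariants(v, segs, sol, contamination = TRUE)
    expect_equal(fit$calls$ml.state, "CONTAMINATION_REF")
    # without the contamination states the variant lands in a germline state
    fit2 <- fitVariants(v, segs, sol, contamination = FALSE)
    expect_false(grepl("CONTAMINATION", fit2$calls$ml.state))
})

test_that("high-purity mode models homozygous SNPs instead of dropping them", {
    segs <- mkSegments("chr1", 0L, 100000L, 0, num.targets = 100L)
    sol <- mkSolution(2L, 0.95, segs)
    v <- mkVariant(1.0, 300, in.dbsnp = TRUE)
    filt <- filterVariants(v, high.purity = TRUE)
    expect_equal(nrow(filt$variants), 1L)
    fit <- fitVariants(filt$variants, segs, sol, high.purity = TRUE,
                       contamination = FALSE)
    expect_equal(fit$calls$ml.state, "GERMLINE_HOMOZYGOUS")
})

test_that("homozygous and mapping-biased variants are filtered", {
    vs <- rbind(
        mkVariant(0.6, 100, normal.f = 1.0, normal.n = 80),     # hom in normal
        mkVariant(0.5, 100, pos = 600L, normal.f = 0.5, normal.n = 100),
        mkVariant(0.35, 100, pos = 700L, normal.f = 0.30, normal.n = 300),
        mkVariant(0.97, 100, pos = 800L),                       # hom, unmatched
        mkVariant(0.5, 100, pos = 900L))
    out <- filterVariants(vs)
    expect_equal(out$removed$reason,
                 c("removed_homozygous", "removed_mapping_bias",
                   "removed_homozygous"))
    expect_equal(out$variants$pos, c(600L, 900L))
    # pool-of-normals version: biased in >= 50% of >= 5 informative normals
    v <- mkVariant(0.5, 100)
    af <- matrix(0.3, 1, 6)
    nn <- matrix(300, 1, 6)
    out2 <- filterVariants(v, pool.af = list(af = af, n = nn))
    expect_equal(out2$removed$reason, "removed_mapping_bias_pool")
    af.few <- matrix(c(0.3, 0.3, 0.3, NA, NA, NA), 1, 6)
    out3 <- filterVariants(v, pool.af = list(af = af.few, n = nn))
    expect_equal(nrow(out3$variants), 1L)
})

test_that("COSMIC evidence never decreases the somatic posterior", {
    segs <- mkSegments("chr1", 0L, 100000L, 0, num.targets = 100L)
    sol <- mkSolution(2L, 0.6, segs)
    for (f in c(0.1, 0.3, 0.5)) {
        p0 <- fitVariants(mkVariant(f, 150), segs,
                          sol)$calls$posterior.somatic
        p3 <- fitVariants(mkVariant(f, 150, cosmic.count = 3L), segs,
                          sol)$calls$posterior.somatic
        expect_gte(p3, p0)
    }
})

test_that("the SNV log-likelihood is additive over variants", {
    segs <- mkSegments("chr1", 0L, 100000L, 0, num.targets = 100L)
    sol <- mkSolution(2L, 0.6, segs)
    vs <- rbind(mkVariant(0.3, 100), mkVariant(0.5, 120, pos = 600L))
    fit1 <- fitVariants(vs, segs, sol)
    fit2 <- fitVariants(rbind(vs, vs), segs, sol)
    expect_equal(snvLogLik(fit2), 2 * snvLogLik(fit1), tolerance = 1e-9)
    # no variants: zero log-likelihood and an explicit flag
    none <- fitVariants(vs[0, ], segs, sol)
    expect_equal(snvLogLik(none), 0)
    expect_true("no variants" %in% none$flags)
})

test_that("variants outside all segments are skipped with a record", {
    segs <- mkSegments("chr1", 0L, 100000L, 0, num.targets = 100L)
    sol <- mkSolution(2L, 0.6, segs)
    vs <- rbind(mkVariant(0.3, 100),
                mkVariant(0.4, 100, chrom = "chr9", pos = 5000L))
    fit <- fitVariants(vs, segs, sol)
    expect_equal(nrow(fit$calls), 1L)
    expect_equal(nrow(fit$skipped), 1L)
    expect_equal(fit$skipped$chrom, "chr9")
})

test_that("post-optimization moves purity toward the truth", {
    set.seed(31)
    truth <- simulateGenome(n.segments = 15, n.targets = 600, purity = 0.5,
                            target.ploidy = 2.2, seed = 32)
    segs <- mkExactSegments(truth$segments$C, purity = 0.5, sd = 0.05,
                            size = truth$segments$size)
    attr(segs, "intervals") <- NULL
    segs$chrom <- truth$segments$chrom
    segs$start <- truth$segments$start
    segs$end <- truth$segments$end
    variants <- simulateVariants(truth, depth = 100, n.germline = 120,
                                 n.somatic = 40, seed = 33)
    start <- fitSolution(segs, 0.55, truth$ploidy, seed = 34,
                         fit.purity = FALSE, fit.shift = FALSE)
    start$purity <- 0.55   # deliberately perturbed away from the truth
    po <- postOptimize(start, segs, variants)
    expect_lte(abs(po$solution$purity - 0.5), abs(0.55 - 0.5))
    fit.start <- fitVariants(variants, segs, start)
    expect_gte(po$solution$cn.loglik + po$variant.fit$snv.loglik,
               start$cn.loglik + fit.start$snv.loglik)
})

test_that("LOH is called from germline fractions: C2/K0 yes, C2/K1 no", {
    truth <- simulateGenome(n.segments = 4, n.targets = 400, purity = 0.7,
                            target.ploidy = 2.0, seed = 35, force.C = 2L)
    truth$segments$K <- c(0L, 1L, 0L, 1L)
    variants <- simulateVariants(truth, depth = 150, n.germline = 200,
                                 n.somatic = 0, seed = 36)
    segs <- truth$segments
    segs$seg.mean <- 0
    segs$sd <- 0.05
    sol <- mkSolution(rep(2L, 4), 0.7, segs)
    fit <- fitVariants(variants, segs, sol)
    out <- callLOH(segs, sol, fit)
    expect_equal(out$K, c(0L, 1L, 0L, 1L))
    expect_equal(out$loh, c(TRUE, FALSE, TRUE, FALSE))
})
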