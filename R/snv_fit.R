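# SNV likelihood model: somatic vs. germline classification, multiplicity
# and clonality, per-variant state posteriors, and the SNV contribution to
# solution ranking.

#' Expected allelic fraction of a variant
#'
#' For a variant with multiplicity `M` (number of tumor chromosome copies
#' carrying it) in a segment of copy number `C`, at purity `p`,
#' `E[f] = (p*M + g*(1-p)) / (p*C + 2*(1-p))` with `g = 1` for germline and
#' `g = 0` for somatic. The sub-clonal somatic state uses `M = 1/3`.
#'
#' @param p Purity in (0, 1].
#' @param C Segment copy number (>= 0).
#' @param M Multiplicity, integer in 0..C or 1/3 (sub-clonal, somatic only).
#' @param g Germline indicator (0 or 1).
#' @return Expected allelic fraction in `[0, 1]`.
#' @export
#' @examples
#' expectedAF(1, 2, 1, 1)      # 0.5, pure heterozygous
#' expectedAF(0.65, 2, 1, 0)   # 0.325, clonal somatic at 65% purity
expectedAF <- function(p, C, M, g) {
    stopifnot(all(p > 0), all(p <= 1), all(C >= 0), all(g %in% c(0, 1)))
    den <- p * C + 2 * (1 - p)
    if (any(den == 0)) stop("expected AF undefined: p*C + 2*(1-p) = 0")
    (p * M + g * (1 - p)) / den
}

#' Beta log-likelihood of an observed allelic fraction
#'
#' The sampling variance of an allelic fraction observed in `n` reads is
#' modeled by evaluating a Beta density with shape parameters
#' `n*f + 1` and `n*(1-f) + 1` at the expected fraction. Depth is capped
#' (default 300) so that unmodeled mapping biases at very high coverage do
#' not produce overwhelming likelihoods.
#'
#' @param f Observed allelic fraction.
#' @param n Read depth (capped at `n.cap`).
#' @param expected Expected allelic fraction (the point of evaluation).
#' @param n.cap Depth cap.
#' @return Log density; `-Inf` for impossible states.
#' @export
afLogLik <- function(f, n, expected, n.cap = 300L) {
    stopifnot(all(n >= 1))
    n <- pmin(n, n.cap)
    stats::dbeta(expected, n * f + 1, n * (1 - f) + 1, log = TRUE)
}

#' Expected allelic fractions of the contamination states
#'
#' Cross-individual DNA contamination at rate `rate` produces two extra
#' germline states: a homozygous SNP whose reference reads come from the
#' contaminating DNA, `E[f] = (p*C + 2(1-p-rate)) / (p*C + 2(1-p))`, and a
#' SNP present only in the contamination, `E[f] = rate / (p*C + 2(1-p))`.
#'
#' @param p Purity.
#' @param C Segment copy number.
#' @param rate Contamination rate (default 0.01).
#' @return Named vector with elements `ref` and `alt`.
#' @export
#' @examples
#' contaminationAF(0.6, 2)   # ref 0.99, alt 0.005
contaminationAF <- function(p, C, rate = 0.01) {
    den <- p * C + 2 * (1 - p)
    c(ref = (p * C + 2 * (1 - p - rate)) / den, alt = rate / den)
}

# The multiplicity support of a (C, g) combination: germline variants can sit
# on 0..C copies; somatic variants on 1..C or the sub-clonal 1/3 state, which
# replaces the impossible (M = 0, g = 0).
.mSupport <- function(C, g) {
    if (g == 1) 0:C else c(1/3, seq_len(C))
}

#' Multiplicity prior P(M | K, C, g)
#'
#' "Allowed" multiplicities (M equal to the minor or major chromosome
#' number, or M <= 1 for somatic variants, counting the sub-clonal state)
#' share probability `PK`; the remaining integer states share `1 - PK`.
#' When every support state is allowed the allowed states carry all mass
#' (1/n_s each). `K` above `floor(C/2)` is impossible and returns 0.
#'
#' @param M Multiplicity (integer in 0..C, or 1/3 with `g = 0`).
#' @param K Minor copy number.
#' @param C Segment copy number.
#' @param g Germline indicator.
#' @param PK Prior mass on allowed states (default 0.999).
#' @return Prior probability.
#' @export
multiplicityPrior <- function(M, K, C, g, PK = 0.999) {
    stopifnot(length(M) == 1, K >= 0, C >= 0, g %in% c(0, 1))
    if (K > floor(C / 2)) return(0)
    support <- .mSupport(C, g)
    if (!any(abs(support - M) < 1e-9)) {
        stop("M = ", M, " not in the multiplicity support for C = ", C,
             ", g = ", g)
    }
    allowed <- support == K | support == (C - K) | (support <= 1 & g == 0)
    n.s <- sum(allowed)
    S <- length(support)
    this <- which(abs(support - M) < 1e-9)[1]
    if (n.s == S) return(1 / n.s)
    if (allowed[this]) PK / n.s else (1 - PK) / (S - n.s)
}

#' Prior probability that a variant is somatic
#'
#' With a matched normal the somatic/germline call of the variant caller is
#' trusted almost fully (0.999 / 0.0001). Without one, database evidence is
#' used: 0.95 if seen more than twice in COSMIC, 0.0005 if in dbSNP, 0.01
#' if in both, 0.5 otherwise.
#'
#' @param in.dbsnp Logical vector.
#' @param cosmic.count Integer vector of COSMIC occurrence counts.
#' @param matched.status `"somatic"`, `"germline"` or `"unknown"`.
#' @param matched Use the matched-normal prior table.
#' @param priors Prior configuration (see [defaultConfig()]`$priors`).
#' @return Vector of priors P(g = somatic).
#' @export
somaticPrior <- function(in.dbsnp, cosmic.count,
                         matched.status = "unknown", matched = FALSE,
                         priors = defaultConfig()$priors) {
    n <- length(in.dbsnp)
    matched.status <- rep_len(matched.status, n)
    cosmic.count <- rep_len(cosmic.count, n)
    unmatched <- ifelse(cosmic.count > 2 & in.dbsnp, priors$unmatched.both,
                 ifelse(cosmic.count > 2, priors$unmatched.cosmic,
                 ifelse(in.dbsnp, priors$unmatched.dbsnp,
                        priors$unmatched.neither)))
    if (!matched) return(unmatched)
    ifelse(matched.status == "somatic", priors$matched.somatic,
    ifelse(matched.status == "germline", priors$matched.germline, unmatched))
}

# Full (C, K, M, g) state table with multiplicity and K priors; static given
# max.copy and PK.
.snvStates <- function(max.copy = 7L, PK = 0.999) {
    rows <- list()
    for (C in 0:max.copy) {
        for (K in 0:floor(C / 2)) {
            for (g in c(1, 0)) {   # germline first: ties resolve to germline
                for (M in .mSupport(C, g)) {
                    rows[[length(rows) + 1L]] <- data.frame(
                        C = C, K = K, M = M, g = g,
                        prior.M = multiplicityPrior(M, K, C, g, PK),
                        prior.K = 1 / (C + 1))
                }
            }
        }
    }
    do.call(rbind, rows)
}

# aggregated (g, M, C) state labels, germline first
.stateLabel <- function(g, M, C) {
    m.lab <- ifelse(abs(M - 1 / 3) < 1e-9, "1/3",
                    vapply(M, function(m) format(m, trim = TRUE),
                           character(1)))
    sprintf("%s_M%s_C%d", ifelse(g == 1, "GERMLINE", "SOMATIC"), m.lab, C)
}

#' Filter variants before SNV fitting
#'
#' Removes (a) homozygous germline variants -- allelic fraction above 0.9 in
#' the matched normal, or above 0.95 in the tumor when unmatched -- unless
#' `high.purity` mode is on (a homozygous state is modeled instead), and
#' (b) variants whose matched-normal allelic fraction is significantly
#' different from 0.5 under the Beta model (two-sided tail probability
#' below `bias.p`), i.e. likely mapping artifacts. A pool-of-normals version
#' removes variants biased in at least half of at least
#' `pool.min.normals` informative normals.
#'
#' @param variants Variant table.
#' @param high.purity Logical; skip homozygous removal.
#' @param pool.af Optional list with matrices `af` and `n`
#'   (variants x normals) of allelic fractions observed in a pool of
#'   normals; `NA` marks uninformative entries.
#' @param hom.cutoff.normal,hom.cutoff.tumor,bias.p,pool.min.normals,pool.biased.frac
#'   Thresholds (see [defaultConfig()]`$filter`).
#' @return List with `variants` (retained) and `removed` (with a `reason`
#'   column).
#' @export
filterVariants <- function(variants, high.purity = FALSE, pool.af = NULL,
                           hom.cutoff.normal = 0.9, hom.cutoff.tumor = 0.95,
                           bias.p = 0.05, pool.min.normals = 5L,
                           pool.biased.frac = 0.5) {
    n <- nrow(variants)
    reason <- rep(NA_character_, n)
    has.normal <- !is.na(variants$normal.f)
    if (!high.purity) {
        hom <- ifelse(has.normal,
                      variants$normal.f > hom.cutoff.normal,
                      variants$f > hom.cutoff.tumor)
        reason[hom & is.na(reason)] <- "removed_homozygous"
    }
    bias.idx <- which(has.normal & is.na(reason) &
                      variants$normal.f >= 0.05 &
                      variants$normal.f <= hom.cutoff.normal)
    if (length(bias.idx)) {
        nf <- variants$normal.f[bias.idx]
        nn <- pmax(variants$normal.n[bias.idx], 1)
        pr <- stats::pbeta(nf, nn / 2 + 1, nn / 2 + 1)
        tail.p <- 2 * pmin(pr, 1 - pr)
        reason[bias.idx[tail.p < bias.p]] <- "removed_mapping_bias"
    }
    if (!is.null(pool.af)) {
        af <- pool.af$af
        nn <- pool.af$n
        stopifnot(nrow(af) == n)
        for (i in which(is.na(reason))) {
            inf.idx <- which(!is.na(af[i, ]))
            if (length(inf.idx) < pool.min.normals) next
            pr <- stats::pbeta(af[i, inf.idx],
                               nn[i, inf.idx] / 2 + 1, nn[i, inf.idx] / 2 + 1)
            biased <- 2 * pmin(pr, 1 - pr) < bias.p
            if (mean(biased) >= pool.biased.frac) {
                reason[i] <- "removed_mapping_bias_pool"
            }
        }
    }
    keep <- is.na(reason)
    removed <- variants[!keep, , drop = FALSE]
    if (nrow(removed)) removed$reason <- reason[!keep]
    list(variants = variants[keep, , drop = FALSE], removed = removed)
}

#' Fit SNVs to a purity/ploidy solution
#'
#' Enumerates all (C, K, M, g) states per variant -- plus contamination
#' states for dbSNP variants and, in high-purity mode, a germline-homozygous
#' state -- weighting each by the segment's copy-number posterior, the flat
#' K prior, the multiplicity prior, and the somatic-status prior, with the
#' Beta likelihood of the observed allelic fraction. Posteriors are
#' normalized per variant; the maximum-likelihood state determines the
#' somatic call, multiplicity and (for somatic calls) the cellular fraction
#' `h = (f/M) * (p*C + 2*(1-p)) / p`.
#'
#' @param variants Filtered variant table.
#' @param segments Segment table of the solution.
#' @param solution A `tumorcn_solution`.
#' @param matched Use matched-normal somatic priors.
#' @param priors Prior configuration.
#' @param high.purity Add the germline-homozygous state.
#' @param contamination Add the two contamination states for dbSNP variants.
#' @param flank Variants within this many bp of a segment inherit it.
#' @return Object of class `tumorcn_variant_fit`: list with `calls` (one row
#'   per fitted variant), `posterior` (variants x states), `states`,
#'   `snv.loglik`, and `skipped`.
#' @export
fitVariants <- function(variants, segments, solution, matched = FALSE,
                        priors = defaultConfig()$priors,
                        high.purity = FALSE, contamination = TRUE,
                        flank = 50L) {
    p <- solution$purity
    seg.of <- .variantSegment(variants, segments, flank)
    skipped <- variants[is.na(seg.of), , drop = FALSE]
    keep <- which(!is.na(seg.of))
    v <- variants[keep, , drop = FALSE]
    seg.of <- seg.of[keep]
    nv <- nrow(v)
    if (nv == 0) {
        return(structure(list(
            calls = v, posterior = NULL, states = NULL,
            snv.loglik = 0, skipped = skipped,
            flags = "no variants"), class = "tumorcn_variant_fit"))
    }
    max.copy <- ncol(solution$posterior) - 2L
    states <- .snvStates(max.copy, priors$PK)
    ef <- expectedAF(p, states$C, states$M, states$g)
    # segment copy-number posterior over integer states, per variant
    pC <- solution$posterior[seg.of, seq_len(max.copy + 1L), drop = FALSE]
    pC <- pC / pmax(rowSums(pC), .Machine$double.xmin)
    prior.somatic <- somaticPrior(v$in.dbsnp, v$cosmic.count,
                                  v$matched.status, matched, priors)
    n.capped <- pmin(v$n, priors$n.cap)
    sh1 <- n.capped * v$f + 1
    sh2 <- n.capped * (1 - v$f) + 1
    B <- nrow(states)
    loglik <- matrix(stats::dbeta(rep(ef, each = nv),
                                  rep(sh1, B), rep(sh2, B), log = TRUE),
                     nrow = nv)
    logw <- log(pC[, states$C + 1L, drop = FALSE]) +
        rep(log(states$prior.K * states$prior.M), each = nv)
    logw <- matrix(logw, nrow = nv)
    lp.som <- log(prior.somatic)
    lp.germ <- log1p(-prior.somatic)
    logw <- logw + outer(rep(1, nv), as.numeric(states$g == 0)) * lp.som +
        outer(rep(1, nv), as.numeric(states$g == 1)) * lp.germ
    joint <- logw + loglik
    # aggregate over K to the reported (g, M, C) states
    lab <- .stateLabel(states$g, states$M, states$C)
    ulab <- unique(lab)
    agg <- vapply(ulab, function(u) {
        cols <- which(lab == u)
        if (length(cols) == 1) joint[, cols] else
            apply(joint[, cols, drop = FALSE], 1, .logSumExp)
    }, numeric(nv))
    agg <- matrix(agg, nrow = nv, dimnames = list(NULL, ulab))
    smap <- states[match(ulab, lab), c("C", "M", "g")]
    # special states
    extra <- NULL
    if (contamination) {
        cc <- 0:max.copy
        caf <- vapply(cc, contaminationAF, numeric(2), p = p,
                      rate = priors$contamination.rate)
        ef7 <- caf["ref", ]
        ef8 <- caf["alt", ]
        db7 <- matrix(stats::dbeta(rep(ef7, each = nv), rep(sh1, max.copy + 1L),
                                   rep(sh2, max.copy + 1L)), nrow = nv)
        db8 <- matrix(stats::dbeta(rep(ef8, each = nv), rep(sh1, max.copy + 1L),
                                   rep(sh2, max.copy + 1L)), nrow = nv)
        lik7 <- rowSums(pC * db7)
        lik8 <- rowSums(pC * db8)
        lp.cont <- ifelse(v$in.dbsnp, log(priors$contamination.prior), -Inf)
        extra <- cbind(CONTAMINATION_REF = lp.cont + log(lik7),
                       CONTAMINATION_ALT = lp.cont + log(lik8))
    }
    if (high.purity) {
        k.ref <- round(n.capped * (1 - v$f))
        hom.ll <- stats::dbinom(k.ref, n.capped, priors$error.rate, log = TRUE)
        extra <- cbind(extra,
                       GERMLINE_HOMOZYGOUS = log(priors$hom.prior) + hom.ll)
    }
    full <- cbind(agg, extra)
    post <- t(apply(full, 1, function(x) {
        m <- max(x)
        if (!is.finite(m)) return(rep(0, length(x)))
        e <- exp(x - m)
        e / sum(e)
    }))
    colnames(post) <- colnames(full)
    n.reg <- ncol(agg)
    somatic.cols <- which(smap$g == 0)
    posterior.somatic <- rowSums(post[, somatic.cols, drop = FALSE])
    ml.idx <- max.col(post, ties.method = "first")
    is.special <- ml.idx > n.reg
    ml.C <- ifelse(is.special, NA_integer_, smap$C[pmin(ml.idx, n.reg)])
    ml.M <- ifelse(is.special, NA_real_, smap$M[pmin(ml.idx, n.reg)])
    ml.g <- ifelse(is.special, NA_real_, smap$g[pmin(ml.idx, n.reg)])
    ml.state <- colnames(full)[ml.idx]
    ml.somatic <- !is.special & ml.g == 0
    # expected AF of the ML state (GoF); contamination states use the modal C
    c.mode <- max.col(pC, ties.method = "first") - 1L
    exp.af <- numeric(nv)
    reg <- which(!is.special)
    if (length(reg)) {
        exp.af[reg] <- expectedAF(p, ml.C[reg], ml.M[reg], ml.g[reg])
    }
    for (i in which(is.special)) {
        caf <- contaminationAF(p, c.mode[i], priors$contamination.rate)
        exp.af[i] <- switch(ml.state[i],
            CONTAMINATION_REF = caf[["ref"]],
            CONTAMINATION_ALT = caf[["alt"]],
            GERMLINE_HOMOZYGOUS = 1)
    }
    h.raw <- rep(NA_real_, nv)
    som <- which(ml.somatic)
    if (length(som)) {
        h.raw[som] <- (v$f[som] / ml.M[som]) *
            (p * ml.C[som] + 2 * (1 - p)) / p
    }
    ml.loglik <- full[cbind(seq_len(nv), ml.idx)]
    calls <- data.frame(
        v[, c("chrom", "pos", "ref", "alt", "f", "n", "in.dbsnp",
              "cosmic.count")],
        segment = seg.of,
        prior.somatic = prior.somatic,
        posterior.somatic = posterior.somatic,
        ml.state = ml.state,
        ml.somatic = ml.somatic,
        ml.C = ml.C, ml.M = ml.M,
        expected.af = exp.af,
        h.raw = h.raw,
        cellfraction = ifelse(ml.somatic, pmin(h.raw, 1), NA_real_),
        loglik.ml = ml.loglik,
        flag = ifelse(!is.na(h.raw) & h.raw > 1, "h>1;check fit", ""),
        stringsAsFactors = FALSE
    )
    structure(list(
        calls = calls,
        posterior = post,
        states = smap,
        snv.loglik = sum(ml.loglik),
        skipped = skipped,
        flags = character(0)
    ), class = "tumorcn_variant_fit")
}

# map each variant to the segment containing it (50 bp flank tolerance)
.variantSegment <- function(variants, segments, flank = 50L) {
    out <- rep(NA_integer_, nrow(variants))
    for (i in seq_len(nrow(segments))) {
        hit <- variants$chrom == segments$chrom[i] &
            variants$pos - 1L >= segments$start[i] &
            variants$pos - 1L < segments$end[i]
        out[hit & is.na(out)] <- i
    }
    miss <- which(is.na(out))
    if (length(miss) && flank > 0) {
        for (i in seq_len(nrow(segments))) {
            hit <- variants$chrom[miss] == segments$chrom[i] &
                variants$pos[miss] - 1L >= segments$start[i] - flank &
                variants$pos[miss] - 1L < segments$end[i] + flank
            out[miss[hit & is.na(out[miss])]] <- i
        }
    }
    out
}

#' SNV log-likelihood of a fitted solution
#'
#' The sum over variants of the log-likelihood of each variant's most
#' likely state. Zero when no variants were fitted.
#'
#' @param variant.fit Result of [fitVariants()].
#' @return Scalar log-likelihood.
#' @export
snvLogLik <- function(variant.fit) {
    if (is.null(variant.fit$calls) || nrow(variant.fit$calls) == 0) return(0)
    sum(variant.fit$calls$loglik.ml)
}

#' Post-optimize purity over copy number and allelic fractions jointly
#'
#' Re-evaluates the total (copy-number plus SNV) log-likelihood over the
#' purity grid, replaces the solution's purity by the argmax, and refreshes
#' the copy assignments and variant posteriors once. Off by default in the
#' pipeline; recommended when variant classification is the goal.
#'
#' @param solution A `tumorcn_solution`.
#' @param segments Segment table used to fit the solution.
#' @param variants Filtered variant table.
#' @param matched,priors,high.purity,contamination Passed to [fitVariants()].
#' @param purity.grid Purity values searched.
#' @return List with the updated `solution` and `variant.fit`.
#' @export
postOptimize <- function(solution, segments, variants, matched = FALSE,
                         priors = defaultConfig()$priors,
                         high.purity = FALSE, contamination = TRUE,
                         purity.grid = seq(0.15, 0.95, by = 0.01)) {
    eval.p <- function(p) {
        sol.p <- .refitAtPurity(solution, segments, p)
        fit <- fitVariants(variants, segments, sol.p, matched, priors,
                           high.purity, contamination)
        list(total = sol.p$cn.loglik + fit$snv.loglik, sol = sol.p, fit = fit)
    }
    evals <- lapply(purity.grid, eval.p)
    totals <- vapply(evals, `[[`, numeric(1), "total")
    best <- evals[[which.max(totals)]]
    sol <- best$sol
    sol$snv.loglik <- best$fit$snv.loglik
    sol$total.loglik <- sol$cn.loglik + sol$snv.loglik
    list(solution = sol, variant.fit = best$fit)
}

# deterministic re-fit of assignments/ploidy at a fixed purity (shift kept)
.refitAtPurity <- function(solution, segments, p) {
    r <- segments$seg.mean
    sdv <- segments$sd
    nt <- segments$num.targets
    l <- segments$size
    s <- solution$shift
    max.copy <- ncol(solution$posterior) - 2L
    D <- solution$ploidy
    for (i in 1:10) {
        ml <- max.col(.statesLogLik(r, sdv, nt, p, D, s, max.copy),
                      ties.method = "first")
        D.new <- .ploidyFromAssign(ml, r + s, l, p, D, max.copy)
        if (abs(D.new - D) < 1e-12) { D <- D.new; break }
        D <- D.new
    }
    ll <- .statesLogLik(r, sdv, nt, p, D, s, max.copy)
    ml <- max.col(ll, ties.method = "first")
    posterior <- t(apply(ll, 1, function(x) { e <- exp(x - max(x)); e / sum(e) }))
    colnames(posterior) <- colnames(solution$posterior)
    sol <- solution
    sol$purity <- p
    sol$ploidy <- D
    sol$assign <- ml
    sol$subclonal <- ml == max.copy + 2L
    sol$C <- ifelse(sol$subclonal, NA_integer_, ml - 1L)
    sol$posterior <- posterior
    sol$cn.loglik <- .assignLL(r, sdv, nt, ml, p, D, s, max.copy)
    sol
}

#' Call minor copy number and LOH per segment
#'
#' Estimates each segment's minor copy number `K` from the mirrored allelic
#' fractions of its (predicted) germline heterozygous SNPs, by maximizing
#' the Beta likelihood over `K <= floor(C/2)` with each SNP phased to either
#' parental chromosome with probability one half. A segment is in LOH if
#' `C = 1` or `K = 0`.
#'
#' @param segments Segment table.
#' @param solution Fitted solution providing `C` and purity.
#' @param variant.fit Result of [fitVariants()]; germline dbSNP calls are
#'   used. May be `NULL` (K then unknown except where forced by `C`).
#' @param n.cap Depth cap for the Beta likelihood.
#' @return `segments` with columns `C`, `K`, `loh` added.
#' @export
callLOH <- function(segments, solution, variant.fit = NULL, n.cap = 300L) {
    p <- solution$purity
    segments$C <- solution$C
    segments$K <- NA_integer_
    segments$loh <- NA
    germ <- NULL
    if (!is.null(variant.fit) && !is.null(variant.fit$calls) &&
        nrow(variant.fit$calls)) {
        calls <- variant.fit$calls
        germ <- calls[!calls$ml.somatic & calls$in.dbsnp &
                      calls$f >= 0.05 & calls$f <= 0.95, , drop = FALSE]
    }
    for (i in seq_len(nrow(segments))) {
        C <- segments$C[i]
        if (is.na(C)) next
        if (C <= 1) {
            segments$K[i] <- 0L
            segments$loh[i] <- TRUE
            next
        }
        if (is.null(germ)) next
        snp <- germ[germ$segment == i, , drop = FALSE]
        if (nrow(snp) == 0) next
        ks <- 0:floor(C / 2)
        score <- vapply(ks, function(K) {
            e1 <- expectedAF(p, C, K, 1)
            e2 <- expectedAF(p, C, C - K, 1)
            sum(log(0.5 * exp(afLogLik(snp$f, snp$n, e1, n.cap)) +
                    0.5 * exp(afLogLik(snp$f, snp$n, e2, n.cap)) +
                    .Machine$double.xmin))
        }, numeric(1))
        segments$K[i] <- ks[which.max(score)]
        segments$loh[i] <- segments$K[i] == 0L
    }
    segments$loh[!is.na(segments$C) & segments$C == 1] <- TRUE
    segments
}
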