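# Solution ranking, goodness-of-fit, bootstrap re-ranking, and sample flags.

#' Goodness of fit of the SNV model
#'
#' The mean absolute deviation `d` between observed allelic fractions and
#' the expectation of each variant's most likely state, mapped to a 0-100%
#' score anchored so that `d = 0.2` (the worst plausible fit) gives 0% and
#' `d = 0` gives 100%.
#'
#' @param variant.fit Result of [fitVariants()].
#' @return Percentage in `[0, 100]`, or `NA` when no variants were fitted.
#' @export
goodnessOfFit <- function(variant.fit) {
    calls <- variant.fit$calls
    if (is.null(calls) || nrow(calls) == 0) return(NA_real_)
    d <- mean(abs(calls$f - calls$expected.af))
    100 * max(0, 1 - d / 0.2)
}

#' Bootstrap re-ranking of purity/ploidy solutions
#'
#' Resamples variants with replacement; per replicate each solution's SNV
#' log-likelihood is recomputed on the resample and solutions are re-ranked
#' by total log-likelihood. The bootstrap value of a solution is the
#' fraction of replicates in which it ranked first. Solutions that never
#' reach the top `top` in any replicate are removed; when the best
#' solution's bootstrap value falls below `ambiguous`, the "ambiguous
#' solutions" flag is raised.
#'
#' @param solutions List of `tumorcn_solution`, each with a
#'   `variant.loglik` vector (per-variant ML-state log-likelihoods).
#' @param replicates Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param top Rank counted as "high".
#' @param min.variants Minimum variants required to bootstrap.
#' @param ambiguous Flag threshold on the top solution's bootstrap value.
#' @return List with `solutions` (pruned, bootstrap values filled) and
#'   `flags`.
#' @export
bootstrapRank <- function(solutions, replicates = 500L, seed = NULL,
                          top = 2L, min.variants = 20L, ambiguous = 0.95) {
    flags <- character(0)
    if (length(solutions) < 2) {
        if (length(solutions) == 1) solutions[[1]]$bootstrap.value <- 1
        return(list(solutions = solutions, flags = flags))
    }
    vl <- lapply(solutions, `[[`, "variant.loglik")
    nv <- unique(lengths(vl))
    if (length(nv) != 1 || nv < min.variants) {
        return(list(solutions = solutions,
                    flags = "too few variants for bootstrap"))
    }
    cn <- vapply(solutions, `[[`, numeric(1), "cn.loglik")
    ns <- length(solutions)
    first <- integer(ns)
    ever.top <- logical(ns)
    .withSeed(seed, {
        for (b in seq_len(replicates)) {
            idx <- sample.int(nv, nv, replace = TRUE)
            tot <- cn + vapply(vl, function(x) sum(x[idx]), numeric(1))
            ord <- order(-tot)
            first[ord[1]] <- first[ord[1]] + 1L
            ever.top[ord[seq_len(min(top, ns))]] <- TRUE
        }
    })
    bv <- first / replicates
    for (i in seq_len(ns)) solutions[[i]]$bootstrap.value <- bv[i]
    keep <- which(ever.top)
    solutions <- solutions[keep]
    if (solutions[[which.max(bv[keep])]]$bootstrap.value < ambiguous) {
        flags <- "ambiguous solutions"
    }
    list(solutions = solutions, flags = flags)
}

#' Flag a sample for manual curation
#'
#' Evaluates the maximum-likelihood solution against characteristics rarely
#' seen in correct fits: noisy segmentation, rare ploidy, excessive LOH or
#' homozygous losses, a non-aberrant or poly-genomic profile, evidence of
#' DNA contamination, and a low goodness-of-fit. All thresholds are
#' configuration defaults (see [defaultConfig()]`$curation`).
#'
#' @param solution Ranked `tumorcn_solution`.
#' @param segments Segment table with `C`, `K`, `loh` columns.
#' @param variant.fit Result of [fitVariants()], or `NULL`.
#' @param gof Goodness of fit (percent), or `NA`.
#' @param thresholds Curation thresholds.
#' @return Character vector of flags (possibly empty).
#' @export
flagSample <- function(solution, segments, variant.fit = NULL,
                       gof = NA_real_,
                       thresholds = defaultConfig()$curation) {
    flags <- character(0)
    th <- thresholds
    if (mean(segments$sd) > th$noisy.sd) {
        flags <- c(flags, "NOISY_SEGMENTATION")
    }
    if (solution$ploidy < th$rare.ploidy.low ||
        solution$ploidy > th$rare.ploidy.high) {
        flags <- c(flags, "RARE_PLOIDY")
    }
    tot.len <- sum(as.numeric(segments$size))
    if (!is.null(segments$loh)) {
        loh.len <- sum(as.numeric(segments$size[!is.na(segments$loh) &
                                                segments$loh]))
        if (loh.len / tot.len > th$excessive.loh.frac) {
            flags <- c(flags, "EXCESSIVE_LOH")
        }
    }
    if (!is.null(segments$C)) {
        hom.len <- sum(as.numeric(segments$size[!is.na(segments$C) &
                                                segments$C == 0]))
        if (hom.len / tot.len > th$hom.loss.frac) {
            flags <- c(flags, "EXCESSIVE_HOMOZYGOUS_LOSS")
        }
        normal21 <- !is.na(segments$C) & segments$C == 2 &
            (is.na(segments$K) | segments$K == 1)
        aberrant.len <- sum(as.numeric(segments$size[!normal21]))
        if (aberrant.len / tot.len < th$non.aberrant.frac) {
            flags <- c(flags, "NON_ABERRANT")
        }
    }
    sub.len <- sum(as.numeric(segments$size[solution$subclonal]))
    if (sub.len / tot.len > th$polygenomic.frac) {
        flags <- c(flags, "POLYGENOMIC")
    }
    if (!is.null(variant.fit) && !is.null(variant.fit$calls) &&
        nrow(variant.fit$calls)) {
        calls <- variant.fit$calls
        db <- calls[calls$in.dbsnp, , drop = FALSE]
        if (nrow(db)) {
            contam <- mean(grepl("^CONTAMINATION", db$ml.state))
            if (contam >= th$contamination.frac) {
                flags <- c(flags, "CONTAMINATION")
            }
        }
    }
    if (!is.na(gof) && gof < th$low.gof) {
        flags <- c(flags, "LOW_GOF")
    }
    flags
}

#' Rank solutions by total log-likelihood
#'
#' Discarded solutions are excluded from ranking. When the low-purity
#' haploid adjustment is on, a solution with purity below `low.purity` and
#' ploidy below 1.5 has its SNV log-likelihood capped at the best SNV
#' log-likelihood among near-diploid solutions (ploidy 1.5-2.5), giving
#' haploid and diploid explanations the same effective prior at low purity.
#'
#' @param solutions List of `tumorcn_solution`.
#' @param haploid.adjust Apply the low-purity haploid/diploid equalization.
#' @param low.purity Purity threshold for the adjustment.
#' @return List of solutions sorted by (adjusted) total log-likelihood,
#'   with `rank` filled; discarded solutions follow, unranked.
#' @export
rankSolutions <- function(solutions, haploid.adjust = TRUE,
                          low.purity = 0.35) {
    discarded <- vapply(solutions, function(s) isTRUE(s$discarded),
                        logical(1))
    act <- solutions[!discarded]
    if (!length(act)) return(solutions)
    total <- vapply(act, function(s) {
        if (is.na(s$snv.loglik)) s$cn.loglik else s$cn.loglik + s$snv.loglik
    }, numeric(1))
    if (haploid.adjust) {
        ploidy <- vapply(act, `[[`, numeric(1), "ploidy")
        purity <- vapply(act, `[[`, numeric(1), "purity")
        snv <- vapply(act, `[[`, numeric(1), "snv.loglik")
        dip <- which(ploidy >= 1.5 & ploidy <= 2.5 & !is.na(snv))
        hap <- which(ploidy < 1.5 & purity < low.purity & !is.na(snv))
        if (length(dip) && length(hap)) {
            cap <- max(snv[dip])
            for (i in hap) {
                total[i] <- act[[i]]$cn.loglik + min(snv[i], cap)
            }
        }
    }
    # ties (which arise from the haploid/diploid equalization) resolve
    # toward the solution with ploidy nearest diploid
    ploidy.all <- vapply(act, `[[`, numeric(1), "ploidy")
    ord <- order(-total, abs(ploidy.all - 2))
    act <- act[ord]
    for (i in seq_along(act)) {
        act[[i]]$rank <- i
        act[[i]]$total.loglik <- if (is.na(act[[i]]$snv.loglik))
            act[[i]]$cn.loglik else act[[i]]$cn.loglik + act[[i]]$snv.loglik
    }
    c(act, solutions[discarded])
}
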