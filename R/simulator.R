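# Synthetic tumor samples with known truth, emulating benchmarking designs
# for targeted sequencing: piecewise-constant integer copy-number genomes,
# coverage scaled by copy number and purity, and allelic fractions sampled
# from the expected-fraction model with SNPs randomly phased to a parental
# chromosome.

#' Simulate a piecewise-constant copy-number genome
#'
#' Draws segment lengths (in targets) from a log-normal distribution with a
#' minimum of `min.targets`, assigns integer copy numbers per segment from a
#' distribution steered (by rejection) so the length-weighted mean ploidy is
#' within `ploidy.tol` of `target.ploidy`, and draws each segment's minor
#' copy number uniformly in `0..floor(C/2)`.
#'
#' @param n.segments Number of segments.
#' @param n.targets Total number of targets.
#' @param purity True tumor purity (stored as truth).
#' @param target.ploidy Desired length-weighted mean copy number, in 1-6.
#' @param seed Integer seed; fixed seeds give identical truth.
#' @param n.chrom Number of chromosomes the segments are distributed over.
#' @param target.width,target.spacing Target geometry in bp.
#' @param min.targets Minimum targets per segment.
#' @param ploidy.tol Rejection tolerance around `target.ploidy`.
#' @param max.tries Rejection cap before erroring.
#' @param force.C Optional fixed copy number for every segment (e.g. 2 for
#'   a flat diploid genome).
#' @param max.copy Highest copy number simulated.
#' @return Object of class `tumorcn_truth`: list with `intervals`,
#'   `segments` (with true `C`, `K`), `purity`, `ploidy`, `seed`, `design`.
#' @export
simulateGenome <- function(n.segments = 40L, n.targets = 2000L,
                           purity = 0.6, target.ploidy = 2.0, seed = NULL,
                           n.chrom = 20L, target.width = 200L,
                           target.spacing = 3000L, min.targets = 5L,
                           ploidy.tol = 0.15, max.tries = 2000L,
                           force.C = NULL, max.copy = 7L) {
    stopifnot(target.ploidy >= 0.5, target.ploidy <= 7)
    .withSeed(seed, {
        raw <- stats::rlnorm(n.segments, log(n.targets / n.segments), 0.7)
        len <- pmax(min.targets, round(raw / sum(raw) * n.targets))
        # adjust the largest segments so lengths sum exactly to n.targets
        while (sum(len) != n.targets) {
            i <- if (sum(len) > n.targets) which.max(len) else which.min(len)
            len[i] <- max(min.targets, len[i] + sign(n.targets - sum(len)))
        }
        n.chrom <- min(n.chrom, n.segments)
        chrom.of <- sort(rep_len(seq_len(n.chrom), n.segments))
        l.bp <- len * target.spacing
        if (is.null(force.C)) {
            ok <- FALSE
            for (i in seq_len(max.tries)) {
                C <- pmin(max.copy, pmax(0, round(
                    stats::rnorm(n.segments, target.ploidy, 1.2))))
                wm <- sum(l.bp * C) / sum(l.bp)
                if (abs(wm - target.ploidy) <= ploidy.tol) { ok <- TRUE; break }
            }
            if (!ok) stop("could not reach target ploidy ", target.ploidy,
                          " within ", max.tries, " tries")
        } else {
            C <- rep_len(force.C, n.segments)
        }
        K <- vapply(C, function(cc) {
            if (cc == 0) 0L else sample.int(floor(cc / 2) + 1L, 1L) - 1L
        }, integer(1))
        # build the target grid chromosome by chromosome
        iv <- NULL
        segs <- NULL
        first <- 1L
        for (s in seq_len(n.segments)) {
            ch <- paste0("chr", chrom.of[s])
            prev.on.chrom <- if (s > 1 && chrom.of[s] == chrom.of[s - 1]) {
                segs$end[s - 1]
            } else 0L
            starts <- prev.on.chrom + (seq_len(len[s]) - 1L) * target.spacing
            iv <- rbind(iv, data.frame(
                chrom = ch, start = starts, end = starts + target.width,
                gc.fraction = stats::runif(len[s], 0.3, 0.75),
                on.target = TRUE, stringsAsFactors = FALSE))
            segs <- rbind(segs, data.frame(
                chrom = ch, start = starts[1],
                end = starts[len[s]] + target.spacing,
                first.target = first, last.target = first + len[s] - 1L,
                num.targets = len[s], size = len[s] * target.spacing,
                C = C[s], K = K[s], stringsAsFactors = FALSE))
            first <- first + len[s]
        }
        ploidy <- sum(as.numeric(segs$size) * segs$C) / sum(as.numeric(segs$size))
        structure(list(
            intervals = iv, segments = segs,
            purity = purity, ploidy = ploidy, seed = seed,
            design = list(n.segments = n.segments, n.targets = n.targets,
                          target.ploidy = target.ploidy,
                          target.width = target.width,
                          target.spacing = target.spacing)
        ), class = "tumorcn_truth")
    })
}

# copy number of the segment containing each target
.targetCopy <- function(truth) {
    rep(truth$segments$C, truth$segments$num.targets)
}

#' Simulate tumor and reference coverage for a truth genome
#'
#' The reference sample gets per-target capture efficiencies (log-normal,
#' coefficient of variation `noise.cv`) shared with the tumor -- emulating a
#' process-matched normal -- plus sample-specific GC bias slopes which the
#' GC normalization step is expected to remove. Tumor coverage is the
#' reference expectation scaled by `(p*C + 2(1-p))/2` for the target's true
#' copy number. Both samples receive multiplicative sampling noise whose
#' coefficient of variation shrinks with expected depth (Poisson-like).
#'
#' @param truth A `tumorcn_truth`.
#' @param depth Mean target coverage of the design.
#' @param noise.cv Coefficient of variation of capture efficiency across
#'   targets.
#' @param seed Integer seed.
#' @param gc.bias.sd Standard deviation of the per-sample linear GC bias
#'   slope (0 disables GC bias).
#' @return List with `tumor` and `reference` coverage vectors.
#' @export
simulateCoverage <- function(truth, depth = 100, noise.cv = 0.2,
                             seed = NULL, gc.bias.sd = 0.2) {
    stopifnot(depth > 0)
    .withSeed(seed, {
        iv <- truth$intervals
        nt <- nrow(iv)
        p <- truth$purity
        sdl <- sqrt(log(1 + noise.cv^2))
        phi <- stats::rlnorm(nt, -sdl^2 / 2, sdl)
        slope.n <- stats::rnorm(1, 0, gc.bias.sd)
        slope.t <- stats::rnorm(1, 0, gc.bias.sd)
        gc.dev <- iv$gc.fraction - 0.5
        bias.n <- pmax(1 + slope.n * gc.dev, 0.1)
        bias.t <- pmax(1 + slope.t * gc.dev, 0.1)
        ratio <- (p * .targetCopy(truth) + 2 * (1 - p)) / 2
        mean.ref <- depth * phi * bias.n
        mean.tum <- depth * phi * bias.t * ratio
        samp <- function(mu) {
            # counting noise shrinking with depth; scaled so the default
            # noise.cv of 0.2 matches Poisson (CV = 1/sqrt(depth)) and
            # noise.cv = 0 gives the exact noiseless limit
            cv <- (noise.cv / 0.2) / sqrt(pmax(mu, 1))
            if (all(cv == 0)) return(mu)
            s <- sqrt(log(1 + cv^2))
            mu * stats::rlnorm(length(mu), -s^2 / 2, s)
        }
        list(tumor = samp(mean.tum), reference = samp(mean.ref))
    })
}

#' Simulate germline SNPs and somatic variants for a truth genome
#'
#' Germline SNPs are placed uniformly on targets and phased to a random
#' parental chromosome, so their multiplicity is the segment's minor or
#' major copy number; somatic variants are clonal with multiplicity 1,
#' except for a configurable sub-clonal share carried by a third of the
#' tumor cells. Depths are Poisson around the design depth and alt counts
#' binomial around the expected allelic fraction; variants with zero alt
#' reads are not emitted (a caller would not report them). dbSNP membership
#' is simulated with small error rates, and a share of somatic variants
#' gets COSMIC hotspot counts.
#'
#' @param truth A `tumorcn_truth`.
#' @param depth Mean variant depth.
#' @param n.germline,n.somatic Variant counts.
#' @param subclonal.fraction Share of somatic variants that are sub-clonal.
#' @param seed Integer seed.
#' @param dbsnp.fn Fraction of germline SNPs missing from dbSNP.
#' @param somatic.dbsnp Fraction of somatic variants overlapping dbSNP.
#' @param cosmic.rate Fraction of somatic variants with a COSMIC count > 2.
#' @param matched Also simulate matched-normal allelic fractions/depths.
#' @return Variant table with the standard columns plus truth columns
#'   `g.true` ("germline"/"somatic"), `M.true`, `subclonal.true`.
#' @export
simulateVariants <- function(truth, depth = 100, n.germline = NULL,
                             n.somatic = 100L, subclonal.fraction = 0.1,
                             seed = NULL, dbsnp.fn = 0.01,
                             somatic.dbsnp = 0.001, cosmic.rate = 0.02,
                             matched = FALSE) {
    iv <- truth$intervals
    if (is.null(n.germline)) n.germline <- round(nrow(iv) / 10)
    .withSeed(seed, {
        p <- truth$purity
        seg.of.target <- rep(seq_len(nrow(truth$segments)),
                             truth$segments$num.targets)
        mk <- function(n.var, germline) {
            if (n.var <= 0) return(NULL)
            if (germline) {
                t.idx <- sample.int(nrow(iv), min(n.var, nrow(iv)))
            } else {
                eligible <- which(truth$segments$C[seg.of.target] >= 1)
                t.idx <- sample(eligible, n.var, replace = TRUE)
            }
            seg <- seg.of.target[t.idx]
            C <- truth$segments$C[seg]
            K <- truth$segments$K[seg]
            pos <- iv$start[t.idx] +
                sample.int(iv$end[t.idx][1] - iv$start[t.idx][1],
                           length(t.idx), replace = TRUE)
            if (germline) {
                maternal <- stats::runif(length(t.idx)) < 0.5
                M <- ifelse(maternal, K, C - K)
                ef <- expectedAF(p, C, M, 1)
                sub <- rep(FALSE, length(t.idx))
            } else {
                sub <- stats::runif(length(t.idx)) < subclonal.fraction
                M <- rep(1, length(t.idx))
                ef <- ifelse(sub,
                             (p * (1 / 3)) / (p * C + 2 * (1 - p)),
                             expectedAF(p, C, M, 0))
            }
            n <- pmax(stats::rpois(length(t.idx), depth), 2L)
            alt <- stats::rbinom(length(t.idx), n, ef)
            db <- if (germline) stats::runif(length(t.idx)) > dbsnp.fn
                  else stats::runif(length(t.idx)) < somatic.dbsnp
            cosmic <- rep(0L, length(t.idx))
            if (!germline) {
                hot <- stats::runif(length(t.idx)) < cosmic.rate
                cosmic[hot] <- 3L + stats::rpois(sum(hot), 5)
            }
            out <- data.frame(
                chrom = iv$chrom[t.idx], pos = pos + 1L,
                ref = "A", alt = "T",
                f = alt / n, n = n,
                in.dbsnp = db, cosmic.count = cosmic,
                matched.status = "unknown",
                normal.f = NA_real_, normal.n = NA_real_,
                g.true = if (germline) "germline" else "somatic",
                M.true = M, subclonal.true = sub,
                stringsAsFactors = FALSE)
            if (matched) {
                nn <- pmax(stats::rpois(nrow(out), depth), 2L)
                nf <- if (germline) stats::rbinom(nrow(out), nn, 0.5) / nn
                      else rep(0, nrow(out))
                out$normal.f <- nf
                out$normal.n <- nn
                out$matched.status <- if (germline) "germline" else "somatic"
            }
            out[alt > 0, , drop = FALSE]
        }
        out <- rbind(mk(n.germline, TRUE), mk(n.somatic, FALSE))
        if (is.null(out)) return(out)
        out <- out[order(match(out$chrom, unique(iv$chrom)), out$pos), ,
                   drop = FALSE]
        rownames(out) <- NULL
        out
    })
}

#' Simulate a complete tumor sample
#'
#' Bundles genome, coverage and variant simulation under one seed with two
#' canned designs: `"exome"` (2,000 targets at 100x, one heterozygous SNP
#' per 10 targets, 100 somatic variants) and `"panel"` (a 560-gene-like
#' design: 3,000 small targets at 400x).
#'
#' @param design `"exome"` or `"panel"`.
#' @param purity True purity.
#' @param target.ploidy Target ploidy in 1-6.
#' @param seed Integer seed.
#' @param ... Overrides passed to the stage simulators.
#' @return Object of class `tumorcn_sim`: list with `truth`, `intervals`,
#'   `tumor`, `reference`, `variants`, `design`, `seed`.
#' @export
simulateSample <- function(design = c("exome", "panel"), purity = 0.6,
                           target.ploidy = 2.0, seed = 1L, ...) {
    design <- match.arg(design)
    prm <- if (design == "exome") {
        list(n.targets = 2000L, n.segments = 40L, depth = 100,
             target.width = 200L, n.somatic = 100L)
    } else {
        list(n.targets = 3000L, n.segments = 40L, depth = 400,
             target.width = 100L, n.somatic = 60L)
    }
    dots <- list(...)
    for (k in names(dots)) prm[[k]] <- dots[[k]]
    truth <- simulateGenome(n.segments = prm$n.segments,
                            n.targets = prm$n.targets,
                            purity = purity, target.ploidy = target.ploidy,
                            seed = .stageSeed(seed, 1),
                            target.width = prm$target.width)
    cov <- simulateCoverage(truth, depth = prm$depth,
                            seed = .stageSeed(seed, 2))
    variants <- simulateVariants(truth, depth = prm$depth,
                                 n.somatic = prm$n.somatic,
                                 seed = .stageSeed(seed, 3))
    structure(list(truth = truth, intervals = truth$intervals,
                   tumor = cov$tumor, reference = cov$reference,
                   variants = variants, design = design, seed = seed),
              class = "tumorcn_sim")
}

#' Write a simulated sample to disk
#'
#' Emits GATK-dialect coverage TSVs for tumor and reference, a minimal VCF
#' with AD fields and dbSNP/COSMIC annotations, a BED file with a GC
#' column, and the truth as JSON.
#'
#' @param sim A `tumorcn_sim`.
#' @param dir Output directory.
#' @param name Sample name used in file names.
#' @return Character vector of files written, invisibly.
#' @export
writeSimulatedSample <- function(sim, dir, name = "sim") {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    iv <- sim$intervals
    key <- .intervalKey(iv$chrom, iv$start, iv$end)
    wr.cov <- function(cov, path) {
        utils::write.table(
            data.frame(Target = key,
                       total_coverage = round(cov * (iv$end - iv$start)),
                       average_coverage = sprintf("%.4f", cov)),
            path, sep = "\t", quote = FALSE, row.names = FALSE)
        path
    }
    f1 <- wr.cov(sim$tumor, file.path(dir, paste0(name, "_tumor.tsv")))
    f2 <- wr.cov(sim$reference, file.path(dir, paste0(name, "_normal.tsv")))
    bed <- file.path(dir, paste0(name, "_targets.bed"))
    utils::write.table(
        data.frame(iv$chrom, iv$start, iv$end, "target",
                   sprintf("%.4f", iv$gc.fraction)),
        bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    vcf <- file.path(dir, paste0(name, ".vcf"))
    v <- sim$variants
    info <- ifelse(v$in.dbsnp, "DB", ".")
    info <- ifelse(v$cosmic.count > 0,
                   paste0(ifelse(v$in.dbsnp, "DB;", ""), "Cnt=",
                          v$cosmic.count),
                   info)
    alt.n <- round(v$f * v$n)
    lines <- c(
        "##fileformat=VCFv4.2",
        "##INFO=<ID=DB,Number=0,Type=Flag,Description=\"dbSNP membership\">",
        "##INFO=<ID=Cnt,Number=1,Type=Integer,Description=\"COSMIC occurrence count\">",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
        paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
               name),
        sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s\tGT:AD\t0/1:%d,%d",
                v$chrom, v$pos,
                ifelse(v$in.dbsnp, sprintf("rs%07d", seq_len(nrow(v))), "."),
                v$ref, v$alt, info, v$n - alt.n, alt.n)
    )
    writeLines(lines, vcf)
    truth.json <- file.path(dir, paste0(name, "_truth.json"))
    jsonlite::write_json(list(
        purity = sim$truth$purity, ploidy = sim$truth$ploidy,
        seed = sim$seed, design = sim$design,
        segments = sim$truth$segments,
        variants = data.frame(chrom = v$chrom, pos = v$pos,
                              g.true = v$g.true, M.true = v$M.true,
                              subclonal.true = v$subclonal.true)
    ), truth.json, auto_unbox = TRUE, digits = NA)
    invisible(c(f1, f2, bed, vcf, truth.json))
}
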