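#' Default pipeline configuration
#'
#' Returns the full set of tunable parameters used by [runPipeline()] and the
#' individual stage functions, as a nested list. Every threshold, prior and
#' grid used anywhere in the package appears here so that a run can be
#' reproduced from its serialized configuration alone.
#'
#' @details Sections:
#' \describe{
#'   \item{norm}{GC-normalization span, pool-of-normals weight ceiling,
#'     low-coverage exclusion fraction, PCA components, coverage cap.}
#'   \item{segmentation}{CBS significance and permutations, breakpoint-pruning
#'     thresholds, copy-neutral LOH split parameters, Ward cut factor, SNP
#'     flank size in bp.}
#'   \item{fit}{Purity grid (0.15-0.95 in steps of 0.01), ploidy search range
#'     (1-6), maximum integer copy number (7), annealing and convergence
#'     controls, log-ratio recalibration ranges.}
#'   \item{priors}{Somatic-status prior table, multiplicity prior P_K,
#'     contamination rate and state prior, sub-clonal multiplicity, sequencing
#'     error rate, read-depth cap, low-purity threshold.}
#'   \item{filter}{Homozygous-variant and mapping-bias removal thresholds.}
#'   \item{curation}{Bootstrap and sample-flag thresholds.}
#'   \item{modes}{Switches: matched, high.purity, post.optimize,
#'     haploid.adjust, contamination.states.}
#' }
#'
#' @return Nested list of defaults.
#' @export
#' @examples
#' cfg <- defaultConfig()
#' cfg$fit$max.copy
defaultConfig <- function() {
    list(
        seed = 1L,
        cache = FALSE,
        norm = list(
            gc.span = 0.3,
            min.targets = 100L,
            weight.ceiling = 3,
            low.cov.frac = 0.2,
            pca.components = 3L,
            max.coverage = 100
        ),
        segmentation = list(
            alpha = 0.005,
            nperm = 10000L,
            min.width = 2L,
            prune.p = 0.001,
            prune.t = 0.2,
            prune.min.snps = 3L,
            loh.alpha = 0.005,
            loh.min.snps = 10L,
            ward.cut = 0.5,
            flank = 50L,
            het.range = c(0.1, 0.9)
        ),
        fit = list(
            purity.grid = seq(0.15, 0.95, by = 0.01),
            ploidy.min = 1.0,
            ploidy.max = 6.0,
            ploidy.step = 0.1,
            max.copy = 7L,
            max.candidates = 20L,
            shift.factor = 0.25,
            retry.shift.factor = 1.0,
            discard.delta = 0.75,
            max.sweeps = 100L,
            stable.sweeps = 3L,
            use.logsumexp = FALSE
        ),
        priors = list(
            matched.somatic = 0.999,
            matched.germline = 0.0001,
            unmatched.cosmic = 0.95,
            unmatched.dbsnp = 0.0005,
            unmatched.both = 0.01,
            unmatched.neither = 0.5,
            PK = 0.999,
            contamination.rate = 0.01,
            contamination.prior = 0.01,
            subclonal.M = 1 / 3,
            error.rate = 1e-3 / 3,
            n.cap = 300L,
            low.purity = 0.35,
            hom.prior = 0.05
        ),
        filter = list(
            hom.cutoff.normal = 0.9,
            hom.cutoff.tumor = 0.95,
            bias.p = 0.05,
            pool.min.normals = 5L,
            pool.biased.frac = 0.5
        ),
        curation = list(
            bootstrap.n = 500L,
            bootstrap.min.variants = 20L,
            bootstrap.top = 2L,
            bootstrap.ambiguous = 0.95,
            noisy.sd = 0.25,
            rare.ploidy.low = 1.5,
            rare.ploidy.high = 4.5,
            excessive.loh.frac = 0.9,
            hom.loss.frac = 0.05,
            non.aberrant.frac = 0.01,
            polygenomic.frac = 0.2,
            contamination.frac = 0.02,
            low.gof = 75
        ),
        modes = list(
            matched = FALSE,
            high.purity = FALSE,
            post.optimize = FALSE,
            haploid.adjust = TRUE,
            contamination.states = TRUE
        )
    )
}

#' Read a YAML configuration file
#'
#' Reads a YAML file and merges it over [defaultConfig()]; any omitted entry
#' keeps its default. Unknown keys raise an error so typos do not silently
#' fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return Nested configuration list.
#' @export
readConfig <- function(path) {
    user <- yaml::read_yaml(path)
    mergeConfig(user)
}

#' Merge a partial configuration over the defaults
#'
#' @param user Nested list with a subset of [defaultConfig()] entries.
#' @return Full configuration list.
#' @export
mergeConfig <- function(user) {
    base <- defaultConfig()
    if (is.null(user)) return(base)
    merge2 <- function(b, u, prefix) {
        for (k in names(u)) {
            if (!k %in% names(b)) {
                stop("unknown configuration key: ", paste0(prefix, k))
            }
            if (is.list(b[[k]]) && is.list(u[[k]])) {
                b[[k]] <- merge2(b[[k]], u[[k]], paste0(prefix, k, "."))
            } else {
                b[[k]] <- u[[k]]
            }
        }
        b
    }
    merge2(base, user, "")
}

#' Write a configuration to YAML
#'
#' @param config Configuration list.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeConfig <- function(config, path) {
    yaml::write_yaml(config, path)
    invisible(path)
}
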