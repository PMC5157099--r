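# Fixture builders shared across the test files. Everything is generated in
# code; nothing is read from disk except files the tests themselves write.

# a simple target grid on one or more chromosomes
mkIntervals <- function(n = 100, chrom = "chr1", spacing = 1000L,
                        width = 200L, gc = NULL) {
    per <- ceiling(n / length(chrom))
    out <- do.call(rbind, lapply(chrom, function(ch) {
        starts <- (seq_len(per) - 1L) * spacing
        data.frame(chrom = ch, start = starts, end = starts + width,
                   stringsAsFactors = FALSE)
    }))[seq_len(n), , drop = FALSE]
    out$gc.fraction <- if (is.null(gc)) rep(0.5, n) else rep_len(gc, n)
    out$on.target <- TRUE
    rownames(out) <- NULL
    out
}

# a log-ratio profile object as produced by calculateLogRatios()
mkProfile <- function(lr, intervals = NULL, weights = NULL) {
    if (is.null(intervals)) intervals <- mkIntervals(length(lr))
    if (is.null(weights)) weights <- rep(1, length(lr))
    structure(list(lr = lr, weights = weights,
                   retained = !is.na(lr), intervals = intervals,
                   sex = "unknown"),
              class = "tumorcn_lrprofile")
}

# a segment table row in the internal format
mkSegments <- function(chrom, start, end, seg.mean, sd = 0.05,
                       num.targets = 50L, bp.p = NA_real_,
                       intervals = NULL) {
    n <- length(seg.mean)
    num.targets <- rep_len(num.targets, n)
    sd <- rep_len(sd, n)
    bp.p <- rep_len(bp.p, n)
    segs <- data.frame(
        chrom = rep_len(chrom, n), start = start, end = end,
        first.target = cumsum(c(1, num.targets[-n])),
        last.target = cumsum(num.targets),
        num.targets = num.targets,
        size = end - start,
        seg.mean = seg.mean, sd = pmax(sd, 1e-4),
        sum.w = num.targets,
        sum.wx = num.targets * seg.mean,
        sum.wx2 = num.targets * (seg.mean^2 + sd^2),
        bp.p = bp.p, stringsAsFactors = FALSE)
    if (!is.null(intervals)) {
        attr(segs, "intervals") <- intervals
        attr(segs, "retained") <- rep(TRUE, nrow(intervals))
    }
    segs
}

# segments with log-ratios exactly at the expectation for given copy numbers
mkExactSegments <- function(C, purity, sd = 0.05, size = NULL,
                            num.targets = 50L) {
    n <- length(C)
    if (is.null(size)) size <- rep(150000L, n)
    D <- sum(size * C) / sum(size)
    r <- log2((purity * C + 2 * (1 - purity)) /
              (purity * D + 2 * (1 - purity)))
    start <- c(0, cumsum(size))[seq_len(n)]
    mkSegments("chr1", start, start + size, r, sd = sd,
               num.targets = num.targets)
}

# a minimal solution object for SNV-fitting tests: copy-number posterior
# concentrated on the given per-segment C
mkSolution <- function(C, purity, segments, max.copy = 7L,
                       concentration = 0.999) {
    n <- length(C)
    post <- matrix((1 - concentration) / (max.copy + 1), n, max.copy + 2L)
    post[, max.copy + 2L] <- 0
    post[cbind(seq_len(n), C + 1L)] <- concentration
    post <- post / rowSums(post)
    colnames(post) <- c(as.character(0:max.copy), "SUBCLONAL")
    D <- sum(segments$size * C) / sum(segments$size)
    structure(list(purity = purity, ploidy = D, shift = 0,
                   C = C, subclonal = rep(FALSE, n),
                   assign = C + 1L, posterior = post,
                   cn.loglik = 0, snv.loglik = NA_real_,
                   total.loglik = 0, gof = NA_real_,
                   flags = character(0), bootstrap.value = NA_real_,
                   rank = NA_integer_, discarded = FALSE),
              class = "tumorcn_solution")
}

# one-row variant table
mkVariant <- function(f, n, chrom = "chr1", pos = 500L, in.dbsnp = FALSE,
                      cosmic.count = 0L, matched.status = "unknown",
                      normal.f = NA_real_, normal.n = NA_real_) {
    data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
               f = f, n = n, in.dbsnp = in.dbsnp,
               cosmic.count = cosmic.count,
               matched.status = matched.status,
               normal.f = normal.f, normal.n = normal.n,
               stringsAsFactors = FALSE)
}

# write a small VCF for readVariants() tests
writeTestVCF <- function(path, rows, samples = "TUMOR") {
    header <- c(
        "##fileformat=VCFv4.2",
        "##INFO=<ID=DB,Number=0,Type=Flag,Description=\"dbSNP\">",
        "##INFO=<ID=SOMATIC,Number=0,Type=Flag,Description=\"somatic\">",
        "##INFO=<ID=Cnt,Number=1,Type=Integer,Description=\"COSMIC count\">",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", samples), collapse = "\t")
    )
    writeLines(c(header, rows), path)
    path
}

corSafe <- function(x, y) suppressWarnings(stats::cor(x, y))
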