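# I/O for target intervals, coverage tables, VCFs and result files.
# Internally all interval coordinates are 0-based half-open; emitted SEG and
# VCF coordinates follow their own conventions (1-based).

#' Read target intervals (BED or Picard-style interval list)
#'
#' Reads the capture target definitions. BED input is 0-based half-open;
#' Picard/GATK interval lists (lines starting with `@` in the header, then
#' `chrom start end strand name`) are 1-based closed and converted. An
#' optional numeric column in `[0,1]` (BED column 4 or 5, interval-list
#' column 6) is interpreted as the per-target GC fraction; otherwise a
#' reference FASTA must be supplied to compute it.
#'
#' @param path Interval file.
#' @param reference Optional path to a genome FASTA (or a
#'   [Biostrings::DNAStringSet]) used to compute GC fractions when the file
#'   does not provide them.
#' @return `data.frame` with columns `chrom`, `start` (0-based), `end`
#'   (exclusive), `gc.fraction`, `on.target`; sorted and validated.
#' @export
readIntervals <- function(path, reference = NULL) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    is.ilist <- any(startsWith(lines, "@"))
    body <- lines[!startsWith(lines, "@") & !startsWith(lines, "#") &
                  !startsWith(lines, "track") & !startsWith(lines, "browser")]
    if (length(body) == 0) stop("no intervals found in ", path)
    fields <- strsplit(body, "\t|[ ]+")
    ncols <- lengths(fields)
    if (any(ncols < 3)) stop("format error: lines with fewer than 3 columns")
    get <- function(i) vapply(fields, function(f)
        if (length(f) >= i) f[i] else NA_character_, character(1))
    chrom <- get(1)
    a <- suppressWarnings(as.numeric(get(2)))
    b <- suppressWarnings(as.numeric(get(3)))
    if (anyNA(a) || anyNA(b)) stop("format error: non-numeric coordinates")
    if (is.ilist) {
        start <- as.integer(a) - 1L   # 1-based closed -> 0-based half-open
        end <- as.integer(b)
        gc <- .maybeGCColumn(fields, 6L)
    } else {
        start <- as.integer(a)
        end <- as.integer(b)
        gc <- .maybeGCColumn(fields, 4L)
        if (all(is.na(gc))) gc <- .maybeGCColumn(fields, 5L)
    }
    intervals <- data.frame(chrom = chrom, start = start, end = end,
                            gc.fraction = gc, on.target = TRUE,
                            stringsAsFactors = FALSE)
    .validateIntervals(intervals)
    if (all(is.na(intervals$gc.fraction))) {
        if (is.null(reference)) {
            stop("no GC column in ", path,
                 " and no reference sequence provided")
        }
        intervals$gc.fraction <- .gcFromReference(intervals, reference)
    }
    bad <- which(!is.na(intervals$gc.fraction) &
                 (intervals$gc.fraction < 0 | intervals$gc.fraction > 1))
    if (length(bad)) stop("gc.fraction outside [0,1] at interval ",
                          .intervalKey(intervals$chrom[bad[1]],
                                       intervals$start[bad[1]],
                                       intervals$end[bad[1]]))
    rownames(intervals) <- NULL
    intervals
}

.maybeGCColumn <- function(fields, i) {
    v <- suppressWarnings(as.numeric(vapply(fields, function(f)
        if (length(f) >= i) f[i] else NA_character_, character(1))))
    if (all(!is.na(v)) && all(v >= 0) && all(v <= 1)) v else rep(NA_real_, length(fields))
}

.validateIntervalOrder <- function(intervals) {
    for (ch in unique(intervals$chrom)) {
        idx <- which(intervals$chrom == ch)
        s <- intervals$start[idx]
        e <- intervals$end[idx]
        if (any(s >= e)) {
            k <- idx[which(s >= e)[1]]
            stop("invalid interval (start >= end): ",
                 .intervalKey(intervals$chrom[k], intervals$start[k],
                              intervals$end[k]))
        }
        if (length(idx) > 1) {
            prev.end <- e[-length(e)]
            nxt.start <- s[-1]
            off <- which(nxt.start < prev.end)
            if (length(off)) {
                k <- idx[off[1] + 1L]
                stop("overlapping or unsorted intervals at ",
                     .intervalKey(intervals$chrom[k], intervals$start[k],
                                  intervals$end[k]))
            }
        }
    }
    invisible(TRUE)
}

.validateIntervals <- .validateIntervalOrder

.gcFromReference <- function(intervals, reference) {
    seqs <- if (methods::is(reference, "DNAStringSet")) reference
            else Biostrings::readDNAStringSet(reference)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    missing <- setdiff(unique(intervals$chrom), names(seqs))
    if (length(missing)) {
        stop("chromosomes missing from reference: ",
             paste(missing, collapse = ", "))
    }
    vapply(seq_len(nrow(intervals)), function(i) {
        s <- Biostrings::subseq(seqs[[intervals$chrom[i]]],
                                start = intervals$start[i] + 1L,
                                end = intervals$end[i])
        fr <- Biostrings::letterFrequency(s, c("A", "C", "G", "T"))
        tot <- sum(fr)
        if (tot == 0) return(NA_real_)
        unname((fr[["C"]] + fr[["G"]]) / tot)
    }, numeric(1))
}

#' Read a per-target coverage table
#'
#' Accepts either GATK DepthOfCoverage `sample_interval_summary` output
#' (a `Target` column in the 1-based `chrom:start-end` dialect plus
#' `total_coverage` / `average_coverage` columns) or a plain 4-column TSV
#' (`chrom`, `start`, `end`, `average_coverage`; 0-based half-open). The
#' dialect is auto-detected from the header.
#'
#' @param path Coverage file.
#' @param intervals Target intervals from [readIntervals()].
#' @return Numeric vector of average coverage, aligned to `intervals`.
#' @export
readCoverage <- function(path, intervals) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE)
    cols <- tolower(names(tab))
    if ("target" %in% cols) {
        keys <- tab[[which(cols == "target")[1]]]
        avg.col <- which(cols %in% c("average_coverage", "mean_coverage"))
        if (!length(avg.col)) stop("no average_coverage column in ", path)
        cov <- as.numeric(tab[[avg.col[1]]])
    } else if (all(c("chrom", "start", "end") %in% cols)) {
        avg.col <- which(cols %in% c("average_coverage", "coverage"))
        if (!length(avg.col)) stop("no coverage column in ", path)
        keys <- .intervalKey(tab[[which(cols == "chrom")[1]]],
                             tab[[which(cols == "start")[1]]],
                             tab[[which(cols == "end")[1]]])
        cov <- as.numeric(tab[[avg.col[1]]])
    } else {
        stop("unrecognized coverage file header in ", path)
    }
    if (anyDuplicated(keys)) {
        stop("duplicated interval row in ", path, ": ",
             keys[duplicated(keys)][1])
    }
    want <- .intervalKey(intervals$chrom, intervals$start, intervals$end)
    idx <- match(want, keys)
    if (anyNA(idx)) {
        miss <- want[is.na(idx)]
        stop("coverage file ", path, " missing targets: ",
             paste(utils::head(miss, 5), collapse = ", "),
             if (length(miss) > 5) sprintf(" (and %d more)", length(miss) - 5))
    }
    if (length(keys) != nrow(intervals)) {
        extra <- setdiff(keys, want)
        stop("coverage file ", path, " contains intervals not in the target ",
             "set: ", paste(utils::head(extra, 5), collapse = ", "))
    }
    cov[idx]
}

#' Read SNVs from a VCF
#'
#' Parses a VCF (e.g. MuTect output) into the variant table used by the SNV
#' model. Only biallelic SNVs are kept; skipped records are counted in the
#' `skipped` attribute. Allelic fraction and depth are derived from the `AD`
#' field; dbSNP membership from the ID column (`rs...`) or a `DB` INFO flag;
#' COSMIC evidence from a configurable INFO count key.
#'
#' @param path VCF file.
#' @param tumor.id Tumor sample name; defaults to the only sample, or the
#'   first sample that is not `normal.id`.
#' @param normal.id Optional matched-normal sample name.
#' @param cosmic.field INFO key holding the COSMIC occurrence count.
#' @return `data.frame` with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `f`, `n`, `in.dbsnp`, `cosmic.count`, `matched.status`, `normal.f`,
#'   `normal.n`.
#' @export
readVariants <- function(path, tumor.id = NULL, normal.id = NULL,
                         cosmic.field = "Cnt") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    if (nrow(fix) == 0) stop("no records in ", path)
    info <- vcfR::getINFO(v)
    samples <- colnames(v@gt)[-1]
    if (length(samples) == 0) stop("no sample (tumor) column in ", path)
    if (is.null(tumor.id)) {
        tumor.id <- setdiff(samples, normal.id)[1]
    }
    if (!tumor.id %in% samples) stop("tumor sample ", tumor.id, " not in VCF")
    if (!is.null(normal.id) && !normal.id %in% samples) {
        stop("normal sample ", normal.id, " not in VCF")
    }
    ad <- vcfR::extract.gt(v, element = "AD")
    if (is.null(ad) || all(is.na(ad[, tumor.id]))) {
        stop("AD field missing for tumor sample in ", path)
    }
    is.snv <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
        fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
    n.skipped <- sum(!is.snv)
    keep <- which(is.snv)
    parseAD <- function(x) {
        parts <- strsplit(x, ",", fixed = TRUE)
        ref <- vapply(parts, function(p)
            suppressWarnings(as.numeric(p[1])), numeric(1))
        alt <- vapply(parts, function(p)
            if (length(p) >= 2) suppressWarnings(as.numeric(p[2])) else NA_real_,
            numeric(1))
        cbind(ref, alt)
    }
    tad <- parseAD(ad[keep, tumor.id])
    if (anyNA(tad)) stop("AD field missing or malformed for some records")
    n <- tad[, 1] + tad[, 2]
    f <- ifelse(n > 0, tad[, 2] / n, 0)
    id <- fix$ID[keep]
    inf <- info[keep]
    in.dbsnp <- (!is.na(id) & grepl("^rs", id)) |
        grepl("(^|;)DB(;|$)", inf)
    cnt <- rep(0L, length(keep))
    m <- regmatches(inf, regexpr(paste0("(^|;)", cosmic.field, "=[0-9]+"), inf))
    has <- lengths(regmatches(inf,
        gregexpr(paste0("(^|;)", cosmic.field, "=[0-9]+"), inf))) > 0
    cnt[has] <- as.integer(sub(paste0(".*", cosmic.field, "="), "",
                               m[seq_len(sum(has))]))
    status <- rep("unknown", length(keep))
    normal.f <- rep(NA_real_, length(keep))
    normal.n <- rep(NA_real_, length(keep))
    if (!is.null(normal.id)) {
        nad <- parseAD(ad[keep, normal.id])
        nn <- nad[, 1] + nad[, 2]
        normal.n <- nn
        normal.f <- ifelse(nn > 0, nad[, 2] / nn, 0)
        somatic.flag <- grepl("(^|;)SOMATIC(;|$)", inf)
        status <- ifelse(somatic.flag | normal.f <= 0.02, "somatic", "germline")
    }
    out <- data.frame(
        chrom = fix$CHROM[keep],
        pos = as.integer(fix$POS[keep]),
        ref = fix$REF[keep],
        alt = fix$ALT[keep],
        f = f, n = n,
        in.dbsnp = in.dbsnp,
        cosmic.count = cnt,
        matched.status = status,
        normal.f = normal.f,
        normal.n = normal.n,
        stringsAsFactors = FALSE
    )
    attr(out, "skipped") <- n.skipped
    out
}

#' Read a SEG file
#'
#' Reads segmented copy-number data (columns sample, chrom, start, end,
#' num_targets/num.mark, seg_mean; 1-based start) as an alternative pipeline
#' entry point. An optional `sd` column carries per-segment log-ratio noise.
#'
#' @param path SEG file.
#' @return `data.frame` with `sample`, `chrom`, `start` (0-based), `end`,
#'   `num.targets`, `seg.mean` and optionally `sd`.
#' @export
readSegFile <- function(path) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE)
    cols <- tolower(gsub("[._]", "", names(tab)))
    pick <- function(alts) {
        i <- which(cols %in% alts)
        if (!length(i)) stop("SEG file missing column: ", alts[1])
        tab[[i[1]]]
    }
    out <- data.frame(
        sample = as.character(pick(c("id", "sample", "sampleid"))),
        chrom = as.character(pick(c("chrom", "chromosome", "chr"))),
        start = as.integer(pick(c("locstart", "start"))) - 1L,
        end = as.integer(pick(c("locend", "end"))),
        num.targets = as.integer(pick(c("nummark", "numtargets", "numprobes"))),
        seg.mean = as.numeric(pick(c("segmean", "mean"))),
        stringsAsFactors = FALSE
    )
    if (any(cols == "sd")) out$sd <- as.numeric(tab[[which(cols == "sd")[1]]])
    out
}

#' Write pipeline outputs
#'
#' Writes (a) a SEG file of the best solution with extra `C`, `K`, `LOH`
#' columns, (b) a per-variant TSV with state posteriors, and (c) a run
#' summary both as human-readable text and as a machine-readable
#' key-value table. SEG coordinates are written 1-based.
#'
#' @param result A pipeline result from [runPipeline()] (or a compatible
#'   list with elements `best`, `segments`, `variant.fit`, `sample.id`).
#' @param prefix Output path prefix; files `<prefix>_seg.tsv`,
#'   `<prefix>_variants.tsv`, `<prefix>_summary.txt` and
#'   `<prefix>_summary.tsv` are created.
#' @return Character vector of the files written, invisibly.
#' @export
writeOutputs <- function(result, prefix) {
    dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    sol <- result$best
    sample.id <- if (!is.null(result$sample.id)) result$sample.id else "sample"
    segs <- result$segments
    seg.path <- paste0(prefix, "_seg.tsv")
    seg.out <- data.frame(
        ID = sample.id,
        chrom = segs$chrom,
        loc.start = segs$start + 1L,
        loc.end = segs$end,
        num.mark = segs$num.targets,
        seg.mean = sprintf("%.6g", segs$seg.mean),
        C = if (!is.null(segs$C)) segs$C else NA,
        K = if (!is.null(segs$K)) segs$K else NA,
        LOH = if (!is.null(segs$loh)) segs$loh else NA,
        stringsAsFactors = FALSE
    )
    utils::write.table(seg.out, seg.path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, seg.path)
    if (!is.null(result$variant.fit)) {
        var.path <- paste0(prefix, "_variants.tsv")
        calls <- result$variant.fit$calls
        var.out <- data.frame(
            chrom = calls$chrom, pos = calls$pos,
            ref = calls$ref, alt = calls$alt,
            AF = sprintf("%.6g", calls$f), depth = calls$n,
            prior.somatic = sprintf("%.6g", calls$prior.somatic),
            posterior.somatic = sprintf("%.6g", calls$posterior.somatic),
            ML.SOMATIC = calls$ml.somatic,
            ML.state = calls$ml.state,
            ML.C = calls$ml.C, ML.M = calls$ml.M,
            expected.AF = sprintf("%.6g", calls$expected.af),
            CELLFRACTION = ifelse(is.na(calls$cellfraction), "",
                                  sprintf("%.6g", calls$cellfraction)),
            h.raw = ifelse(is.na(calls$h.raw), "",
                           sprintf("%.6g", calls$h.raw)),
            flags = calls$flag,
            stringsAsFactors = FALSE
        )
        utils::write.table(var.out, var.path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        files <- c(files, var.path)
    }
    kv <- c(
        sample = sample.id,
        purity = sprintf("%.4f", sol$purity),
        ploidy = sprintf("%.4f", sol$ploidy),
        cn.loglik = sprintf("%.6g", sol$cn.loglik),
        snv.loglik = if (is.na(sol$snv.loglik)) "NA"
                     else sprintf("%.6g", sol$snv.loglik),
        total.loglik = sprintf("%.6g", sol$total.loglik),
        gof = if (is.null(result$gof) || is.na(result$gof)) "NA"
              else sprintf("%.2f", result$gof),
        bootstrap.value = if (is.na(sol$bootstrap.value)) "NA"
                          else sprintf("%.3f", sol$bootstrap.value),
        sex = if (!is.null(result$sex)) result$sex else "unknown",
        mode = if (is.null(result$variant.fit)) "copy-number-only" else "full",
        flags = paste(result$flags, collapse = ","),
        needs.curation = as.character(length(result$flags) > 0)
    )
    kv.path <- paste0(prefix, "_summary.tsv")
    utils::write.table(data.frame(key = names(kv), value = unname(kv)),
                       kv.path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, kv.path)
    txt.path <- paste0(prefix, "_summary.txt")
    txt <- c(
        sprintf("Sample: %s", sample.id),
        sprintf("Purity: %s  Ploidy: %s", kv[["purity"]], kv[["ploidy"]]),
        sprintf("Log-likelihood (copy number): %s", kv[["cn.loglik"]]),
        sprintf("Log-likelihood (SNV): %s", kv[["snv.loglik"]]),
        sprintf("Goodness of fit: %s%%", kv[["gof"]]),
        sprintf("Bootstrap value: %s", kv[["bootstrap.value"]]),
        sprintf("Sex: %s", kv[["sex"]]),
        sprintf("Mode: %s", kv[["mode"]]),
        sprintf("Flags: %s", if (nzchar(kv[["flags"]])) kv[["flags"]]
                             else "none"),
        sprintf("Needs curation: %s", kv[["needs.curation"]])
    )
    writeLines(txt, txt.path)
    files <- c(files, txt.path, kv.path)
    invisible(unique(files))
}
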