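#' Is a chromosome name a sex chromosome?
#'
#' Accepts any case and an optional "chr" prefix.
#'
#' @param chrom character vector of chromosome names.
#' @return logical vector, `TRUE` for X or Y.
#' @keywords internal
is_sex_chromosome <- function(chrom) {
  core <- toupper(sub("^chr", "", as.character(chrom), ignore.case = TRUE))
  core %in% c("X", "Y")
}

#' Read a somatic SNV table
#'
#' Reads a tab-separated table with one row per somatic SNV. Required
#' columns are `chrom`, `pos` (1-based), `ref_count` and `alt_count`; extra
#' columns are ignored (an `id` column, if present, is kept as the SNV
#' identifier). The variant allele frequency `beta = alt_count / total` is
#' computed per row. On a male sample, SNVs on X or Y are flagged as haploid
#' (`male_sex_chrom`), which switches the prevalence model for those loci.
#'
#' @param path path to the TSV file, or a `data.frame` with the same columns.
#' @param sex `"female"` (default) or `"male"`.
#' @return a `data.frame` with columns `id`, `chrom`, `pos`, `ref_count`,
#'   `alt_count`, `total`, `beta`, `male_sex_chrom`.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("chrom\tpos\tref_count\talt_count", "chr1\t100\t60\t40"), tsv)
#' read_snv_table(tsv)
#' @export
read_snv_table <- function(path, sex = c("female", "male")) {
  sex <- match.arg(sex)
  tab <- if (is.data.frame(path)) {
    path
  } else {
    if (!file.exists(path)) stop("SNV file not found: ", path)
    utils::read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE)
  }
  needed <- c("chrom", "pos", "ref_count", "alt_count")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0) {
    stop("SNV table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  pos <- as.integer(tab$pos)
  ref <- as.integer(tab$ref_count)
  alt <- as.integer(tab$alt_count)
  bad <- which(is.na(pos) | is.na(ref) | is.na(alt) | ref < 0 | alt < 0)
  if (length(bad) > 0) {
    stop("invalid SNV counts (negative or non-numeric) at row ", bad[1])
  }
  total <- ref + alt
  zero <- which(total == 0)
  if (length(zero) > 0) {
    stop("SNV with zero read depth at row ", zero[1])
  }
  id <- if ("id" %in% names(tab)) as.character(tab$id) else
    paste0(tab$chrom, ":", pos)
  if (anyDuplicated(id)) id <- make.unique(id, sep = "_")
  data.frame(
    id = id,
    chrom = as.character(tab$chrom),
    pos = pos,
    ref_count = ref,
    alt_count = alt,
    total = total,
    beta = alt / total,
    male_sex_chrom = is_sex_chromosome(tab$chrom) & sex == "male",
    stringsAsFactors = FALSE
  )
}

#' Read somatic SNVs from a VCF file
#'
#' Convenience reader for MuTect-style VCFs: alt/ref depths are taken from
#' the `AD` FORMAT field of one sample. The TSV interface
#' ([read_snv_table()]) is the canonical input; this reader simply converts
#' to the same data frame.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param sample sample name; defaults to the first sample column.
#' @inheritParams read_snv_table
#' @return as [read_snv_table()].
#' @export
read_snv_vcf <- function(path, sex = c("female", "male"), sample = NULL) {
  sex <- match.arg(sex)
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package; ",
         "use the TSV interface otherwise")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(sample)) sample <- colnames(ad)[1]
  if (!sample %in% colnames(ad)) stop("sample not found in VCF: ", sample)
  parts <- strsplit(ad[, sample], ",", fixed = TRUE)
  ref <- vapply(parts, function(p) suppressWarnings(as.integer(p[1])), 1L)
  alt <- vapply(parts, function(p) suppressWarnings(as.integer(p[2])), 1L)
  keep <- !is.na(ref) & !is.na(alt) & (ref + alt) > 0
  fix <- vcfR::getFIX(v)
  read_snv_table(data.frame(
    chrom = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"]),
    ref_count = ref[keep],
    alt_count = alt[keep],
    stringsAsFactors = FALSE
  ), sex = sex)
}

#' Read allele-specific copy-number segments
#'
#' Reads a Battenberg-like tab-separated segment table with columns `chrom`,
#' `start`, `end` (0-based, half-open), `major`, `minor` and optionally
#' `frac` (fraction of cells in that state). Rows sharing an identical
#' `(chrom, start, end)` interval are merged into one multistate segment,
#' encoding copy-number events that happened independently in different
#' subclones on the same region. Partially overlapping intervals on a
#' chromosome are rejected.
#'
#' @param path path to the TSV file, or a `data.frame` with the same columns.
#' @return a `data.frame` of copy-number states with columns `segment_id`,
#'   `chrom`, `start`, `end`, `major`, `minor`, `frac` (NA when absent) and
#'   `multistate`; one row per state, sorted by chromosome and start, with
#'   states of a segment sharing `segment_id`.
#' @export
read_cna_segments <- function(path) {
  tab <- if (is.data.frame(path)) {
    path
  } else {
    if (!file.exists(path)) stop("CNA file not found: ", path)
    utils::read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE)
  }
  needed <- c("chrom", "start", "end", "major", "minor")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0) {
    stop("CNA table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(tab) == 0) {
    return(data.frame(segment_id = character(), chrom = character(),
                      start = integer(), end = integer(), major = integer(),
                      minor = integer(), frac = numeric(),
                      multistate = logical(), stringsAsFactors = FALSE))
  }
  start <- as.numeric(tab$start)
  end <- as.numeric(tab$end)
  major <- as.integer(tab$major)
  minor <- as.integer(tab$minor)
  frac <- if ("frac" %in% names(tab)) as.numeric(tab$frac) else
    rep(NA_real_, nrow(tab))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad) > 0) stop("CNA segment with start >= end at row ", bad[1])
  bad <- which(is.na(major) | is.na(minor) | minor < 0 | major < minor)
  if (length(bad) > 0) {
    stop("CNA state with major < minor or negative copies at row ", bad[1])
  }
  bad <- which(!is.na(frac) & (frac <= 0 | frac > 1))
  if (length(bad) > 0) stop("CNA state fraction outside (0,1] at row ", bad[1])

  key <- paste(tab$chrom, start, end, sep = "\r")
  ord <- order(tab$chrom, start, match(key, unique(key)))
  out <- data.frame(
    segment_id = key,
    chrom = as.character(tab$chrom),
    start = start, end = end, major = major, minor = minor, frac = frac,
    stringsAsFactors = FALSE
  )[ord, ]
  n_states <- table(out$segment_id)
  out$multistate <- as.vector(n_states[out$segment_id] > 1)

  # per-segment fraction budget
  fs <- tapply(out$frac, out$segment_id, function(f) {
    if (all(is.na(f))) 0 else sum(f, na.rm = TRUE)
  })
  if (any(fs > 1 + 1e-9)) {
    stop("CNA state fractions sum to more than 1 for segment ",
         sub("\r", ":", names(fs)[which(fs > 1 + 1e-9)[1]]))
  }

  # reject partial overlaps: within a chromosome, distinct intervals must
  # be disjoint once identical intervals are merged
  seg <- unique(out[, c("segment_id", "chrom", "start", "end")])
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)])) {
      stop("overlapping but non-identical CNA segments on chromosome ", ch)
    }
  }
  seg_ids <- unique(out$segment_id)
  out$segment_id <- sprintf("seg%03d", match(out$segment_id, seg_ids))
  rownames(out) <- NULL
  out
}

#' Match SNVs to copy-number segments
#'
#' Finds, for each SNV, the segment whose half-open `[start, end)` interval
#' (0-based) contains the SNV's 1-based position. The coordinate conversion
#' (`pos - 1`) happens only here.
#'
#' @param snv SNV data frame from [read_snv_table()].
#' @param segments state table from [read_cna_segments()], or `NULL`.
#' @return character vector of `segment_id`s, `NA` where the SNV falls on no
#'   segment (no CNA event).
#' @export
lookup_cna <- function(snv, segments) {
  if (is.null(segments) || nrow(segments) == 0) {
    return(rep(NA_character_, nrow(snv)))
  }
  seg <- unique(segments[, c("segment_id", "chrom", "start", "end")])
  out <- rep(NA_character_, nrow(snv))
  for (ch in unique(snv$chrom)) {
    s <- seg[seg$chrom == ch, ]
    idx <- which(snv$chrom == ch)
    if (nrow(s) == 0) next
    s <- s[order(s$start), ]
    p0 <- snv$pos[idx] - 1                        # 1-based -> 0-based
    j <- findInterval(p0, s$start)
    hit <- j >= 1
    hit[hit] <- p0[hit] < s$end[j[hit]]
    out[idx[hit]] <- s$segment_id[j[hit]]
  }
  out
}

fmt_num <- function(x) formatC(x, digits = 6, format = "g")

#' Write challenge-style output files
#'
#' Writes the five SMC-Het-style text files summarising an inference result:
#' `1A.txt` (tumor purity), `1B.txt` (number of subclones), `1C.txt` (one
#' line per subclone: index from 1, SNV count, cellular prevalence),
#' `2A.txt` (one subclone index per input SNV, in input order) and `3A.txt`
#' (parent index per subclone; 0 denotes the normal-cell root parent).
#'
#' @param fit a fitted [subclones()] object (or a list with elements
#'   `purity`, `peaks`, `snv_support`, `assignment`, `tree`).
#' @param dir output directory, created if needed.
#' @return invisibly, the vector of files written.
#' @export
write_smchet_outputs <- function(fit, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create output directory: ", dir)
  }
  files <- file.path(dir, c("1A.txt", "1B.txt", "1C.txt", "2A.txt", "3A.txt"))
  writeLines(fmt_num(fit$purity), files[1])
  C <- length(fit$peaks)
  writeLines(as.character(C), files[2])
  writeLines(paste(seq_len(C), fit$snv_support, fmt_num(fit$peaks),
                   sep = "\t"), files[3])
  writeLines(as.character(fit$assignment), files[4])
  writeLines(as.character(fit$tree$parent), files[5])
  invisible(files)
}

#' Write SNV and CNA tables in the canonical TSV dialect
#'
#' @param snv SNV data frame ([read_snv_table()] layout).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_snv_table <- function(snv, path) {
  utils::write.table(
    snv[, c("chrom", "pos", "ref_count", "alt_count")], path,
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_snv_table
#' @param segments CNA state table ([read_cna_segments()] layout).
#' @export
write_cna_segments <- function(segments, path) {
  cols <- c("chrom", "start", "end", "major", "minor")
  if (any(!is.na(segments$frac))) cols <- c(cols, "frac")
  utils::write.table(segments[, cols], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
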