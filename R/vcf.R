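# VCF header harmonization, record sorting and per-sample splitting.
#
# Upstream VCFs vary by analysis center: different header entries,
# numbers of samples per file, numbers of files per sample, and
# variant callers.  The harmonized header standard is a fixed-order
# block of eight entries --
#
#   ##fileformat, ##filedate, ##center, ##platform, ##genome_ref.name,
#   ##genome_ref.url, ##patient_id, ##specimen_id
#
# -- followed by every remaining header line from the original file in
# its original order.  Record lines are never modified by
# harmonization; sorting reorders them so positions are numerically
# non-decreasing within each chromosome block.
#
# All functions here operate on plain-text VCF as a character vector of
# lines (as from readLines()); bgzip is out of scope.

harmonized_keys <- c("fileformat", "filedate", "center", "platform",
                     "genome_ref.name", "genome_ref.url", "patient_id",
                     "specimen_id")

# Split VCF lines into meta (## lines), the #CHROM column line, and
# record lines.  Errors if the column line is missing or a non-comment
# line precedes it.
vcf_parts <- function(lines) {
  is_meta <- str_starts(lines, "##")
  hdr_idx <- which(str_starts(lines, "#CHROM"))
  if (length(hdr_idx) != 1) {
    vault_abort("unparseable VCF: expected exactly one #CHROM line",
                class = "tcgavault_vcf_error")
  }
  if (any(!is_meta[seq_len(hdr_idx - 1)])) {
    vault_abort("unparseable VCF: non-header line before #CHROM",
                class = "tcgavault_vcf_error")
  }
  records <- lines[seq_along(lines) > hdr_idx]
  records <- records[nzchar(records)]
  list(meta = lines[seq_len(hdr_idx - 1)], header = lines[hdr_idx],
       records = records)
}

# "##key=value" -> c(key, value); non matching -> NULL
header_kv <- function(line) {
  m <- regmatches(line, regexec("^##([^=]+)=(.*)$", line))[[1]]
  if (length(m) == 3) m[2:3] else NULL
}

#' Harmonize a VCF header
#'
#' Rewrites the header block to the eight-entry standard in fixed
#' order, followed by all remaining original header lines in their
#' original order.  Values for the eight entries are taken from the
#' original header when present; otherwise they are filled from `meta`.
#' Record lines pass through untouched, and the operation is
#' idempotent.
#'
#' @param vcf_lines Character vector of VCF lines.
#' @param meta Named list (or one-row data frame) supplying fallback
#'   values for the standard keys: `center`, `platform`,
#'   `genome_ref.name`, `genome_ref.url`, `patient_id`, `specimen_id`,
#'   and optionally `fileformat` and `filedate`.
#' @return Character vector of harmonized VCF lines.
#' @export
harmonize_header <- function(vcf_lines, meta = list()) {
  meta <- as.list(meta)
  p <- vcf_parts(vcf_lines)
  kvs <- lapply(p$meta, header_kv)
  keys <- vapply(kvs, function(kv) if (is.null(kv)) NA_character_ else kv[1],
                 character(1))
  vals <- vapply(kvs, function(kv) if (is.null(kv)) NA_character_ else kv[2],
                 character(1))
  std <- character(0)
  for (k in harmonized_keys) {
    hit <- which(keys == k)
    v <- if (length(hit) > 0) vals[hit[1]] else meta[[k]]
    if (is.null(v) || length(v) == 0 || is.na(v)) {
      vault_abort(paste0("harmonization value for '", k,
                         "' found in neither header nor metadata"),
                  class = "tcgavault_vcf_error")
    }
    std <- c(std, paste0("##", k, "=", v))
  }
  passthrough <- p$meta[is.na(keys) | !(keys %in% harmonized_keys)]
  c(std, passthrough, p$header, p$records)
}

#' Sort VCF records within chromosome blocks
#'
#' Reorders record lines so POS is numerically non-decreasing within
#' each CHROM block.  Chromosome blocks keep the first-appearance order
#' of the input; ties at equal (CHROM, POS) keep input order, so the
#' sort is a stable permutation and idempotent.
#'
#' @param vcf_lines Character vector of VCF lines.
#' @return Character vector with records reordered.
#' @export
sort_records <- function(vcf_lines) {
  p <- vcf_parts(vcf_lines)
  if (length(p$records) == 0) return(c(p$meta, p$header))
  chrom <- sub("\t.*$", "", p$records)
  pos_txt <- vapply(strsplit(p$records, "\t", fixed = TRUE),
                    function(f) if (length(f) >= 2) f[2] else NA_character_,
                    character(1))
  bad <- which(is.na(pos_txt) | !grepl("^[0-9]+$", pos_txt))
  if (length(bad) > 0) {
    line_no <- length(p$meta) + 1 + bad[1]
    vault_abort(paste0("non-integer POS at line ", line_no),
                class = "tcgavault_vcf_error")
  }
  pos <- as.numeric(pos_txt)
  block <- match(chrom, unique(chrom))
  ord <- order(block, pos)  # stable
  c(p$meta, p$header, p$records[ord])
}

#' Split a multi-sample VCF per sample
#'
#' Under the `"split"` policy, emits one single-sample VCF per sample
#' column, each carrying the shared fixed columns (CHROM..FORMAT) plus
#' that sample's genotype column; every output has the full record
#' count.  Under `"no_split"` the input is returned as a singleton list
#' unchanged.
#'
#' @param vcf_lines Character vector of VCF lines.
#' @param policy `"split"` or `"no_split"`.
#' @return Named list of character vectors (names are sample ids).
#' @export
split_by_sample <- function(vcf_lines, policy = c("no_split", "split")) {
  policy <- match.arg(policy)
  if (policy == "no_split") return(list(vcf_lines))
  p <- vcf_parts(vcf_lines)
  hdr_fields <- strsplit(p$header, "\t", fixed = TRUE)[[1]]
  if (length(hdr_fields) <= 9) {
    vault_abort("split requested but the VCF has no sample columns",
                class = "tcgavault_vcf_error")
  }
  samples <- hdr_fields[-(1:9)]
  rec_fields <- strsplit(p$records, "\t", fixed = TRUE)
  out <- lapply(seq_along(samples), function(si) {
    col <- 9 + si
    hdr <- paste(c(hdr_fields[1:9], samples[si]), collapse = "\t")
    recs <- vapply(rec_fields, function(f)
      paste(c(f[1:9], f[col]), collapse = "\t"), character(1))
    c(p$meta, hdr, recs)
  })
  setNames(out, samples)
}

# Multiset of (CHROM, POS, REF, ALT) keys -- the conserved quantity of
# harmonization and sorting.
vcf_record_keys <- function(vcf_lines) {
  p <- vcf_parts(vcf_lines)
  if (length(p$records) == 0) return(character(0))
  f <- strsplit(p$records, "\t", fixed = TRUE)
  sort(vapply(f, function(x) paste(x[c(1, 2, 4, 5)], collapse = "|"),
              character(1)))
}
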