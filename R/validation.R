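# Data validation routines.
#
# Five checks run against fetched files before ingest:
#   1. barcode/UUID correspondence (with correction from the
#      authoritative UUID map),
#   2. tissue-source-site name standardization via a curated mapping
#      table covering alternative names, hyphens, misspellings and
#      extra spaces,
#   3. VCF chromosome/position sortedness,
#   4. MD5 checksum verification,
#   5. download-log audit identifying failed attempts for retry.
#
# Checks return findings, never throw for data problems: severity is
# one of ok / corrected / flagged / error.

finding <- function(check, path, severity, detail = "", extra = list()) {
  out <- tibble::tibble(check = check, path = path %||% NA_character_,
                        severity = severity, detail = detail)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

#' Check barcode/UUID correspondence
#'
#' TCGA barcodes must correspond to the analysis-specific UUID of the
#' entity (sample, aliquot, shipped portion).  The UUID map is treated
#' as authoritative: on mismatch the barcode is corrected to the map's
#' value; a UUID absent from the map is flagged and the barcode left
#' untouched.
#'
#' @param file_meta List or one-row data frame with `barcode`, `uuid`,
#'   and optionally `path`.
#' @param uuid_map Tibble with columns `uuid`, `barcode` (see
#'   [read_uuid_map()]).
#' @return One-row finding tibble with an extra `corrected_barcode`
#'   column (the barcode to use downstream).
#' @export
check_barcode_uuid <- function(file_meta, uuid_map) {
  fm <- as.list(file_meta)
  expected <- uuid_map$barcode[uuid_map$uuid == fm$uuid]
  if (length(expected) == 0) {
    return(finding("barcode_uuid", fm$path, "flagged",
                   paste0("uuid ", fm$uuid, " absent from map"),
                   list(corrected_barcode = fm$barcode)))
  }
  if (identical(expected[1], fm$barcode)) {
    finding("barcode_uuid", fm$path, "ok", "",
            list(corrected_barcode = fm$barcode))
  } else {
    finding("barcode_uuid", fm$path, "corrected",
            paste0("barcode '", fm$barcode, "' corrected to '",
                   expected[1], "'"),
            list(corrected_barcode = expected[1]))
  }
}

#' Load a barcode/UUID mapping table
#'
#' Two-column tab-delimited file with header `uuid<TAB>barcode`.
#'
#' @param path Path to the mapping file.
#' @return Tibble with columns `uuid`, `barcode`.
#' @export
read_uuid_map <- function(path) {
  m <- read_tsv_quiet(path)
  if (!all(c("uuid", "barcode") %in% names(m))) {
    vault_abort("uuid map must have columns 'uuid' and 'barcode'")
  }
  if (anyDuplicated(m$uuid)) vault_abort("duplicate uuids in map")
  m
}

#' Load a tissue-source-site mapping table
#'
#' Two-column tab-delimited file (`raw_name`, `canonical_name`)
#' accounting for alternative names, hyphens, misspellings and extra
#' spaces.  Canonical names must be fixpoints of the mapping.  With no
#' path, the table shipped with the package is loaded.
#'
#' @param path Optional path to a mapping file.
#' @return Tibble with columns `raw_name`, `canonical_name`, plus a
#'   normalized lookup key column `key`.
#' @export
read_tss_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "tss_mapping.tsv",
                                package = "tcgavault")
  m <- read_tsv_quiet(path)
  if (!all(c("raw_name", "canonical_name") %in% names(m))) {
    vault_abort("tss table must have columns 'raw_name' and 'canonical_name'")
  }
  m$key <- tss_key(m$raw_name)
  canon <- unique(m$canonical_name)
  missing_fix <- setdiff(tss_key(canon), m$key)
  if (length(missing_fix) > 0) {
    vault_abort("tss table: canonical names must map to themselves")
  }
  m
}

# Normalized lookup key: trim, collapse whitespace, case-fold.
tss_key <- function(x) tolower(str_squish(x))

#' Standardize a tissue-source-site name
#'
#' Looks the name up after trimming/collapsing whitespace and case
#' folding.  Canonical names map to themselves; the function is
#' idempotent.
#'
#' @param raw_name Character vector of site names.
#' @param table Mapping table from [read_tss_table()].
#' @return Tibble with columns `raw_name`, `canonical_name` (`NA` when
#'   unmapped), `mapped` (logical).
#' @export
normalize_tss <- function(raw_name, table = read_tss_table()) {
  idx <- match(tss_key(raw_name), table$key)
  tibble::tibble(
    raw_name = raw_name,
    canonical_name = table$canonical_name[idx],
    mapped = !is.na(idx)
  )
}

#' Check that a VCF is chromosome/position sorted
#'
#' Ok iff POS is numerically non-decreasing within every CHROM block
#' (blocks in first-appearance order); otherwise flagged with the first
#' offending record.
#'
#' @param vcf_lines Character vector of VCF lines.
#' @return One-row finding tibble with extra column `first_violation`
#'   (record index, `NA` when sorted).
#' @export
check_vcf_sorted <- function(vcf_lines) {
  p <- tryCatch(vcf_parts(vcf_lines), error = function(e) e)
  if (inherits(p, "error")) {
    return(finding("vcf_sorted", NA_character_, "error", conditionMessage(p),
                   list(first_violation = NA_integer_)))
  }
  if (length(p$records) == 0) {
    return(finding("vcf_sorted", NA_character_, "ok", "",
                   list(first_violation = NA_integer_)))
  }
  fields <- strsplit(p$records, "\t", fixed = TRUE)
  chrom <- vapply(fields, `[`, character(1), 1)
  pos_txt <- vapply(fields, function(f)
    if (length(f) >= 2) f[2] else NA_character_, character(1))
  if (any(is.na(pos_txt)) || any(!grepl("^[0-9]+$", pos_txt))) {
    bad <- which(is.na(pos_txt) | !grepl("^[0-9]+$", pos_txt))[1]
    return(finding("vcf_sorted", NA_character_, "error",
                   paste0("malformed record ", bad),
                   list(first_violation = bad)))
  }
  pos <- as.numeric(pos_txt)
  seen_last <- list()
  for (i in seq_along(chrom)) {
    prev <- seen_last[[chrom[i]]]
    if (!is.null(prev) && pos[i] < prev) {
      return(finding("vcf_sorted", NA_character_, "flagged",
                     paste0("POS decreases at record ", i),
                     list(first_violation = i)))
    }
    seen_last[[chrom[i]]] <- pos[i]
  }
  finding("vcf_sorted", NA_character_, "ok", "",
          list(first_violation = NA_integer_))
}

#' Verify a file's MD5 checksum
#'
#' @param path Path to a file.
#' @param expected_md5 Expected 32-hex-digit checksum.
#' @return One-row finding tibble with extra column `observed_md5`.
#' @export
verify_checksum <- function(path, expected_md5) {
  if (!file.exists(path)) {
    return(finding("checksum", path, "error", "file missing",
                   list(observed_md5 = NA_character_)))
  }
  got <- md5_file(path)
  if (identical(got, tolower(expected_md5))) {
    finding("checksum", path, "ok", "", list(observed_md5 = got))
  } else {
    finding("checksum", path, "flagged",
            paste0("md5 mismatch: expected ", expected_md5, ", got ", got),
            list(observed_md5 = got))
  }
}

#' Audit a download log for paths needing retry
#'
#' The download log is append-only, one tab-delimited record per fetch
#' attempt (`timestamp`, `path`, `attempt`, `outcome`, `md5`).  A path
#' needs retry iff its latest entry is a failure.
#'
#' @param log Either a path to a log file or a tibble of log entries.
#' @return Character vector of paths whose latest attempt failed,
#'   deduplicated.
#' @export
audit_download_log <- function(log) {
  entries <- if (is.character(log)) read_download_log(log) else log
  if (nrow(entries) == 0) return(character(0))
  latest <- entries |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$path) |>
    dplyr::slice_max(.data$.row, n = 1) |>
    dplyr::ungroup()
  sort(latest$path[latest$outcome != "ok"])
}

#' Read a download log
#'
#' @param path Path to a log written by [fetch_file()].
#' @return Tibble of log entries.
#' @export
read_download_log <- function(path) {
  if (!file.exists(path)) {
    return(tibble::tibble(timestamp = character(0), path = character(0),
                          attempt = integer(0), outcome = character(0),
                          md5 = character(0)))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) != 5)
  if (length(bad) > 0) {
    vault_abort(paste0("corrupt download log line ", bad[1]),
                class = "tcgavault_log_error")
  }
  tibble::tibble(
    timestamp = vapply(fields, `[`, character(1), 1),
    path = vapply(fields, `[`, character(1), 2),
    attempt = as.integer(vapply(fields, `[`, character(1), 3)),
    outcome = vapply(fields, `[`, character(1), 4),
    md5 = vapply(fields, `[`, character(1), 5)
  )
}
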