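# Repository file-name grammar and directory layout.
#
# Repository names extend the TCGA barcode with up to twelve further
# metadata components, in a fixed order:
#
#   (1) TCGA barcode, (2) access type (public|controlled), (3) disease
#   study abbreviation, (4) analysis center, (5) analysis platform,
#   (6) data level, (7) experiment id from the source archive name,
#   (8) analysis revision number, (9) TCGA revision number, (10)
#   reference genome (optional), (11) portion name (optional; e.g. the
#   "red"/"grn" idat portions of array methylation), (12) portion
#   number (default "1"), (13) repository version number.
#
# Components (2)-(13) are joined with "."; the barcode keeps its
# internal hyphens, so a single split on "." recovers every component.
# The file extension follows the last component and may itself contain
# dots (e.g. "tar.gz").  Metadata values are sanitized so no component
# contains a delimiter.
#
# Only files that arrive through the serial-numbered DCC-style archive
# are renamed with this grammar; BAM stubs and level-4 bundles keep
# their original names, and mass-spectrometry files gain an analysis
# date prefix (see ms_file_name()).

mandatory_name_fields <- c("barcode", "access", "disease", "center_name",
                           "platform", "level", "experiment_id",
                           "analysis_revision", "tcga_revision",
                           "repo_version", "extension")

#' Construct file-name fields
#'
#' Builds the one-row tibble of naming metadata consumed by
#' [build_file_name()] and [build_directory_path()].  `datatype` is
#' carried for directory construction and repository identity; it is
#' not itself a name component, but by construction the experiment id
#' is `<datatype>_<serial>`, so it is recoverable from the name.
#'
#' @param barcode TCGA barcode text (aliquot or truncated depth).
#' @param access `"public"` or `"controlled"`.
#' @param disease Disease study abbreviation (e.g. `"BRCA"`).
#' @param center_name Analysis center (e.g. `"broad.mit.edu"`).
#' @param platform Analysis platform label.
#' @param level Data level code (`"1"`..`"4"`, or `"0"`).
#' @param experiment_id Experiment id from the source archive name;
#'   conventionally `<datatype>_<serial>`.
#' @param analysis_revision,tcga_revision Integer revision numbers.
#' @param ref_genome Optional reference genome label (e.g. `"GRCh37"`).
#' @param portion_name Optional portion name (`"red"`/`"grn"`).
#' @param portion_number Integer, defaults to 1.
#' @param repo_version Repository version number, integer >= 1.
#' @param extension File suffix without leading dot (may contain dots,
#'   e.g. `"tar.gz"`).
#' @param datatype Datatype code; defaults to the experiment id with
#'   its trailing serial stripped.
#' @return A one-row tibble of class `tv_name_fields`.
#' @export
file_name_fields <- function(barcode, access, disease, center_name, platform,
                             level, experiment_id, analysis_revision = 1L,
                             tcga_revision = 1L, ref_genome = NA_character_,
                             portion_name = NA_character_, portion_number = 1L,
                             repo_version = 1L, extension = "txt",
                             datatype = NULL) {
  f <- tibble::tibble(
    barcode = as.character(barcode),
    access = as.character(access),
    disease = sanitize_component(disease),
    center_name = sanitize_component(center_name),
    platform = sanitize_component(platform),
    level = as.character(level),
    experiment_id = sanitize_component(experiment_id),
    analysis_revision = as.integer(analysis_revision),
    tcga_revision = as.integer(tcga_revision),
    ref_genome = if (is.na(ref_genome)) NA_character_ else sanitize_component(ref_genome),
    portion_name = as.character(portion_name),
    portion_number = as.integer(portion_number %||% 1L),
    repo_version = as.integer(repo_version),
    extension = as.character(extension),
    datatype = as.character(datatype %||% sub("_[0-9]+$", "", experiment_id))
  )
  validate_name_fields(f)
  class(f) <- c("tv_name_fields", class(f))
  f
}

validate_name_fields <- function(f) {
  for (fld in mandatory_name_fields) {
    v <- f[[fld]]
    if (is.null(v) || any(is.na(v)) || any(!nzchar(as.character(v)))) {
      vault_abort(paste0("missing mandatory naming field: ", fld),
                  class = "tcgavault_naming_error")
    }
  }
  if (!all(f$access %in% c("public", "controlled"))) {
    vault_abort("access must be 'public' or 'controlled'",
                class = "tcgavault_naming_error")
  }
  if (any(f$repo_version < 1L) || any(f$portion_number < 1L)) {
    vault_abort("repo_version and portion_number must be >= 1",
                class = "tcgavault_naming_error")
  }
  # extension may legitimately contain dots (e.g. tar.gz): it is the
  # terminal segment, recovered as everything after the version.
  non_barcode <- setdiff(names(f), c("barcode", "datatype", "extension"))
  for (fld in non_barcode) {
    v <- as.character(f[[fld]])
    if (any(grepl("[.[:space:]]", v[!is.na(v)]))) {
      vault_abort(paste0("naming field '", fld, "' contains a delimiter"),
                  class = "tcgavault_naming_error")
    }
  }
  invisible(f)
}

#' Build a repository file name
#'
#' Emits the present components in the enumerated (1)-(13) order,
#' followed by the extension.  Absent optional components (reference
#' genome, portion name) are omitted; the portion number is always
#' emitted, defaulting to `"1"`.
#'
#' @param f A [file_name_fields()] tibble (one or more rows).
#' @return Character vector of file names.
#' @examples
#' f <- file_name_fields("TCGA-A1-A0SB-01A-11D-A141-01", "public", "BRCA",
#'                       "broad.mit.edu", "IlluminaGA_DNASeq", "2",
#'                       "Somatic_Mutations_1", extension = "maf")
#' build_file_name(f)
#' @export
build_file_name <- function(f) {
  validate_name_fields(f)
  vapply(seq_len(nrow(f)), function(i) {
    r <- f[i, ]
    comps <- c(r$barcode, r$access, r$disease, r$center_name, r$platform,
               r$level, r$experiment_id, r$analysis_revision, r$tcga_revision,
               if (!is.na(r$ref_genome)) r$ref_genome,
               if (!is.na(r$portion_name)) r$portion_name,
               r$portion_number, r$repo_version)
    paste0(paste(comps, collapse = "."), ".", r$extension)
  }, character(1))
}

#' Parse a repository file name
#'
#' Inverse of [build_file_name()].  The two optional label components
#' after the revision numbers are disambiguated by vocabulary: a label
#' matching a known portion name (`"red"`/`"grn"`) is the portion name,
#' any other label is the reference genome; when both are present they
#' appear in (10), (11) order.
#'
#' @param text Character vector of names produced by [build_file_name()].
#' @return A tibble of name fields, one row per name.
#' @export
parse_file_name <- function(text) {
  dplyr::bind_rows(lapply(text, parse_file_name_one))
}

parse_file_name_one <- function(x) {
  toks <- strsplit(x, ".", fixed = TRUE)[[1]]
  if (length(toks) < 12) {
    vault_abort(paste0("file name '", x, "': expected at least 12 dot-",
                       "delimited components, got ", length(toks)),
                class = "tcgavault_naming_error")
  }
  bc <- toks[1]
  # Validates the barcode and fails early on tampered names.
  parse_barcode(bc)
  if (!toks[2] %in% c("public", "controlled")) {
    vault_abort(paste0("file name '", x, "': component 2 ('", toks[2],
                       "') is not an access type"),
                class = "tcgavault_naming_error")
  }
  as_int <- function(tok, what) {
    if (!grepl("^[0-9]+$", tok)) {
      vault_abort(paste0("file name '", x, "': ", what, " ('", tok,
                         "') is not an integer"),
                  class = "tcgavault_naming_error")
    }
    as.integer(tok)
  }
  rest <- toks[-(1:9)]
  # Optional labels precede the first integer token (portion number).
  n_lab <- 0
  while (n_lab < length(rest) && !grepl("^[0-9]+$", rest[n_lab + 1])) {
    n_lab <- n_lab + 1
  }
  if (n_lab > 2 || length(rest) < n_lab + 3) {
    vault_abort(paste0("file name '", x, "': malformed optional/terminal ",
                       "components"), class = "tcgavault_naming_error")
  }
  labs <- rest[seq_len(n_lab)]
  ref_genome <- NA_character_
  portion_name <- NA_character_
  if (n_lab == 2) {
    ref_genome <- labs[1]; portion_name <- labs[2]
  } else if (n_lab == 1) {
    if (labs %in% known_portion_names()) portion_name <- labs else ref_genome <- labs
  }
  tail_toks <- if (n_lab > 0) rest[-seq_len(n_lab)] else rest
  file_name_fields(
    barcode = bc, access = toks[2], disease = toks[3], center_name = toks[4],
    platform = toks[5], level = toks[6], experiment_id = toks[7],
    analysis_revision = as_int(toks[8], "analysis revision"),
    tcga_revision = as_int(toks[9], "TCGA revision"),
    ref_genome = ref_genome, portion_name = portion_name,
    portion_number = as_int(tail_toks[1], "portion number"),
    repo_version = as_int(tail_toks[2], "repository version"),
    extension = paste(tail_toks[-(1:2)], collapse = ".")
  )
}

#' Count the metadata components of a repository file name
#'
#' The number of dot-delimited components preceding the extension; a
#' maximally specified name has 13.
#'
#' @param text A file name produced by [build_file_name()].
#' @return Integer count.
#' @export
count_name_components <- function(text) {
  f <- parse_file_name_one(text)
  toks <- strsplit(text, ".", fixed = TRUE)[[1]]
  ext_toks <- length(strsplit(f$extension, ".", fixed = TRUE)[[1]])
  length(toks) - ext_toks
}

#' Build the participant/sample-oriented directory path
#'
#' `<disease>/<participant barcode>/<sample barcode>/<datatype>/Level_<n>/`.
#' A pure function of the name fields; the sample segment falls back to
#' the participant barcode when the barcode is truncated above sample
#' depth.
#'
#' @param f A [file_name_fields()] tibble.
#' @return Character vector of relative directory paths.
#' @export
build_directory_path <- function(f) {
  validate_name_fields(f)
  vapply(seq_len(nrow(f)), function(i) {
    r <- f[i, ]
    participant <- truncate_barcode(r$barcode, 3)
    sample <- truncate_barcode(r$barcode, 4)
    file.path(r$disease, participant, sample, r$datatype,
              paste0("Level_", r$level))
  }, character(1))
}

#' Date-prefixed mass-spectrometry file name
#'
#' Mass-spectrometry sources carry no versioning; the analysis date is
#' attached as a `YYYYMMDD_` prefix and the original name is otherwise
#' kept.
#'
#' @param original_name Original file name.
#' @param analysis_date ISO date (`"YYYY-MM-DD"`) or Date.
#' @return Prefixed file name.
#' @examples
#' ms_file_name("run.tsv", "2014-06-01")
#' @export
ms_file_name <- function(original_name, analysis_date) {
  d <- as.Date(analysis_date)
  if (any(is.na(d))) {
    vault_abort("analysis_date is not a valid ISO date",
                class = "tcgavault_naming_error")
  }
  paste0(format(d, "%Y%m%d"), "_", original_name)
}

#' Strip a mass-spectrometry date prefix
#'
#' @param name A name produced by [ms_file_name()].
#' @return The original file name.
#' @export
ms_strip_prefix <- function(name) {
  sub("^[0-9]{8}_", "", name)
}
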