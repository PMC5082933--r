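# The versioned, participant/sample-oriented local file store.
#
# Layout under the repository root:
#
#   current/<disease>/<participant>/<sample>/<datatype>/Level_<n>/<name>
#   archive/...   superseded or archived-on-removal versions
#   staging/      verified downloads before atomic ingest
#   index.tsv     one row per (logical_id, repo_version)
#
# A logical file is the identity under which successive content
# revisions are versioned: (datatype, barcode, level, portion name,
# portion number).  Exactly one current version exists per logical id
# (zero once deleted); versions run 1..k with no gaps; archived bytes
# and records are immutable.

index_cols <- c("logical_id", "repo_version", "status", "rel_path", "md5",
                "source_md5", "ingest_timestamp", "removed_timestamp", "barcode",
                "datatype", "disease", "level", "source_serial",
                "archive_name", "original_name", "original_path",
                "uses_grammar")

empty_index <- function() {
  out <- tibble::as_tibble(setNames(
    lapply(index_cols, function(x) character(0)), index_cols))
  out$repo_version <- integer(0)
  out$source_serial <- integer(0)
  out
}

#' Create a repository
#'
#' @param root Directory to create the repository under.
#' @return A `tv_repo` handle.
#' @export
repo_create <- function(root) {
  if (dir.exists(root) && file.exists(file.path(root, "index.tsv"))) {
    vault_abort(paste0("repository already exists at ", root),
                class = "tcgavault_repo_error")
  }
  for (d in c("current", "archive", "staging"))
    dir.create(file.path(root, d), recursive = TRUE, showWarnings = FALSE)
  write_tsv_quiet(empty_index(), file.path(root, "index.tsv"))
  writeLines(iso_now(), file.path(root, "created_at"))
  repo_handle(root)
}

repo_handle <- function(root) {
  structure(list(root = normalizePath(root)), class = "tv_repo")
}

#' Open an existing repository
#'
#' @param root Repository root created by [repo_create()].
#' @return A `tv_repo` handle.
#' @export
repo_open <- function(root) {
  if (!file.exists(file.path(root, "index.tsv"))) {
    vault_abort(paste0("no repository at ", root),
                class = "tcgavault_repo_error")
  }
  repo_handle(root)
}

read_index <- function(repo) {
  idx <- read_tsv_quiet(file.path(repo$root, "index.tsv"))
  if (nrow(idx) == 0) return(empty_index())
  idx$repo_version <- as.integer(idx$repo_version)
  idx$source_serial <- as.integer(idx$source_serial)
  idx
}

write_index <- function(repo, idx) {
  write_tsv_quiet(idx, file.path(repo$root, "index.tsv"))
}

#' Logical file identity
#'
#' The key under which successive content revisions of one analysis
#' output are versioned.
#'
#' @param f A [file_name_fields()] tibble.
#' @return Character vector of logical ids.
#' @export
logical_id <- function(f) {
  paste(f$datatype, f$barcode, f$level,
        ifelse(is.na(f$portion_name), "-", f$portion_name),
        f$portion_number, sep = "|")
}

# Monotonic ingest clock: never behind the latest index timestamp.
next_timestamp <- function(idx, now = NULL) {
  now <- now %||% iso_now()
  stamps <- c(idx$ingest_timestamp, idx$removed_timestamp)
  stamps <- stamps[!is.na(stamps)]
  if (length(stamps) > 0 && now <= max(stamps)) {
    now <- iso_plus(max(stamps), 1)
  }
  now
}

#' Ingest a verified staged file
#'
#' New logical ids enter at version 1.  Re-ingest with changed content
#' archives the previous version and creates the next version as
#' current; re-ingest with identical content creates no new version and
#' only refreshes the referenced archive serial in the provenance.
#'
#' @param repo A `tv_repo` handle.
#' @param staged_path Path to the verified staged file.
#' @param fields [file_name_fields()] for the file.
#' @param provenance List with `archive_name`, `serial`,
#'   `original_name`, `original_path`, and optionally `source_md5`
#'   (the upstream manifest checksum of the fetched bytes, kept so the
#'   repository remains auditable against the source even when
#'   harmonization rewrites the stored payload).
#' @param use_grammar Rename with the thirteen-component grammar
#'   (serial-archive files) or keep the original name (BAM stubs,
#'   level-4 bundles, date-prefixed mass-spec files).
#' @param expected_md5 Optional checksum; a mismatching staged file is
#'   rejected.
#' @param now Optional ISO instant for the ingest timestamp (defaults
#'   to the wall clock, kept strictly monotone per repository).
#' @return The stored file's one-row index entry.
#' @export
ingest_file <- function(repo, staged_path, fields, provenance = list(),
                        use_grammar = TRUE, expected_md5 = NULL,
                        now = NULL) {
  stopifnot(inherits(repo, "tv_repo"))
  md5 <- md5_file(staged_path)
  if (is.na(md5)) {
    vault_abort(paste0("staged file missing: ", staged_path),
                class = "tcgavault_repo_error")
  }
  if (!is.null(expected_md5) && !identical(md5, tolower(expected_md5))) {
    vault_abort(paste0("staged checksum mismatch for ", staged_path),
                class = "tcgavault_repo_error")
  }
  idx <- read_index(repo)
  lid <- logical_id(fields)
  mine <- idx[idx$logical_id == lid, ]
  cur <- mine[mine$status == "current", ]
  now <- next_timestamp(idx, now)
  if (nrow(cur) == 1 && identical(cur$md5, md5)) {
    # Unchanged content under a new archive serial: metadata-only
    # refresh, no new version.
    sel <- idx$logical_id == lid & idx$status == "current"
    idx$source_serial[sel] <- as.integer(provenance$serial %||%
                                           cur$source_serial)
    idx$archive_name[sel] <- provenance$archive_name %||% cur$archive_name
    write_index(repo, idx)
    return(idx[sel, ])
  }
  version <- if (nrow(mine) == 0) 1L else max(mine$repo_version) + 1L
  if (nrow(cur) == 1) {
    idx <- archive_version(repo, idx, lid, now)
  }
  fields$repo_version <- version
  dir_rel <- build_directory_path(fields)
  fname <- if (use_grammar) build_file_name(fields)
           else fields_original_name(fields, provenance, version)
  rel_path <- file.path("current", dir_rel, fname)
  dest <- file.path(repo$root, rel_path)
  dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
  move_file(staged_path, dest)
  row <- tibble::tibble(
    logical_id = lid, repo_version = version, status = "current",
    rel_path = rel_path, md5 = md5,
    source_md5 = as.character(provenance$source_md5 %||% md5),
    ingest_timestamp = now,
    removed_timestamp = NA_character_, barcode = fields$barcode,
    datatype = fields$datatype, disease = fields$disease,
    level = fields$level,
    source_serial = as.integer(provenance$serial %||% NA_integer_),
    archive_name = as.character(provenance$archive_name %||% NA_character_),
    original_name = as.character(provenance$original_name %||% fname),
    original_path = as.character(provenance$original_path %||% NA_character_),
    uses_grammar = as.character(use_grammar))
  idx <- dplyr::bind_rows(idx, row)
  write_index(repo, idx)
  row
}

# Original-name files get a version suffix only in the archive area;
# the current copy keeps the pristine name.
fields_original_name <- function(fields, provenance, version) {
  provenance$stored_name %||% provenance$original_name %||%
    vault_abort("original_name provenance required when the naming grammar is not used",
                class = "tcgavault_repo_error")
}

# Move the current version of lid into the archive area, marking it
# archived.  Archived bytes are never touched again.
archive_version <- function(repo, idx, lid, now) {
  sel <- idx$logical_id == lid & idx$status == "current"
  old <- idx[sel, ]
  arch_rel <- sub("^current/", "archive/", old$rel_path)
  if (identical(old$uses_grammar, "FALSE")) {
    arch_rel <- paste0(arch_rel, ".v", old$repo_version)
  }
  dest <- file.path(repo$root, arch_rel)
  dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
  move_file(file.path(repo$root, old$rel_path), dest)
  idx$status[sel] <- "archived"
  idx$rel_path[sel] <- arch_rel
  idx
}

move_file <- function(from, to) {
  ok <- suppressWarnings(file.rename(from, to))
  if (!ok) {
    if (!file.copy(from, to, overwrite = TRUE)) {
      vault_abort(paste0("cannot move ", from, " to ", to),
                  class = "tcgavault_repo_error")
    }
    unlink(from)
  }
  invisible(to)
}

#' Remove a logical file
#'
#' Under the `"archive"` policy the bytes are retained under the
#' archive area; under `"delete"` the bytes are removed and only the
#' tombstone record remains.  Either way the logical file's status
#' becomes `deleted` and snapshots before the removal instant still
#' list it.
#'
#' @param repo A `tv_repo` handle.
#' @param lid Logical id (see [logical_id()]).
#' @param policy `"archive"` or `"delete"`.
#' @param now Optional ISO instant for the removal timestamp.
#' @return The removed file's updated index entry.
#' @export
remove_file <- function(repo, lid, policy = c("archive", "delete"),
                        now = NULL) {
  policy <- match.arg(policy)
  idx <- read_index(repo)
  sel <- idx$logical_id == lid & idx$status == "current"
  if (sum(sel) != 1) {
    vault_abort(paste0("no current version for logical id: ", lid),
                class = "tcgavault_repo_error")
  }
  now <- next_timestamp(idx, now)
  old <- idx[sel, ]
  if (policy == "archive") {
    arch_rel <- sub("^current/", "archive/", old$rel_path)
    if (identical(old$uses_grammar, "FALSE")) {
      arch_rel <- paste0(arch_rel, ".v", old$repo_version)
    }
    dest <- file.path(repo$root, arch_rel)
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    move_file(file.path(repo$root, old$rel_path), dest)
    idx$rel_path[sel] <- arch_rel
  } else {
    unlink(file.path(repo$root, old$rel_path))
    idx$rel_path[sel] <- NA_character_
  }
  idx$status[sel] <- "deleted"
  idx$removed_timestamp[sel] <- now
  write_index(repo, idx)
  idx[sel, ]
}

#' Current repository contents
#'
#' @param repo A `tv_repo` handle.
#' @param disease,datatype,barcode_prefix Optional filters.
#' @return Tibble of current index entries, ordered by logical id.
#' @export
repo_current <- function(repo, disease = NULL, datatype = NULL,
                         barcode_prefix = NULL) {
  idx <- read_index(repo)
  cur <- idx[idx$status == "current", ]
  if (!is.null(disease)) cur <- cur[cur$disease %in% disease, ]
  if (!is.null(datatype)) cur <- cur[cur$datatype %in% datatype, ]
  if (!is.null(barcode_prefix))
    cur <- cur[startsWith(cur$barcode, barcode_prefix), ]
  dplyr::arrange(cur, .data$logical_id)
}

#' Reconstruct the repository as of an instant
#'
#' For each logical id, the version whose ingest timestamp is the
#' latest at or before `as_of` and that was not removed at or before
#' `as_of` -- the "data freeze" view used for reproducible analyses.
#' Snapshots key on the repository's ingest clock.
#'
#' @param repo A `tv_repo` handle.
#' @param as_of ISO-8601 instant (default: now).
#' @return Manifest tibble with columns `logical_id`, `repo_version`,
#'   `rel_path`, `md5`, ordered by logical id.
#' @export
repo_snapshot <- function(repo, as_of = iso_now()) {
  if (!is_iso_instant(as_of)) {
    vault_abort("as_of must be an ISO-8601 instant (YYYY-MM-DDTHH:MM:SSZ)",
                class = "tcgavault_repo_error")
  }
  idx <- read_index(repo)
  if (nrow(idx) == 0) {
    return(tibble::tibble(logical_id = character(0),
                          repo_version = integer(0),
                          rel_path = character(0), md5 = character(0)))
  }
  idx |>
    dplyr::filter(.data$ingest_timestamp <= as_of) |>
    dplyr::group_by(.data$logical_id) |>
    dplyr::slice_max(.data$repo_version, n = 1) |>
    dplyr::ungroup() |>
    dplyr::filter(is.na(.data$removed_timestamp) |
                    .data$removed_timestamp > as_of) |>
    dplyr::select("logical_id", "repo_version", "rel_path", "md5") |>
    dplyr::arrange(.data$logical_id)
}

#' Write a snapshot manifest
#'
#' Tab-delimited manifest (logical_id, version, path, md5) suitable for
#' command-line scripting.
#'
#' @param repo A `tv_repo` handle.
#' @param path Output file.
#' @param as_of ISO instant passed to [repo_snapshot()].
#' @return The manifest tibble, invisibly.
#' @export
write_snapshot_manifest <- function(repo, path, as_of = iso_now()) {
  snap <- repo_snapshot(repo, as_of)
  write_tsv_quiet(snap, path)
  invisible(snap)
}

#' Full version history of the repository
#'
#' @param repo A `tv_repo` handle.
#' @return The complete index tibble.
#' @export
repo_history <- function(repo) read_index(repo)
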