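# Provenance metadata store.
#
# One embedded relational-style store (tab-delimited tables under the
# store root) is the system of record; the triple form is an export.
# Tables:
#
#   records.tsv        file metadata, keyed by (logical_id, repo_version)
#   subscriptions.tsv  subscriber id + JSON filter
#   sync_state.tsv     per-source-store cursor (last serial / last date)
#   outbox.ndjson      notification events (transport is out of scope)
#   messages/          per-run JSON change-message documents

#' Create a metadata store
#'
#' @param root Directory to create the store under.
#' @param vocab_dir Optional directory of vocabulary overrides (see
#'   [load_vocabularies()]).
#' @return A `tv_meta` handle.
#' @export
meta_create <- function(root, vocab_dir = NULL) {
  if (dir.exists(root) && file.exists(file.path(root, "records.tsv"))) {
    vault_abort(paste0("metadata store already exists at ", root),
                class = "tcgavault_meta_error")
  }
  dir.create(file.path(root, "messages"), recursive = TRUE,
             showWarnings = FALSE)
  write_tsv_quiet(empty_records(), file.path(root, "records.tsv"))
  write_tsv_quiet(tibble::tibble(subscriber = character(0),
                                 filter = character(0),
                                 created = character(0)),
                  file.path(root, "subscriptions.tsv"))
  write_tsv_quiet(tibble::tibble(store = source_stores(),
                                 last_serial = c(0L, NA, 0L, NA),
                                 last_sync_date = NA_character_),
                  file.path(root, "sync_state.tsv"))
  file.create(file.path(root, "outbox.ndjson"))
  meta_handle(root, vocab_dir)
}

meta_handle <- function(root, vocab_dir = NULL) {
  structure(list(root = normalizePath(root), vocab_dir = vocab_dir),
            class = "tv_meta")
}

#' Open an existing metadata store
#'
#' @param root Store root created by [meta_create()].
#' @param vocab_dir Optional vocabulary override directory.
#' @return A `tv_meta` handle.
#' @export
meta_open <- function(root, vocab_dir = NULL) {
  if (!file.exists(file.path(root, "records.tsv"))) {
    vault_abort(paste0("no metadata store at ", root),
                class = "tcgavault_meta_error")
  }
  meta_handle(root, vocab_dir)
}

record_cols <- c("logical_id", "repo_version", "status", "barcode",
                 "access", "disease", "disease_name", "tss_code",
                 "tss_name", "sample_type_code", "sample_type_name",
                 "analyte_code", "analyte_name", "center_name",
                 "platform", "level", "datatype", "experiment_id",
                 "analysis_revision", "tcga_revision", "ref_genome",
                 "ref_genome_source", "algorithm_name",
                 "algorithm_version", "portion_name", "portion_number",
                 "extension", "archive_name", "source_serial", "md5",
                 "local_path", "original_path", "original_name", "uuid",
                 "ingest_timestamp")

empty_records <- function() {
  out <- tibble::as_tibble(setNames(
    lapply(record_cols, function(x) character(0)), record_cols))
  for (ic in c("repo_version", "analysis_revision", "tcga_revision",
               "portion_number", "source_serial"))
    out[[ic]] <- integer(0)
  out
}

read_records <- function(store) {
  r <- read_tsv_quiet(file.path(store$root, "records.tsv"))
  if (nrow(r) == 0) return(empty_records())
  for (ic in c("repo_version", "analysis_revision", "tcga_revision",
               "portion_number", "source_serial"))
    r[[ic]] <- as.integer(r[[ic]])
  r
}

write_records <- function(store, r) {
  write_tsv_quiet(r, file.path(store$root, "records.tsv"))
}

#' Insert or replace a file metadata record
#'
#' The record is keyed by (logical_id, repo_version).  Vocabulary codes
#' (disease study; tissue source site, sample type and portion analyte
#' from the barcode) are resolved into description fields at upsert
#' time; an unresolvable code errors with the table and code named.
#'
#' @param store A `tv_meta` handle.
#' @param rec Named list or one-row tibble of record fields (see
#'   package vignette); minimally `logical_id`, `repo_version`,
#'   `barcode`, `disease`, `status`.
#' @return The stored record (one-row tibble).
#' @export
upsert_record <- function(store, rec) {
  rec <- as.list(rec)
  vocab <- load_vocabularies(store$vocab_dir)
  b <- parse_barcode(rec$barcode)
  rec$disease_name <- resolve_code(vocab, "disease_study", rec$disease)
  rec$tss_code <- b$tss
  rec$tss_name <- resolve_code(vocab, "tissue_source_site", b$tss)
  rec$sample_type_code <- b$sample_type
  rec$sample_type_name <- if (!is.na(b$sample_type))
    resolve_code(vocab, "sample_type", b$sample_type) else NA_character_
  rec$analyte_code <- b$analyte
  rec$analyte_name <- if (!is.na(b$analyte))
    resolve_code(vocab, "portion_analyte", b$analyte) else NA_character_
  row <- empty_records()[0, ]
  for (nm in record_cols) {
    v <- rec[[nm]]
    row[1, nm] <- if (is.null(v)) NA else v
  }
  recs <- read_records(store)
  recs <- recs[!(recs$logical_id == row$logical_id &
                   recs$repo_version == row$repo_version), ]
  if (identical(row$status, "current")) {
    # A new current version supersedes older versions of the logical id.
    stale <- recs$logical_id == row$logical_id & recs$status == "current"
    recs$status[stale] <- "archived"
  }
  recs <- dplyr::bind_rows(recs, row)
  write_records(store, recs)
  row
}

# Mark every version of a logical id with a status (used for deletions).
set_record_status <- function(store, lid, status) {
  recs <- read_records(store)
  recs$status[recs$logical_id == lid & recs$status == "current"] <- status
  write_records(store, recs)
  invisible(NULL)
}

# Refresh the referenced archive serial for an unchanged file.
refresh_record_serial <- function(store, lid, serial, archive_name = NULL) {
  recs <- read_records(store)
  sel <- recs$logical_id == lid & recs$status == "current"
  recs$source_serial[sel] <- as.integer(serial)
  if (!is.null(archive_name)) recs$archive_name[sel] <- archive_name
  write_records(store, recs)
  invisible(NULL)
}

#' Query the manifest of current files
#'
#' Conjunction of the supplied filters over status-current records; an
#' absent filter matches everything.  Output is deterministic, ordered
#' by (logical_id, repo_version), and carries the local directory
#' locations.
#'
#' @param store A `tv_meta` handle.
#' @param disease,datatype,level,platform,center,access Optional
#'   equality filters.
#' @param barcode_prefix Optional barcode prefix filter.
#' @param date_from,date_to Optional ISO instants bounding the ingest
#'   timestamp (inclusive).
#' @return Tibble of matching records.
#' @export
query_manifest <- function(store, disease = NULL, datatype = NULL,
                           level = NULL, platform = NULL, center = NULL,
                           access = NULL, barcode_prefix = NULL,
                           date_from = NULL, date_to = NULL) {
  for (d in c(date_from, date_to)) {
    if (!is.null(d) && !is_iso_instant(d)) {
      vault_abort("malformed date range: use ISO instants",
                  class = "tcgavault_meta_error")
    }
  }
  if (!is.null(date_from) && !is.null(date_to) && date_from > date_to) {
    vault_abort("malformed date range: date_from after date_to",
                class = "tcgavault_meta_error")
  }
  r <- read_records(store)
  r <- r[r$status == "current", ]
  if (!is.null(disease)) r <- r[r$disease %in% disease, ]
  if (!is.null(datatype)) r <- r[r$datatype %in% datatype, ]
  if (!is.null(level)) r <- r[r$level %in% as.character(level), ]
  if (!is.null(platform)) r <- r[r$platform %in% platform, ]
  if (!is.null(center)) r <- r[r$center_name %in% center, ]
  if (!is.null(access)) r <- r[r$access %in% access, ]
  if (!is.null(barcode_prefix)) r <- r[startsWith(r$barcode, barcode_prefix), ]
  if (!is.null(date_from)) r <- r[r$ingest_timestamp >= date_from, ]
  if (!is.null(date_to)) r <- r[r$ingest_timestamp <= date_to, ]
  dplyr::arrange(r, .data$logical_id, .data$repo_version)
}

# Canonical JSON form of a subscription filter (sorted keys).
canonical_filter <- function(filter) {
  if (length(filter) == 0) return("{}")
  filter <- filter[order(names(filter))]
  as.character(jsonlite::toJSON(filter, auto_unbox = TRUE))
}

subscription_filter_keys <- c("disease", "datatype", "level", "platform",
                              "center", "access", "barcode_prefix")

# Subscription filters are stored URL-encoded so the JSON survives the
# tab-delimited table unmangled.
read_subscriptions <- function(store) {
  subs <- read_tsv_quiet(file.path(store$root, "subscriptions.tsv"))
  subs$filter <- vapply(subs$filter, uri_decode, character(1),
                        USE.NAMES = FALSE)
  subs
}

write_subscriptions <- function(store, subs) {
  subs$filter <- vapply(subs$filter, uri_encode, character(1),
                        USE.NAMES = FALSE)
  write_tsv_quiet(subs, file.path(store$root, "subscriptions.tsv"))
}

#' Subscribe to dataset changes
#'
#' Registers interest in repository changes matching a manifest-style
#' filter; matching changes from later sync runs are emitted as
#' notification events.  Idempotent per (subscriber, filter).
#'
#' @param store A `tv_meta` handle.
#' @param subscriber Subscriber id.
#' @param filter Named list of filter fields (subset of disease,
#'   datatype, level, platform, center, access, barcode_prefix); empty
#'   list subscribes to everything.
#' @return One-row subscription tibble.
#' @export
subscribe <- function(store, subscriber, filter = list()) {
  bad <- setdiff(names(filter), subscription_filter_keys)
  if (length(bad) > 0) {
    vault_abort(paste0("invalid subscription filter field(s): ",
                       paste(bad, collapse = ", ")),
                class = "tcgavault_meta_error")
  }
  subs <- read_subscriptions(store)
  fjson <- canonical_filter(filter)
  if (!any(subs$subscriber == subscriber & subs$filter == fjson)) {
    subs <- dplyr::bind_rows(subs, tibble::tibble(
      subscriber = subscriber, filter = fjson, created = iso_now()))
    write_subscriptions(store, subs)
  }
  subs[subs$subscriber == subscriber & subs$filter == fjson, ]
}

#' Remove a subscription
#'
#' @param store A `tv_meta` handle.
#' @param subscriber Subscriber id.
#' @param filter The filter it was registered with.
#' @return Invisibly, the number of subscriptions removed (0 or 1).
#' @export
unsubscribe <- function(store, subscriber, filter = list()) {
  subs <- read_subscriptions(store)
  fjson <- canonical_filter(filter)
  drop <- subs$subscriber == subscriber & subs$filter == fjson
  write_subscriptions(store, subs[!drop, ])
  invisible(sum(drop))
}

#' List subscriptions
#'
#' @param store A `tv_meta` handle.
#' @return Tibble of subscriptions.
#' @export
list_subscriptions <- function(store) {
  read_subscriptions(store)
}

filter_matches_change <- function(filter, change) {
  for (nm in names(filter)) {
    if (nm == "barcode_prefix") {
      if (!isTRUE(startsWith(change$barcode, filter[[nm]]))) return(FALSE)
    } else {
      if (!isTRUE(as.character(change[[nm]]) ==
                    as.character(filter[[nm]]))) return(FALSE)
    }
  }
  TRUE
}

#' Emit notification events for a sync run
#'
#' One event per (matching subscription x applied change).  Changes are
#' matched on their metadata attributes; metadata-only serial bumps
#' produce no events -- only content changes (new, modified or deleted
#' files) are "meaningful differences".
#'
#' @param store A `tv_meta` handle.
#' @param changes Tibble of applied changes (columns `action` in
#'   added/modified/deleted, `logical_id`, `repo_version`, plus the
#'   filterable metadata attributes).
#' @param run_id Sync run identifier.
#' @return Tibble of emitted events; also appended to the store outbox.
#' @export
emit_notifications <- function(store, changes, run_id) {
  subs <- list_subscriptions(store)
  changes <- changes[changes$action %in% c("added", "modified", "deleted"), ]
  events <- list()
  for (i in seq_len(nrow(subs))) {
    filt <- jsonlite::fromJSON(subs$filter[i])
    for (j in seq_len(nrow(changes))) {
      ch <- changes[j, ]
      if (filter_matches_change(filt, ch)) {
        events[[length(events) + 1]] <- tibble::tibble(
          subscriber = subs$subscriber[i], change_kind = ch$action,
          logical_id = ch$logical_id,
          repo_version = as.integer(ch$repo_version), run_id = run_id)
      }
    }
  }
  out <- if (length(events) > 0) dplyr::bind_rows(events) else
    tibble::tibble(subscriber = character(0), change_kind = character(0),
                   logical_id = character(0), repo_version = integer(0),
                   run_id = character(0))
  if (nrow(out) > 0) {
    lines <- vapply(seq_len(nrow(out)), function(k)
      as.character(jsonlite::toJSON(as.list(out[k, ]), auto_unbox = TRUE)),
      character(1))
    cat(lines, sep = "\n", file = file.path(store$root, "outbox.ndjson"),
        append = TRUE)
  }
  out
}

#' Read the notification outbox
#'
#' @param store A `tv_meta` handle.
#' @return Tibble of all emitted notification events.
#' @export
read_outbox <- function(store) {
  lines <- readLines(file.path(store$root, "outbox.ndjson"), warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(subscriber = character(0),
                          change_kind = character(0),
                          logical_id = character(0),
                          repo_version = integer(0), run_id = character(0)))
  }
  dplyr::bind_rows(lapply(lines, function(l)
    tibble::as_tibble(jsonlite::fromJSON(l))))
}

# ---- change messages ------------------------------------------------------

change_message_schema <- function() {
  jsonlite::fromJSON(system.file("schema", "change_message.json",
                                 package = "tcgavault"),
                     simplifyVector = FALSE)
}

#' Validate a change message against the shipped schema
#'
#' @param msg Named list.
#' @return `TRUE`, or an error naming the violation.
#' @export
validate_change_message <- function(msg) {
  sch <- change_message_schema()
  req <- unlist(sch$required)
  miss <- setdiff(req, names(msg))
  if (length(miss) > 0) {
    vault_abort(paste0("change message missing required field(s): ",
                       paste(miss, collapse = ", ")),
                class = "tcgavault_message_error")
  }
  extra <- setdiff(names(msg), names(sch$properties))
  if (length(extra) > 0) {
    vault_abort(paste0("change message has unknown field(s): ",
                       paste(extra, collapse = ", ")),
                class = "tcgavault_message_error")
  }
  if (!msg$action %in% c("added", "modified", "deleted")) {
    vault_abort(paste0("change message action invalid: ", msg$action),
                class = "tcgavault_message_error")
  }
  if (!is.numeric(msg$repo_version) || msg$repo_version < 1 ||
      msg$repo_version != as.integer(msg$repo_version)) {
    vault_abort("change message repo_version must be a positive integer",
                class = "tcgavault_message_error")
  }
  if (!grepl("^[0-9a-f]{32}$|^$", msg$md5 %||% "")) {
    vault_abort("change message md5 malformed",
                class = "tcgavault_message_error")
  }
  TRUE
}

#' Export JSON change messages for a sync run
#'
#' One message per added/modified/deleted file, carrying the logical
#' id, action, repository version, local path, checksum and run id --
#' the hand-off format for loading repository changes into downstream
#' systems.  Messages are schema-validated before writing.
#'
#' @param store A `tv_meta` handle.
#' @param changes Tibble of applied changes (as for
#'   [emit_notifications()], plus `local_path` and `md5`).
#' @param run_id Sync run identifier.
#' @return List of message objects; also written to
#'   `messages/changes_<run_id>.json` under the store root.
#' @export
export_change_messages <- function(store, changes, run_id) {
  changes <- changes[changes$action %in% c("added", "modified", "deleted"), ]
  msgs <- lapply(seq_len(nrow(changes)), function(i) {
    ch <- changes[i, ]
    msg <- list(logical_id = ch$logical_id, action = ch$action,
                repo_version = as.integer(ch$repo_version),
                local_path = ch$local_path %||% "",
                md5 = if (is.na(ch$md5)) "" else ch$md5,
                run_id = run_id,
                datatype = ch$datatype, barcode = ch$barcode,
                timestamp = ch$timestamp %||% iso_now())
    msg$local_path <- if (is.na(msg$local_path)) "" else msg$local_path
    validate_change_message(msg)
    msg
  })
  path <- file.path(store$root, "messages",
                    paste0("changes_", run_id, ".json"))
  jsonlite::write_json(msgs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  msgs
}

#' Parse a change-message document
#'
#' @param path Path to a document written by [export_change_messages()].
#' @return Tibble of messages (lossless round trip).
#' @export
parse_change_messages <- function(path) {
  msgs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (m in msgs) validate_change_message(m)
  dplyr::bind_rows(lapply(msgs, function(m)
    tibble::as_tibble(lapply(m, identity))))
}

# ---- triple export --------------------------------------------------------

nt_escape <- function(x) {
  x <- gsub("\\\\", "\\\\\\\\", x)
  x <- gsub("\"", "\\\\\"", x)
  gsub("\n", "\\\\n", x)
}

nt_unescape <- function(x) {
  x <- gsub("\\\\n", "\n", x)
  x <- gsub("\\\\\"", "\"", x)
  gsub("\\\\\\\\", "\\\\", x)
}

uri_encode <- function(x) utils::URLencode(x, reserved = TRUE)
uri_decode <- function(x) utils::URLdecode(x)

#' Export the metadata store as N-Triples
#'
#' Subject: the file identifier `(logical_id, repo_version)`;
#' predicate: the record field name; object: the field value as a
#' plain literal.  `NA` fields are omitted.
#'
#' @param store A `tv_meta` handle.
#' @param path Optional output file.
#' @return Character vector of N-Triples lines.
#' @export
export_triples <- function(store, path = NULL) {
  recs <- read_records(store)
  lines <- character(0)
  for (i in seq_len(nrow(recs))) {
    r <- recs[i, ]
    subj <- paste0("<urn:tcgavault:file:", uri_encode(r$logical_id), ":",
                   r$repo_version, ">")
    for (fld in setdiff(record_cols, c("logical_id", "repo_version"))) {
      v <- r[[fld]]
      if (is.na(v)) next
      lines <- c(lines, paste0(
        subj, " <urn:tcgavault:field:", fld, "> \"",
        nt_escape(as.character(v)), "\" ."))
    }
    lines <- c(lines, paste0(
      subj, " <urn:tcgavault:field:logical_id> \"",
      nt_escape(r$logical_id), "\" ."),
      paste0(subj, " <urn:tcgavault:field:repo_version> \"",
             r$repo_version, "\" ."))
  }
  if (!is.null(path)) writeLines(lines, path)
  lines
}

#' Import an N-Triples dump back into records
#'
#' Inverse of [export_triples()]; reconstructs one row per subject with
#' all-character columns.
#'
#' @param lines Character vector of N-Triples lines (or a file path).
#' @return Tibble of records.
#' @export
import_triples <- function(lines) {
  if (length(lines) == 1 && file.exists(lines)) lines <- readLines(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(tibble::tibble())
  pat <- "^(<[^>]+>) <urn:tcgavault:field:([^>]+)> \"(.*)\" \\.$"
  m <- regmatches(lines, regexec(pat, lines))
  bad <- which(vapply(m, length, integer(1)) != 4)
  if (length(bad) > 0) {
    vault_abort(paste0("malformed triple at line ", bad[1]),
                class = "tcgavault_meta_error")
  }
  subj <- vapply(m, `[`, character(1), 2)
  fld <- vapply(m, `[`, character(1), 3)
  val <- nt_unescape(vapply(m, `[`, character(1), 4))
  tb <- tibble::tibble(subject = subj, field = fld, value = val)
  out <- tidyr::pivot_wider(tb, names_from = "field",
                            values_from = "value")
  out <- dplyr::arrange(out, .data$logical_id,
                        as.integer(.data$repo_version))
  dplyr::select(out, -"subject")
}

# ---- sync cursor ----------------------------------------------------------

read_sync_state <- function(store) {
  s <- read_tsv_quiet(file.path(store$root, "sync_state.tsv"))
  s$last_serial <- as.integer(s$last_serial)
  s
}

write_sync_state <- function(store, s) {
  write_tsv_quiet(s, file.path(store$root, "sync_state.tsv"))
}
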