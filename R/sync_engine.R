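# Incremental synchronization: change detection per source strategy,
# checksum-verified fetch with retry, and ingestion into the versioned
# repository plus metadata store.
#
# Serial-numbered stores (dcc, level4store) are planned by comparing
# the latest source serial with the serial recorded locally and
# replaying the CHANGES_DCC.txt of every intervening release (last
# action per path wins).  Date-keyed stores (bamstore, msstore) are
# planned by comparing last-modified dates against the last sync date.
# Individual file failures are contained -- logged and reported, never
# aborting the run.

serial_stores <- function() c("dcc", "level4store")
date_stores <- function() c("bamstore", "msstore")

#' Sync configuration
#'
#' @param datatypes Datatype codes to sync (default: every registry
#'   datatype).
#' @param retry_limit Maximum fetch attempts per file (>= 1).
#' @param delete_policy How to handle files deleted upstream:
#'   `"archive"` retains the bytes under the archive area, `"delete"`
#'   removes them leaving a tombstone record.
#' @param remote_root,repo_root,store_root Optional roots used by the
#'   command-line interface.
#' @return A `tv_sync_config` list.
#' @export
sync_config <- function(datatypes = tcga_datatypes()$datatype,
                        retry_limit = 3L,
                        delete_policy = c("archive", "delete"),
                        remote_root = NULL, repo_root = NULL,
                        store_root = NULL) {
  delete_policy <- match.arg(delete_policy)
  assert_known_datatypes(datatypes)
  if (retry_limit < 1) {
    vault_abort("retry_limit must be >= 1", class = "tcgavault_sync_error")
  }
  structure(list(datatypes = datatypes, retry_limit = as.integer(retry_limit),
                 delete_policy = delete_policy, remote_root = remote_root,
                 repo_root = repo_root, store_root = store_root),
            class = "tv_sync_config")
}

#' Read a sync configuration file
#'
#' YAML with keys `datatypes`, `retry_limit`, `delete_policy`, and
#' optional `remote_root` / `repo_root` / `store_root`.
#'
#' @param path Path to the YAML file.
#' @return A `tv_sync_config` list.
#' @export
read_sync_config <- function(path) {
  y <- yaml::read_yaml(path)
  sync_config(
    datatypes = y$datatypes %||% tcga_datatypes()$datatype,
    retry_limit = y$retry_limit %||% 3L,
    delete_policy = y$delete_policy %||% "archive",
    remote_root = y$remote_root, repo_root = y$repo_root,
    store_root = y$store_root)
}

empty_changeset <- function() {
  tibble::tibble(store = character(0), action = character(0),
                 path = character(0), md5 = character(0),
                 serial = integer(0), date_modified = character(0))
}

#' Parse a CHANGES_DCC.txt change list
#'
#' One record per line, `<ACTION><TAB><relative path>` with ACTION one
#' of ADDED, MODIFIED, DELETED; comment lines start with `#`.
#'
#' @param text Character vector of lines, or a file path.
#' @return Changeset tibble with columns `action` (lowercase verb) and
#'   `path`.
#' @export
parse_changes_file <- function(text) {
  if (length(text) == 1 && file.exists(text)) text <- readLines(text)
  out <- tibble::tibble(action = character(0), path = character(0))
  for (i in seq_along(text)) {
    line <- text[i]
    if (!nzchar(line) || startsWith(line, "#")) next
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2 ||
        !parts[1] %in% c("ADDED", "MODIFIED", "DELETED")) {
      vault_abort(paste0("malformed CHANGES line ", i, ": '", line, "'"),
                  class = "tcgavault_sync_error")
    }
    out <- dplyr::bind_rows(out, tibble::tibble(
      action = tolower(parts[1]), path = parts[2]))
  }
  if (anyDuplicated(out$path)) {
    vault_abort("duplicate path under multiple verbs in CHANGES file",
                class = "tcgavault_sync_error")
  }
  out
}

# Local current records, with the source store each belongs to.
local_current_records <- function(store) {
  recs <- read_records(store)
  recs <- recs[recs$status == "current", ]
  reg <- tcga_datatypes()
  recs$source_store <- reg$store[match(recs$datatype, reg$datatype)]
  recs
}

#' Plan a sync against the remote
#'
#' Computes the changeset: which remote paths must be fetched
#' (added/modified), removed (deleted), or merely have their referenced
#' archive serial refreshed (`serial_bump`, for unchanged files under a
#' bumped serial).  An empty local repository plans everything as
#' added; a remote serial behind the local one is a remote regression
#' and errors.
#'
#' @param remote A `tv_remote` handle.
#' @param store A `tv_meta` handle (the local state).
#' @param config A [sync_config()].
#' @return Changeset tibble: `store`, `action` (added / modified /
#'   deleted / serial_bump), `path`, `md5`, `serial`, `date_modified`.
#' @export
plan_sync <- function(remote, store, config = sync_config()) {
  state <- read_sync_state(store)
  local <- local_current_records(store)
  meta <- remote_metadata(remote)
  meta <- meta[meta$datatype %in% config$datatypes, ]
  remote_serial_now <- remote_serial(remote)
  cs <- empty_changeset()

  for (st in serial_stores()) {
    listing <- meta[meta$store == st, ]
    local_serial <- state$last_serial[state$store == st]
    if (is.na(local_serial)) local_serial <- 0L
    if (remote_serial_now < local_serial) {
      vault_abort(paste0("remote serial regression for store ", st, ": ",
                         remote_serial_now, " < ", local_serial),
                  class = "tcgavault_sync_error")
    }
    if (remote_serial_now == local_serial) next
    loc <- local[!is.na(local$source_store) & local$source_store == st, ]
    if (local_serial == 0L) {
      changed <- tibble::tibble(action = rep("added", nrow(listing)),
                                path = listing$path)
    } else {
      # Union of CHANGES across intervening serials, last action wins.
      per <- list()
      for (k in seq(local_serial + 1L, remote_serial_now)) {
        cf <- changes_file_path(remote$root, st, k)
        if (file.exists(cf)) per[[length(per) + 1]] <- parse_changes_file(cf)
      }
      changed <- if (length(per) > 0) dplyr::bind_rows(per) else
        tibble::tibble(action = character(0), path = character(0))
      if (nrow(changed) > 0) {
        changed <- changed |>
          dplyr::mutate(.ord = dplyr::row_number()) |>
          dplyr::group_by(.data$path) |>
          dplyr::slice_max(.data$.ord, n = 1) |>
          dplyr::ungroup() |>
          dplyr::select(-".ord")
      }
    }
    # Restrict to selected datatypes (deleted paths resolve via local
    # records, everything else via the remote listing).
    for (i in seq_len(nrow(changed))) {
      act <- changed$action[i]; p <- changed$path[i]
      known <- p %in% loc$original_path
      if (act == "deleted") {
        if (known) {
          cs <- dplyr::bind_rows(cs, tibble::tibble(
            store = st, action = "deleted", path = p, md5 = NA_character_,
            serial = remote_serial_now, date_modified = NA_character_))
        }
      } else {
        li <- listing[listing$path == p, ]
        if (nrow(li) == 0) next  # changed then deleted, or filtered out
        cs <- dplyr::bind_rows(cs, tibble::tibble(
          store = st, action = if (known) "modified" else "added",
          path = p, md5 = li$md5, serial = li$serial,
          date_modified = li$date_modified))
      }
    }
    # Unchanged files under the bumped serial: metadata-only refresh.
    unchanged <- listing[!(listing$path %in% changed$path) &
                           listing$path %in% loc$original_path, ]
    if (nrow(unchanged) > 0) {
      cs <- dplyr::bind_rows(cs, tibble::tibble(
        store = st, action = "serial_bump", path = unchanged$path,
        md5 = unchanged$md5, serial = remote_serial_now,
        date_modified = unchanged$date_modified))
    }
  }

  for (st in date_stores()) {
    listing <- meta[meta$store == st, ]
    loc <- local[!is.na(local$source_store) & local$source_store == st, ]
    last_date <- state$last_sync_date[state$store == st]
    new <- if (is.na(last_date)) listing else
      listing[listing$date_modified > last_date, ]
    for (i in seq_len(nrow(new))) {
      known <- new$path[i] %in% loc$original_path
      cs <- dplyr::bind_rows(cs, tibble::tibble(
        store = st, action = if (known) "modified" else "added",
        path = new$path[i], md5 = new$md5[i], serial = new$serial[i],
        date_modified = new$date_modified[i]))
    }
    gone <- loc[!(loc$original_path %in% listing$path), ]
    if (nrow(gone) > 0) {
      cs <- dplyr::bind_rows(cs, tibble::tibble(
        store = st, action = "deleted", path = gone$original_path,
        md5 = NA_character_, serial = remote_serial_now,
        date_modified = NA_character_))
    }
  }
  cs
}

#' Fetch one remote file with checksum verification and retry
#'
#' Downloads into the staging area and verifies the MD5 against the
#' manifest value, repeating up to `retry_limit` attempts.  Every
#' attempt is appended to the download log; verification exhaustion
#' yields a failed result, not an exception.
#'
#' @param remote A `tv_remote` handle.
#' @param path Remote relative path.
#' @param expected_md5 Manifest checksum.
#' @param retry_limit Maximum attempts.
#' @param staging_dir Directory for staged bytes.
#' @param log_path Download log file (appended).
#' @return One-row tibble: `path`, `attempts`, `verified`,
#'   `staged_path`.
#' @export
fetch_file <- function(remote, path, expected_md5, retry_limit = 3L,
                       staging_dir = tempfile("staging"),
                       log_path = file.path(staging_dir, "download.log")) {
  dir.create(staging_dir, recursive = TRUE, showWarnings = FALSE)
  staged <- file.path(staging_dir, gsub("/", "__", path))
  attempts <- 0L
  verified <- FALSE
  while (attempts < retry_limit && !verified) {
    attempts <- attempts + 1L
    got <- tryCatch({
      remote_fetch(remote, path, staged)
      md5_file(staged)
    }, error = function(e) NA_character_)
    verified <- identical(got, expected_md5)
    cat(paste(iso_now(), path, attempts,
              if (verified) "ok" else "fail",
              got %||% "NA", sep = "\t"), "\n", sep = "",
        file = log_path, append = TRUE)
  }
  tibble::tibble(path = path, attempts = attempts, verified = verified,
                 staged_path = if (verified) staged else NA_character_)
}

datatype_access <- function(datatype) {
  ifelse(grepl("Protected|cgHub|Low_Pass", datatype), "controlled", "public")
}

# Build naming fields for one remote file's metadata row.
fields_for_remote_file <- function(m, repo_version = 1L) {
  ref_genome <- if (m$file_type %in% c("vcf", "maf", "bam")) "GRCh37"
                else NA_character_
  file_name_fields(
    barcode = m$barcode, access = datatype_access(m$datatype),
    disease = m$disease, center_name = m$center_name,
    platform = m$platform, level = m$level,
    experiment_id = paste0(m$datatype, "_", m$serial),
    analysis_revision = 1L, tcga_revision = 1L, ref_genome = ref_genome,
    portion_name = if (is.na(m$portion_name)) NA_character_ else m$portion_name,
    portion_number = 1L, repo_version = repo_version,
    extension = m$file_type, datatype = m$datatype)
}

# Harmonize a staged VCF in place: sorted records, standard header,
# optional per-sample split (fixture payloads are single-sample, so
# splitting never multiplies files here).
harmonize_staged_vcf <- function(staged, m) {
  lines <- readLines(staged, warn = FALSE)
  b <- parse_barcode(m$barcode)
  meta <- list(
    fileformat = "VCFv4.1",
    filedate = gsub("-", "", substr(m$date_modified, 1, 10)),
    center = m$center_name, platform = m$platform,
    "genome_ref.name" = "GRCh37",
    "genome_ref.url" = "http://www.ncbi.nlm.nih.gov/assembly/GRCh37",
    patient_id = truncate_barcode(m$barcode, 3),
    specimen_id = m$barcode)
  lines <- harmonize_header(lines, meta)
  sorted <- check_vcf_sorted(lines)
  if (sorted$severity != "ok") lines <- sort_records(lines)
  writeLines(lines, staged)
  invisible(staged)
}

new_run_id <- function(store) {
  n <- length(list.files(file.path(store$root, "messages"),
                         pattern = "^changes_.*\\.json$"))
  sprintf("run%04d", n + 1L)
}

#' Run a full synchronization
#'
#' Plan, fetch with verification and retry, validate, harmonize VCF
#' payloads, ingest into the versioned repository, upsert metadata,
#' apply the delete policy, refresh serials for unchanged files, then
#' emit notification events and JSON change messages.  Per-file
#' failures are contained and reported; they never abort the run.
#'
#' @param remote A `tv_remote` handle.
#' @param config A [sync_config()].
#' @param repo A `tv_repo` handle.
#' @param store A `tv_meta` handle.
#' @param now Optional ISO instant used as the ingest clock base.
#' @return A `tv_sync_report` object; see [tidy.tv_sync_report()].
#' @export
run_sync <- function(remote, config, repo, store, now = NULL) {
  started <- iso_now()
  run_id <- new_run_id(store)
  cs <- plan_sync(remote, store, config)
  log_path <- file.path(repo$root, "download.log")
  staging <- file.path(repo$root, "staging")
  outcomes <- list()
  applied <- list()
  downloads <- 0L
  clock <- now

  bump <- cs[cs$action == "serial_bump", ]
  for (i in seq_len(nrow(bump))) {
    loc <- local_current_records(store)
    lid <- loc$logical_id[loc$original_path == bump$path[i]]
    refresh_record_serial(store, lid, bump$serial[i])
    outcomes[[length(outcomes) + 1]] <- tibble::tibble(
      path = bump$path[i], action = "serial_bump", outcome = "refreshed",
      attempts = 0L, logical_id = lid, repo_version = NA_integer_)
  }

  fetches <- cs[cs$action %in% c("added", "modified"), ]
  for (i in seq_len(nrow(fetches))) {
    ch <- fetches[i, ]
    res <- tryCatch({
      m <- remote_metadata(remote, ch$path)
      fr <- fetch_file(remote, ch$path, ch$md5, config$retry_limit,
                       staging, log_path)
      downloads <- downloads + fr$attempts
      if (!fr$verified) {
        list(outcome = "failed_download", attempts = fr$attempts,
             lid = NA_character_, version = NA_integer_)
      } else {
        if (m$file_type == "vcf") harmonize_staged_vcf(fr$staged_path, m)
        fields <- fields_for_remote_file(m)
        use_grammar <- m$store == "dcc"
        stored_name <- if (m$store == "msstore")
          ms_file_name(m$original_name, substr(m$date_modified, 1, 10))
          else m$original_name
        prov <- list(archive_name = paste0(m$store, "_", m$datatype),
                     serial = ch$serial, original_name = m$original_name,
                     stored_name = stored_name,
                     original_path = ch$path, source_md5 = ch$md5)
        row <- ingest_file(repo, fr$staged_path, fields, prov,
                           use_grammar = use_grammar, now = clock)
        rec <- list(
          logical_id = row$logical_id, repo_version = row$repo_version,
          status = "current", barcode = fields$barcode,
          access = fields$access, disease = fields$disease,
          center_name = m$center_name, platform = m$platform,
          level = m$level, datatype = m$datatype,
          experiment_id = fields$experiment_id,
          analysis_revision = fields$analysis_revision,
          tcga_revision = fields$tcga_revision,
          ref_genome = fields$ref_genome,
          ref_genome_source = if (!is.na(fields$ref_genome))
            "mage-tab" else NA_character_,
          algorithm_name = if (m$file_type == "vcf") "muTect" else NA_character_,
          algorithm_version = if (m$file_type == "vcf") "1.1.4" else NA_character_,
          portion_name = fields$portion_name,
          portion_number = fields$portion_number,
          extension = fields$extension, archive_name = prov$archive_name,
          source_serial = as.integer(ch$serial), md5 = row$md5,
          local_path = row$rel_path, original_path = ch$path,
          original_name = m$original_name, uuid = m$uuid,
          ingest_timestamp = row$ingest_timestamp)
        upsert_record(store, rec)
        applied[[length(applied) + 1]] <- tibble::tibble(
          action = ch$action, logical_id = row$logical_id,
          repo_version = row$repo_version, local_path = row$rel_path,
          md5 = row$md5, datatype = m$datatype, disease = m$disease,
          barcode = m$barcode, level = m$level, platform = m$platform,
          center = m$center_name, access = fields$access,
          timestamp = row$ingest_timestamp)
        list(outcome = "ingested", attempts = fr$attempts,
             lid = row$logical_id, version = row$repo_version)
      }
    }, error = function(e) {
      list(outcome = paste0("error: ", conditionMessage(e)),
           attempts = NA_integer_, lid = NA_character_,
           version = NA_integer_)
    })
    outcomes[[length(outcomes) + 1]] <- tibble::tibble(
      path = ch$path, action = ch$action, outcome = res$outcome,
      attempts = res$attempts, logical_id = res$lid,
      repo_version = res$version)
  }

  dels <- cs[cs$action == "deleted", ]
  for (i in seq_len(nrow(dels))) {
    p <- dels$path[i]
    res <- tryCatch({
      loc <- local_current_records(store)
      hit <- loc[loc$original_path == p, ]
      row <- remove_file(repo, hit$logical_id, config$delete_policy,
                         now = clock)
      set_record_status(store, hit$logical_id, "deleted")
      applied[[length(applied) + 1]] <- tibble::tibble(
        action = "deleted", logical_id = hit$logical_id,
        repo_version = row$repo_version, local_path = NA_character_,
        md5 = NA_character_, datatype = hit$datatype,
        disease = hit$disease, barcode = hit$barcode, level = hit$level,
        platform = hit$platform, center = hit$center_name,
        access = hit$access, timestamp = row$removed_timestamp)
      list(outcome = "deleted", lid = hit$logical_id,
           version = row$repo_version)
    }, error = function(e) {
      list(outcome = paste0("error: ", conditionMessage(e)),
           lid = NA_character_, version = NA_integer_)
    })
    outcomes[[length(outcomes) + 1]] <- tibble::tibble(
      path = p, action = "deleted", outcome = res$outcome, attempts = 0L,
      logical_id = res$lid, repo_version = res$version)
  }

  # Advance the cursor.
  st <- read_sync_state(store)
  rs <- remote_serial(remote)
  st$last_serial[st$store %in% serial_stores()] <- rs
  meta_all <- remote_metadata(remote)
  for (ds in date_stores()) {
    dates <- meta_all$date_modified[meta_all$store == ds]
    if (length(dates) > 0) {
      st$last_sync_date[st$store == ds] <- max(dates)
    }
  }
  write_sync_state(store, st)

  applied_tbl <- if (length(applied) > 0) dplyr::bind_rows(applied) else
    tibble::tibble(action = character(0), logical_id = character(0),
                   repo_version = integer(0), local_path = character(0),
                   md5 = character(0), datatype = character(0),
                   disease = character(0), barcode = character(0),
                   level = character(0), platform = character(0),
                   center = character(0), access = character(0),
                   timestamp = character(0))
  events <- emit_notifications(store, applied_tbl, run_id)
  msgs <- export_change_messages(store, applied_tbl, run_id)

  outcomes_tbl <- if (length(outcomes) > 0) dplyr::bind_rows(outcomes) else
    tibble::tibble(path = character(0), action = character(0),
                   outcome = character(0), attempts = integer(0),
                   logical_id = character(0), repo_version = integer(0))
  structure(list(
    run_id = run_id, started = started, finished = iso_now(),
    outcomes = outcomes_tbl,
    failed = outcomes_tbl$path[outcomes_tbl$outcome == "failed_download"],
    downloads = downloads,
    n_planned = nrow(cs), n_messages = length(msgs),
    n_events = nrow(events), changes = applied_tbl),
    class = "tv_sync_report")
}

#' @export
print.tv_sync_report <- function(x, ...) {
  cat("<tcgavault sync report ", x$run_id, ">\n", sep = "")
  cat("  planned:   ", x$n_planned, " change(s)\n", sep = "")
  cat("  downloads: ", x$downloads, " fetch attempt(s)\n", sep = "")
  cat("  ingested:  ", sum(x$outcomes$outcome == "ingested"), "\n", sep = "")
  cat("  deleted:   ", sum(x$outcomes$outcome == "deleted"), "\n", sep = "")
  cat("  refreshed: ", sum(x$outcomes$outcome == "refreshed"), "\n", sep = "")
  cat("  failed:    ", length(x$failed), "\n", sep = "")
  cat("  messages:  ", x$n_messages, ", events: ", x$n_events, "\n", sep = "")
  invisible(x)
}
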