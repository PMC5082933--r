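# Deterministic mock of the four upstream datastores.
#
# The fixture emulates, on the local filesystem, the four source
# dialects the acquisition engine syncs from:
#
#   dcc         serial-numbered archive with per-release CHANGES_DCC.txt
#               and an MD5 manifest (VCF/MAF/tab-delimited/idat/svs
#               payloads with TCGA barcodes embedded),
#   bamstore    BAM stubs keyed by analysis UUID and last-modified date,
#   level4store serial-numbered level-4 bundle store,
#   msstore     dated mass-spectrometry file store.
#
# Every generated remote carries a ground-truth ledger of added /
# modified / deleted events; replaying the ledger reconstructs the
# current file set exactly, which makes the fixture the oracle for
# sync-convergence tests.  Identical (spec, seed) yields byte-identical
# trees: payload bytes come from a seeded RNG and timestamps from a
# synthetic monotonic clock advanced per release.

remote_state_file <- ".remote_state.json"
clock_epoch <- "2014-01-01T00:00:00Z"

# Per-datatype generation profile: platform, analysis center and
# barcode analyte letter used for fixture payloads.
datatype_profile <- function() {
  tibble::tribble(
    ~datatype,                  ~platform,                 ~center_code, ~center_name,       ~analyte,
    "WGS_(cgHub)",              "IlluminaHiSeq_WGS",       "10",         "baylor.edu",       "D",
    "WXS_(cgHub)",              "IlluminaHiSeq_WXS",       "10",         "baylor.edu",       "D",
    "Protected_Mutations",      "IlluminaGA_DNASeq",       "01",         "broad.mit.edu",    "D",
    "Protected_Mutations_MAF",  "IlluminaGA_DNASeq",       "01",         "broad.mit.edu",    "D",
    "Somatic_Mutations",        "IlluminaGA_DNASeq",       "01",         "broad.mit.edu",    "D",
    "RNA-Seq_(cgHub)",          "IlluminaHiSeq_RNASeq",    "07",         "unc.edu",          "R",
    "RNASeq",                   "IlluminaHiSeq_RNASeq",    "07",         "unc.edu",          "R",
    "RNASeqV2",                 "IlluminaHiSeq_RNASeqV2",  "07",         "unc.edu",          "R",
    "CNV_(CN_Array)",           "HG-CGH-244A",             "02",         "hms.harvard.edu",  "D",
    "CNV_(SNP_Array)",          "Genome_Wide_SNP_6",       "01",         "broad.mit.edu",    "D",
    "CNV_(Low_Pass_DNASeq)",    "IlluminaHiSeq_DNASeqC",   "02",         "hms.harvard.edu",  "D",
    "Expression_Exon",          "HuEx-1_0-st-v2",          "03",         "lbl.gov",          "R",
    "Expression_Gene",          "HT_HG-U133A",             "01",         "broad.mit.edu",    "R",
    "Expression_Protein",       "MDA_RPPA_Core",           "04",         "mskcc.org",        "T",
    "Bisulfite-Seq_(cgHub)",    "IlluminaHiSeq_Bisulfite", "09",         "bcgsc.ca",         "D",
    "DNA_Methylation",          "HumanMethylation450",     "05",         "genome.wustl.edu", "D",
    "miRNA-Seq_(cgHub)",        "IlluminaHiSeq_miRNASeq",  "13",         "bcgsc.ca_miRNA",   "R",
    "miRNASeq",                 "IlluminaHiSeq_miRNASeq",  "13",         "bcgsc.ca_miRNA",   "R",
    "Fragment_Analysis_Result", "ABI_3730xl",              "05",         "genome.wustl.edu", "D",
    "Diagnostic_images",        "Aperio_ScanScope",        "02",         "hms.harvard.edu",  "D",
    "Tissue_images",            "Aperio_ScanScope",        "02",         "hms.harvard.edu",  "D",
    "Clinical",                 "bio",                     "02",         "hms.harvard.edu",  "D"
  )
}

#' Specify a mock remote
#'
#' @param n_participants Number of synthetic participants (>= 0).
#' @param datatypes Datatype codes to populate (registry vocabulary,
#'   see [tcga_datatypes()]).  The default covers all four source
#'   stores and the VCF/MAF/matrix/idat/stub payload kinds.
#' @param files_per_sample Files generated per participant and datatype.
#' @param seed Integer seed; identical spec + seed gives byte-identical
#'   remotes.
#' @param disease Disease study abbreviation used throughout the remote.
#' @return A `tv_remote_spec` list.
#' @export
remote_spec <- function(n_participants = 4,
                        datatypes = c("Somatic_Mutations",
                                      "Protected_Mutations",
                                      "RNASeqV2", "DNA_Methylation",
                                      "Clinical", "WXS_(cgHub)",
                                      "CNV_(SNP_Array)",
                                      "Expression_Protein"),
                        files_per_sample = 1, seed = 1L,
                        disease = "BRCA") {
  stopifnot(n_participants >= 0, files_per_sample >= 1)
  assert_known_datatypes(datatypes)
  structure(list(n_participants = as.integer(n_participants),
                 datatypes = datatypes,
                 files_per_sample = as.integer(files_per_sample),
                 seed = as.integer(seed), disease = disease),
            class = "tv_remote_spec")
}

#' Specify one release's mutations
#'
#' Counts of files to add, modify and delete at the next release.
#' Modify/delete targets are drawn at random (under `seed`) from the
#' currently existing files; additions create files for fresh
#' participants.
#'
#' @param add,modify,delete Non-negative counts.
#' @param datatypes Optional datatype codes to restrict the mutation
#'   to; defaults to all datatypes present in the remote.
#' @param seed Integer seed for target selection and new payloads.
#' @return A `tv_mutation_spec` list.
#' @export
mutation_spec <- function(add = 0, modify = 0, delete = 0,
                          datatypes = NULL, seed = 1L) {
  stopifnot(add >= 0, modify >= 0, delete >= 0)
  if (!is.null(datatypes)) assert_known_datatypes(datatypes)
  structure(list(add = as.integer(add), modify = as.integer(modify),
                 delete = as.integer(delete), datatypes = datatypes,
                 seed = as.integer(seed)),
            class = "tv_mutation_spec")
}

empty_files_tbl <- function() {
  tibble::tibble(path = character(0), store = character(0),
                 datatype = character(0), level = character(0),
                 file_type = character(0), barcode = character(0),
                 uuid = character(0), center_name = character(0),
                 platform = character(0), disease = character(0),
                 portion_name = character(0), original_name = character(0),
                 serial = integer(0), date_modified = character(0),
                 md5 = character(0))
}

empty_ledger_tbl <- function() {
  tibble::tibble(serial = integer(0), action = character(0),
                 path = character(0), md5 = character(0),
                 timestamp = character(0))
}

# ---- state persistence ----------------------------------------------------

as_state_tbl <- function(x, empty) {
  if (is.null(x) || length(x) == 0 || NROW(x) == 0) return(empty)
  out <- tibble::as_tibble(x)
  for (nm in names(empty)) {
    v <- if (nm %in% names(out)) out[[nm]] else NA  # all-NA columns drop out of JSON
    out[[nm]] <- if (is.integer(empty[[nm]])) as.integer(v)
                 else as.character(v)
  }
  out[names(empty)]
}

read_remote_state <- function(root) {
  path <- file.path(root, remote_state_file)
  if (!file.exists(path)) {
    vault_abort(paste0("no remote state at ", root),
                class = "tcgavault_remote_error")
  }
  s <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  s$files <- as_state_tbl(s$files, empty_files_tbl())
  s$ledger <- as_state_tbl(s$ledger, empty_ledger_tbl())
  s$faults <- as_state_tbl(s$faults,
                           tibble::tibble(path = character(0),
                                          remaining = integer(0)))
  s
}

write_remote_state <- function(root, state) {
  jsonlite::write_json(state, file.path(root, remote_state_file),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
}

# ---- payload writers ------------------------------------------------------

random_id <- function(n = 8) {
  paste(sample(c(0:9, letters[1:6]), n, replace = TRUE), collapse = "")
}

payload_vcf <- function(barcode, center_name, platform, filedate) {
  n <- sample(4:9, 1)
  chrom <- sample(c("1", "2", "10", "X"), n, replace = TRUE)
  chrom <- chrom[order(match(chrom, unique(chrom)))]
  pos <- sample(1:500000, n)
  bases <- c("A", "C", "G", "T")
  recs <- paste(chrom, pos, ".",
                sample(bases, n, TRUE), sample(bases, n, TRUE),
                ".", "PASS", "NS=1", "GT", "0/1", sep = "\t")
  c(paste0("##fileformat=VCFv4.1"),
    paste0("##filedate=", gsub("-", "", substr(filedate, 1, 10))),
    paste0("##center=", center_name),
    paste0("##reference=GRCh37"),
    "##INFO=<ID=NS,Number=1,Type=Integer,Description=\"Number of Samples\">",
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", barcode, sep = "\t"),
    recs)
}

payload_maf <- function(barcode) {
  n <- sample(3:7, 1)
  genes <- sample(c("TP53", "PIK3CA", "GATA3", "MAP3K1", "BRCA1", "PTEN"), n,
                  replace = TRUE)
  c("Hugo_Symbol\tChromosome\tStart_position\tVariant_Classification\tTumor_Sample_Barcode",
    paste(genes, sample(1:22, n, TRUE), sample(1:10^6, n),
          sample(c("Missense_Mutation", "Silent", "Nonsense_Mutation"), n, TRUE),
          barcode, sep = "\t"))
}

payload_matrix <- function(barcode) {
  n <- sample(4:8, 1)
  genes <- paste0("GENE", sample(1000:9999, n))
  c(paste0("gene_id\t", barcode),
    paste(genes, round(stats::runif(n, 0, 5000), 3), sep = "\t"))
}

payload_blob <- function() {
  # Opaque stub standing in for BAM/idat/svs bytes; content is never
  # interpreted, only checksummed.
  paste(sample(c(0:9, letters[1:6]), 64, replace = TRUE), collapse = "")
}

write_payload <- function(abs_path, file_type, barcode, center_name,
                          platform, filedate) {
  dir.create(dirname(abs_path), recursive = TRUE, showWarnings = FALSE)
  lines <- switch(file_type,
    vcf = payload_vcf(barcode, center_name, platform, filedate),
    maf = payload_maf(barcode),
    txt = payload_matrix(barcode),
    tsv = payload_matrix(barcode),
    payload_blob())
  writeLines(lines, abs_path)
}

# ---- generation -----------------------------------------------------------

participant_barcode_parts <- function(i) {
  tss_codes <- c("A1", "A2", "A7", "AR", "BH", "E2")
  list(tss = tss_codes[(i - 1) %% length(tss_codes) + 1],
       participant = sprintf("A%03d", i))
}

# One file's metadata + payload for participant index i, datatype dt,
# file index j.  Mutates nothing; returns the files-table row.
make_file <- function(root, i, dt, j, disease, clock) {
  prof <- datatype_profile()
  p <- prof[prof$datatype == dt, ]
  reg <- tcga_datatypes()
  r <- reg[reg$datatype == dt, ]
  bp <- participant_barcode_parts(i)
  barcode <- paste0("TCGA-", bp$tss, "-", bp$participant, "-01A-11",
                    p$analyte, "-A", sprintf("%03d", 100 + j), "-",
                    p$center_code)
  portion <- if (dt == "DNA_Methylation") {
    if (j %% 2 == 1) "red" else "grn"
  } else NA_character_
  uuid <- paste0("uuid-", random_id(12))
  original_name <- switch(r$store,
    dcc = paste0(p$center_name, "_", disease, ".", p$platform, ".Level_",
                 r$level, ".", barcode,
                 if (!is.na(portion)) paste0(".", portion) else "",
                 ".", j, ".", r$file_type),
    bamstore = paste0(uuid, ".bam"),
    level4store = paste0(dt, ".", disease, ".", barcode, ".gistic.", j,
                         ".", r$file_type),
    msstore = paste0(barcode, "_run", j, ".tsv"))
  rel_path <- switch(r$store,
    dcc = file.path("dcc", dt, original_name),
    bamstore = file.path("bamstore", uuid, original_name),
    level4store = file.path("level4store", dt, original_name),
    msstore = file.path("msstore", original_name))
  write_payload(file.path(root, rel_path), r$file_type, barcode,
                p$center_name, p$platform, clock)
  tibble::tibble(path = rel_path, store = r$store, datatype = dt,
                 level = r$level, file_type = r$file_type, barcode = barcode,
                 uuid = uuid, center_name = p$center_name,
                 platform = p$platform, disease = disease,
                 portion_name = portion, original_name = original_name,
                 serial = NA_integer_, date_modified = clock,
                 md5 = md5_file(file.path(root, rel_path)))
}

write_md5_manifest <- function(root, files) {
  # Standard md5sum dialect: "<hex>  <path>", one line per file.
  f <- files[order(files$path), ]
  writeLines(paste0(f$md5, "  ", f$path), file.path(root, "MD5SUMS"))
}

changes_file_path <- function(root, store, serial = NULL) {
  if (is.null(serial)) file.path(root, store, "CHANGES_DCC.txt")
  else file.path(root, store, paste0("CHANGES_DCC.", serial, ".txt"))
}

write_changes_files <- function(root, serial, events) {
  # One CHANGES_DCC.txt per serial-numbered store, plus an archived
  # per-serial copy so catch-up over skipped releases can replay them.
  for (st in c("dcc", "level4store")) {
    ev <- events[startsWith(events$path, paste0(st, "/")), ]
    lines <- c(paste0("# serial=", serial),
               if (nrow(ev) > 0)
                 paste0(toupper(ev$action), "\t", ev$path))
    dir.create(file.path(root, st), recursive = TRUE, showWarnings = FALSE)
    writeLines(lines, changes_file_path(root, st))
    writeLines(lines, changes_file_path(root, st, serial))
  }
}

#' Generate a mock remote archive
#'
#' Materializes the four-store remote tree on disk at serial 1: small
#' but well-formed VCF/MAF/tab-delimited payloads with barcodes
#' embedded, opaque stubs for BAM/idat/svs, an MD5 manifest in md5sum
#' format, and a ground-truth ledger holding one `added` event per
#' file.  No CHANGES_DCC.txt exists for the first release.
#'
#' @param spec A [remote_spec()].
#' @param root Directory to create the remote under.
#' @return A `tv_remote` handle.
#' @export
generate_remote <- function(spec, root) {
  stopifnot(inherits(spec, "tv_remote_spec"))
  assert_known_datatypes(spec$datatypes)
  if (dir.exists(root) && file.exists(file.path(root, remote_state_file))) {
    vault_abort(paste0("remote already exists at ", root),
                class = "tcgavault_remote_error")
  }
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  for (st in source_stores())
    dir.create(file.path(root, st), showWarnings = FALSE)
  clock <- clock_epoch
  files <- empty_files_tbl()
  ledger <- empty_ledger_tbl()
  with_seed(spec$seed, {
    if (spec$n_participants > 0) {
      for (i in seq_len(spec$n_participants)) {
        for (dt in spec$datatypes) {
          for (j in seq_len(spec$files_per_sample)) {
            clock <- iso_plus(clock, 7)
            row <- make_file(root, i, dt, j, spec$disease, clock)
            row$serial <- 1L
            files <- dplyr::bind_rows(files, row)
            ledger <- dplyr::bind_rows(ledger, tibble::tibble(
              serial = 1L, action = "added", path = row$path,
              md5 = row$md5, timestamp = clock))
          }
        }
      }
    }
  })
  write_md5_manifest(root, files)
  state <- list(spec = unclass(spec), release = 1L, clock = clock,
                next_participant = spec$n_participants + 1L,
                files = files, ledger = ledger,
                faults = tibble::tibble(path = character(0),
                                        remaining = integer(0)))
  write_remote_state(root, state)
  remote_handle(root)
}

remote_handle <- function(root) {
  structure(list(root = normalizePath(root)), class = "tv_remote")
}

#' Open an existing mock remote
#'
#' @param root Directory previously populated by [generate_remote()].
#' @return A `tv_remote` handle.
#' @export
open_remote <- function(root) {
  read_remote_state(root)  # validates
  remote_handle(root)
}

#' Advance the remote by one release
#'
#' Applies a [mutation_spec()]: additions create files for fresh
#' participants, modifications rewrite an existing payload in place,
#' deletions remove the payload.  The release serial increments, the
#' serial-numbered stores get a CHANGES_DCC.txt listing exactly the
#' mutated paths under their action verbs, and the manifest and ledger
#' are updated.
#'
#' @param remote A `tv_remote` handle.
#' @param mut A [mutation_spec()].
#' @return The handle, invisibly.
#' @export
advance_release <- function(remote, mut) {
  stopifnot(inherits(remote, "tv_remote"), inherits(mut, "tv_mutation_spec"))
  root <- remote$root
  state <- read_remote_state(root)
  serial <- state$release + 1L
  clock <- state$clock
  clock <- iso_plus(clock, 86400)  # one synthetic day per release
  dts <- mut$datatypes %||% state$spec$datatypes
  pool <- state$files[state$files$datatype %in% dts, ]
  if (mut$modify + mut$delete > nrow(pool)) {
    vault_abort(paste0("unsatisfiable mutation: modify+delete = ",
                       mut$modify + mut$delete, " but only ", nrow(pool),
                       " matching files exist"),
                class = "tcgavault_remote_error")
  }
  events <- empty_ledger_tbl()
  with_seed(derive_seed(mut$seed, paste0("release", serial)), {
    targets <- if (nrow(pool) > 0)
      sample(pool$path, mut$modify + mut$delete) else character(0)
    mod_paths <- head(targets, mut$modify)
    del_paths <- tail(targets, mut$delete)
    for (p in mod_paths) {
      clock <- iso_plus(clock, 7)
      row <- state$files[state$files$path == p, ]
      write_payload(file.path(root, p), row$file_type, row$barcode,
                    row$center_name, row$platform, clock)
      new_md5 <- md5_file(file.path(root, p))
      state$files$md5[state$files$path == p] <- new_md5
      state$files$serial[state$files$path == p] <- serial
      state$files$date_modified[state$files$path == p] <- clock
      events <- dplyr::bind_rows(events, tibble::tibble(
        serial = serial, action = "modified", path = p, md5 = new_md5,
        timestamp = clock))
    }
    for (p in del_paths) {
      clock <- iso_plus(clock, 7)
      unlink(file.path(root, p))
      state$files <- state$files[state$files$path != p, ]
      events <- dplyr::bind_rows(events, tibble::tibble(
        serial = serial, action = "deleted", path = p, md5 = NA_character_,
        timestamp = clock))
    }
    if (mut$add > 0) {
      add_dts <- sample(dts, mut$add, replace = TRUE)
      for (k in seq_len(mut$add)) {
        clock <- iso_plus(clock, 7)
        i <- state$next_participant
        state$next_participant <- i + 1L
        row <- make_file(root, i, add_dts[k], 1L, state$spec$disease, clock)
        row$serial <- serial
        state$files <- dplyr::bind_rows(state$files, row)
        events <- dplyr::bind_rows(events, tibble::tibble(
          serial = serial, action = "added", path = row$path, md5 = row$md5,
          timestamp = clock))
      }
    }
  })
  # Serial bumps even when no paths changed; unchanged files keep their
  # original serial so metadata-only refreshes are detectable.
  state$release <- serial
  state$clock <- clock
  state$ledger <- dplyr::bind_rows(state$ledger, events)
  write_changes_files(root, serial, events)
  write_md5_manifest(root, state$files)
  write_remote_state(root, state)
  invisible(remote)
}

#' Inject transient fetch faults
#'
#' The next `n_failures` fetches of `path` return content whose
#' checksum mismatches the manifest; subsequent fetches return correct
#' content.  Exercises the download retry contract.
#'
#' @param remote A `tv_remote` handle.
#' @param path Relative path existing in the remote.
#' @param n_failures Number of corrupted fetches to serve.
#' @return The handle, invisibly.
#' @export
inject_fault <- function(remote, path, n_failures) {
  state <- read_remote_state(remote$root)
  if (!path %in% state$files$path) {
    vault_abort(paste0("unknown remote path: ", path),
                class = "tcgavault_remote_error")
  }
  state$faults <- state$faults[state$faults$path != path, ]
  if (n_failures > 0) {
    state$faults <- dplyr::bind_rows(state$faults, tibble::tibble(
      path = path, remaining = as.integer(n_failures)))
  }
  write_remote_state(remote$root, state)
  invisible(remote)
}

#' List a remote store
#'
#' @param remote A `tv_remote` handle.
#' @param store_name One of `"dcc"`, `"bamstore"`, `"level4store"`,
#'   `"msstore"`.
#' @return Tibble with columns `path`, `serial` (serial-numbered
#'   stores), `date_modified`, `md5`.
#' @export
list_remote <- function(remote, store_name) {
  if (!store_name %in% source_stores()) {
    vault_abort(paste0("unknown store: ", store_name),
                class = "tcgavault_remote_error")
  }
  state <- read_remote_state(remote$root)
  f <- state$files[state$files$store == store_name, ]
  tibble::tibble(path = f$path, serial = f$serial,
                 date_modified = f$date_modified, md5 = f$md5)
}

#' Full per-file metadata of the remote
#'
#' The attribute table the sync engine scrapes for each path: barcode,
#' UUID, center, platform, disease, level, portion and checksum.
#'
#' @param remote A `tv_remote` handle.
#' @param paths Optional path subset.
#' @return Tibble, one row per remote file.
#' @export
remote_metadata <- function(remote, paths = NULL) {
  state <- read_remote_state(remote$root)
  f <- state$files
  if (!is.null(paths)) f <- f[f$path %in% paths, ]
  f
}

#' Ground-truth event ledger of the remote
#'
#' @param remote A `tv_remote` handle.
#' @return Tibble of ledger events (serial, action, path, md5,
#'   timestamp) in emission order.
#' @export
remote_ledger <- function(remote) {
  read_remote_state(remote$root)$ledger
}

#' Current release serial of the remote
#'
#' @param remote A `tv_remote` handle.
#' @return Integer serial.
#' @export
remote_serial <- function(remote) {
  read_remote_state(remote$root)$release
}

#' Replay the ledger into the current file set
#'
#' Applies added/modified/deleted events in order; the result is the
#' ground-truth current (path, md5) set of the remote.
#'
#' @param ledger A ledger tibble, as from [remote_ledger()].
#' @return Tibble with columns `path`, `md5`, sorted by path.
#' @export
ledger_replay <- function(ledger) {
  cur <- list()
  for (i in seq_len(nrow(ledger))) {
    ev <- ledger[i, ]
    if (ev$action == "deleted") cur[[ev$path]] <- NULL
    else cur[[ev$path]] <- ev$md5
  }
  if (length(cur) == 0)
    return(tibble::tibble(path = character(0), md5 = character(0)))
  tibble::tibble(path = names(cur),
                 md5 = unlist(cur, use.names = FALSE)) |>
    dplyr::arrange(.data$path)
}

# Fetch one file's bytes into dest, honouring injected faults: while a
# fault is pending the served bytes are corrupted and the fault counter
# decremented.
remote_fetch <- function(remote, path, dest) {
  state <- read_remote_state(remote$root)
  if (!path %in% state$files$path) {
    vault_abort(paste0("unknown remote path: ", path),
                class = "tcgavault_remote_error")
  }
  dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
  idx <- which(state$faults$path == path)
  if (length(idx) == 1 && state$faults$remaining[idx] > 0) {
    state$faults$remaining[idx] <- state$faults$remaining[idx] - 1L
    if (state$faults$remaining[idx] == 0L)
      state$faults <- state$faults[-idx, ]
    write_remote_state(remote$root, state)
    writeLines(c("CORRUPTED TRANSFER", readLines(file.path(remote$root, path),
                                                 warn = FALSE)), dest)
  } else {
    file.copy(file.path(remote$root, path), dest, overwrite = TRUE)
  }
  invisible(dest)
}
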