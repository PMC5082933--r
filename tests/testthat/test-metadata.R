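# Metadata store: vocabulary resolution, manifest queries vs a linear
# scan, subscriptions and notification events, change messages,
# N-Triples round trip.

demo_record <- function(i = 1, disease = "BRCA", datatype = "Somatic_Mutations",
                        level = "2", version = 1L, status = "current") {
  bc <- sprintf("TCGA-A1-A%03d-01A-11D-A101-01", i)
  list(logical_id = paste(datatype, bc, level, "-", 1, sep = "|"),
       repo_version = version, status = status, barcode = bc,
       access = "public", disease = disease, center_name = "broad.mit.edu",
       platform = "IlluminaGA_DNASeq", level = level, datatype = datatype,
       experiment_id = paste0(datatype, "_1"), analysis_revision = 1L,
       tcga_revision = 1L, ref_genome = "GRCh37",
       portion_number = 1L, extension = "maf",
       archive_name = "dcc_x", source_serial = 1L,
       md5 = paste0(strrep(sprintf("%02d", i %% 100), 16)),
       local_path = paste0("current/f", i), original_path = paste0("dcc/f", i),
       original_name = paste0("f", i, ".maf"), uuid = paste0("uuid-", i),
       ingest_timestamp = sprintf("2015-01-%02dT00:00:00Z", (i %% 27) + 1))
}

local_store <- function(env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  meta_create(file.path(dir, "store"))
}

test_that("upsert resolves vocabulary codes into description fields", {
  store <- local_store()
  rec <- upsert_record(store, demo_record(1))
  expect_equal(rec$disease_name, "Breast invasive carcinoma")
  expect_equal(rec$tss_name, "Breast Cancer Source Site 1")
  expect_equal(rec$sample_type_name, "Primary Solid Tumor")
  expect_equal(rec$analyte_name, "DNA")
  # retrievable by key; double upsert keeps one record
  upsert_record(store, demo_record(1))
  man <- query_manifest(store)
  expect_equal(nrow(man), 1)
})

test_that("unknown vocabulary codes error naming the table and code", {
  store <- local_store()
  bad <- demo_record(1)
  bad$disease <- "ZZZ"
  expect_error(upsert_record(store, bad), "disease_study.*ZZZ|ZZZ.*disease_study")
})

test_that("manifest queries equal a brute-force linear scan on random stores", {
  store <- local_store()
  set.seed(31)
  diseases <- c("BRCA", "GBM", "OV")
  datatypes <- c("Somatic_Mutations", "RNASeqV2", "Clinical")
  for (i in 1:40) {
    upsert_record(store, demo_record(
      i, disease = sample(diseases, 1), datatype = sample(datatypes, 1),
      level = as.character(sample(2:3, 1)),
      status = sample(c("current", "deleted"), 1, prob = c(.8, .2))))
  }
  dump <- tcgavault:::read_records(store)
  for (k in 1:25) {
    q <- list(
      disease = if (runif(1) < .5) sample(diseases, 1),
      datatype = if (runif(1) < .5) sample(datatypes, 1),
      level = if (runif(1) < .3) sample(2:3, 1),
      barcode_prefix = if (runif(1) < .3) "TCGA-A1")
    got <- query_manifest(store, disease = q$disease, datatype = q$datatype,
                          level = q$level, barcode_prefix = q$barcode_prefix)
    keep <- dump$status == "current"
    if (!is.null(q$disease)) keep <- keep & dump$disease == q$disease
    if (!is.null(q$datatype)) keep <- keep & dump$datatype == q$datatype
    if (!is.null(q$level)) keep <- keep & dump$level == as.character(q$level)
    if (!is.null(q$barcode_prefix))
      keep <- keep & startsWith(dump$barcode, q$barcode_prefix)
    expect_setequal(got$logical_id, dump$logical_id[keep])
    # deterministic order
    expect_equal(got$logical_id, sort(got$logical_id))
  }
  # a filter matching nothing is an empty manifest, not an error
  expect_equal(nrow(query_manifest(store, disease = "LUAD")), 0)
  expect_error(query_manifest(store, date_from = "yesterday"), "malformed")
  expect_error(query_manifest(store, date_from = "2015-02-01T00:00:00Z",
                              date_to = "2015-01-01T00:00:00Z"), "malformed")
})

test_that("subscriptions are idempotent, removable, and filter-validated", {
  store <- local_store()
  subscribe(store, "alice", list(disease = "BRCA"))
  subscribe(store, "alice", list(disease = "BRCA"))
  expect_equal(nrow(list_subscriptions(store)), 1)
  subscribe(store, "alice", list())  # everything
  expect_equal(nrow(list_subscriptions(store)), 2)
  expect_equal(unsubscribe(store, "alice", list(disease = "BRCA")), 1)
  expect_equal(nrow(list_subscriptions(store)), 1)
  expect_error(subscribe(store, "bob", list(colour = "red")), "colour")
})

changes_tbl <- function() {
  tibble::tibble(
    action = c("added", "modified", "deleted", "serial_bump"),
    logical_id = paste0("lid", 1:4), repo_version = c(1L, 2L, 1L, 1L),
    local_path = c("p1", "p2", NA, "p4"),
    md5 = c(strrep("a", 32), strrep("b", 32), NA, strrep("d", 32)),
    datatype = c("Somatic_Mutations", "RNASeqV2", "Somatic_Mutations",
                 "Clinical"),
    disease = c("BRCA", "BRCA", "GBM", "BRCA"),
    barcode = sprintf("TCGA-A1-A%03d-01A", 1:4),
    level = c("2", "3", "2", "2"),
    platform = "x", center = "c", access = "public",
    timestamp = "2015-01-01T00:00:00Z")
}

test_that("notification events are the matching subscription-change pairs", {
  store <- local_store()
  expect_equal(nrow(emit_notifications(store, changes_tbl(), "run1")), 0)
  subscribe(store, "alice", list(disease = "BRCA"))
  subscribe(store, "bob", list())
  ev <- emit_notifications(store, changes_tbl(), "run2")
  # alice matches the 2 BRCA content changes; bob matches all 3;
  # the serial bump is metadata-only and produces no events
  expect_equal(sum(ev$subscriber == "alice"), 2)
  expect_equal(sum(ev$subscriber == "bob"), 3)
  expect_false("lid4" %in% ev$logical_id)
  # conservation: |events| equals the sum over subscriptions of matches
  expect_equal(nrow(ev), 5)
  expect_false(any(duplicated(ev)))
  # outbox is append-only and replayable
  box <- read_outbox(store)
  expect_equal(nrow(box), 5)
  expect_setequal(paste(box$subscriber, box$logical_id),
                  paste(ev$subscriber, ev$logical_id))
})

test_that("change messages cover exactly the content changes and round-trip", {
  store <- local_store()
  msgs <- export_change_messages(store, changes_tbl(), "run9")
  expect_length(msgs, 3)  # serial bump excluded
  path <- file.path(store$root, "messages", "changes_run9.json")
  expect_true(file.exists(path))
  back <- parse_change_messages(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$logical_id, c("lid1", "lid2", "lid3"))
  expect_equal(back$action, c("added", "modified", "deleted"))
  expect_equal(back$repo_version, c(1L, 2L, 1L))
  # empty report: empty message list
  empty <- export_change_messages(store, changes_tbl()[0, ], "run10")
  expect_length(empty, 0)
})

test_that("message schema violations are rejected", {
  expect_error(validate_change_message(list(logical_id = "x")),
               "required")
  expect_error(validate_change_message(
    list(logical_id = "x", action = "renamed", repo_version = 1L,
         local_path = "p", md5 = strrep("a", 32), run_id = "r")),
    "action")
  expect_error(validate_change_message(
    list(logical_id = "x", action = "added", repo_version = 0L,
         local_path = "p", md5 = strrep("a", 32), run_id = "r")),
    "repo_version")
  expect_error(validate_change_message(
    list(logical_id = "x", action = "added", repo_version = 1L,
         local_path = "p", md5 = "zz", run_id = "r", surprise = 1)),
    "surprise")
})

test_that("triple export is empty on an empty store and counts fields", {
  store <- local_store()
  expect_length(export_triples(store), 0)
  upsert_record(store, demo_record(1))
  lines <- export_triples(store)
  rec <- tcgavault:::read_records(store)
  populated <- sum(!is.na(unlist(rec[1, ])))
  expect_equal(length(lines), populated)
})

test_that("triple export/import reproduces the records and manifest", {
  store <- local_store()
  set.seed(55)
  for (i in 1:12) {
    upsert_record(store, demo_record(
      i, disease = sample(c("BRCA", "OV"), 1),
      datatype = sample(c("Somatic_Mutations", "Clinical"), 1)))
  }
  lines <- export_triples(store)
  back <- import_triples(lines)
  recs <- tcgavault:::read_records(store)
  recs <- dplyr::arrange(recs, logical_id, repo_version)
  expect_equal(nrow(back), nrow(recs))
  for (col in names(back)) {
    expect_equal(back[[col]], as.character(recs[[col]]),
                 info = col, ignore_attr = TRUE)
  }
  # re-import answers manifest queries identically
  cur <- back[back$status == "current", ]
  expect_setequal(cur$logical_id[cur$disease == "BRCA"],
                  query_manifest(store, disease = "BRCA")$logical_id)
})
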