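# Versioned repository: ingest/versioning semantics, removal policies,
# snapshots against a brute-force replay oracle.

rig_fields <- function(barcode = "TCGA-A1-A001-01A-11D-A101-01",
                       datatype = "Somatic_Mutations", serial = 1) {
  file_name_fields(
    barcode = barcode, access = "public", disease = "BRCA",
    center_name = "broad.mit.edu", platform = "IlluminaGA_DNASeq",
    level = "2", experiment_id = paste0(datatype, "_", serial),
    extension = "maf", datatype = datatype)
}

stage <- function(dir, content) {
  p <- file.path(dir, paste0("staged_", length(list.files(dir)), ".tmp"))
  writeLines(content, p)
  p
}

test_that("first ingest creates version 1, current, under the grammar path", {
  dir <- withr::local_tempdir()
  repo <- repo_create(file.path(dir, "repo"))
  row <- ingest_file(repo, stage(dir, "v1"), rig_fields(),
                     list(serial = 1, original_name = "orig.maf",
                          original_path = "dcc/x/orig.maf"),
                     now = "2015-01-01T00:00:00Z")
  expect_equal(row$repo_version, 1L)
  expect_equal(row$status, "current")
  expect_true(file.exists(file.path(repo$root, row$rel_path)))
  expect_true(startsWith(row$rel_path,
                         "current/BRCA/TCGA-A1-A001/TCGA-A1-A001-01A/"))
  expect_true(endsWith(row$rel_path, ".1.maf"))
})

test_that("identical re-ingest keeps one version; changed content increments", {
  dir <- withr::local_tempdir()
  repo <- repo_create(file.path(dir, "repo"))
  prov <- list(serial = 1, original_name = "o.maf", original_path = "dcc/o")
  ingest_file(repo, stage(dir, "same"), rig_fields(),
              prov, now = "2015-01-01T00:00:00Z")
  prov$serial <- 2
  again <- ingest_file(repo, stage(dir, "same"), rig_fields(), prov,
                       now = "2015-01-02T00:00:00Z")
  expect_equal(again$repo_version, 1L)
  expect_equal(again$source_serial, 2L)  # archive reference refreshed
  expect_equal(nrow(repo_history(repo)), 1)
  v2 <- ingest_file(repo, stage(dir, "different"), rig_fields(), prov,
                    now = "2015-01-03T00:00:00Z")
  expect_equal(v2$repo_version, 2L)
  hist <- repo_history(repo)
  expect_equal(sort(hist$repo_version), c(1L, 2L))
  expect_equal(hist$status[hist$repo_version == 1], "archived")
  # both versions readable
  expect_true(all(file.exists(file.path(repo$root, hist$rel_path))))
})

test_that("archived bytes are never modified by later operations", {
  dir <- withr::local_tempdir()
  repo <- repo_create(file.path(dir, "repo"))
  prov <- list(serial = 1, original_name = "o.maf", original_path = "dcc/o")
  ingest_file(repo, stage(dir, "gen1"), rig_fields(), prov,
              now = "2015-01-01T00:00:00Z")
  ingest_file(repo, stage(dir, "gen2"), rig_fields(), prov,
              now = "2015-01-02T00:00:00Z")
  hist <- repo_history(repo)
  arch <- hist[hist$status == "archived", ]
  arch_md5 <- unname(tools::md5sum(file.path(repo$root, arch$rel_path)))
  ingest_file(repo, stage(dir, "gen3"), rig_fields(), prov,
              now = "2015-01-03T00:00:00Z")
  remove_file(repo, arch$logical_id, "archive", now = "2015-01-04T00:00:00Z")
  expect_equal(unname(tools::md5sum(file.path(repo$root, arch$rel_path))),
               arch_md5)
  expect_equal(repo_history(repo)$md5[repo_history(repo)$repo_version == 1],
               arch$md5)
})

test_that("version numbers never skip across many content revisions", {
  dir <- withr::local_tempdir()
  repo <- repo_create(file.path(dir, "repo"))
  prov <- list(serial = 1, original_name = "o.maf", original_path = "dcc/o")
  for (k in 1:6) {
    ingest_file(repo, stage(dir, paste0("content", k)), rig_fields(), prov,
                now = sprintf("2015-01-%02dT00:00:00Z", k))
  }
  hist <- repo_history(repo)
  expect_equal(sort(hist$repo_version), 1:6)
  expect_equal(sum(hist$status == "current"), 1)
  expect_equal(hist$repo_version[hist$status == "current"], 6L)
})

test_that("removal policies: archive retains bytes, delete leaves a tombstone", {
  dir <- withr::local_tempdir()
  repo <- repo_create(file.path(dir, "repo"))
  prov <- list(serial = 1, original_name = "a.maf", original_path = "dcc/a")
  r1 <- ingest_file(repo, stage(dir, "a"), rig_fields("TCGA-A1-A001-01A"),
                    prov, now = "2015-01-01T00:00:00Z")
  r2 <- ingest_file(repo, stage(dir, "b"),
                    rig_fields("TCGA-A1-A002-01A"),
                    list(serial = 1, original_name = "b.maf",
                         original_path = "dcc/b"),
                    now = "2015-01-02T00:00:00Z")
  arch <- remove_file(repo, r1$logical_id, "archive",
                      now = "2015-02-01T00:00:00Z")
  expect_equal(arch$status, "deleted")
  expect_true(startsWith(arch$rel_path, "archive/"))
  expect_true(file.exists(file.path(repo$root, arch$rel_path)))
  gone <- remove_file(repo, r2$logical_id, "delete",
                      now = "2015-02-02T00:00:00Z")
  expect_equal(gone$status, "deleted")
  expect_true(is.na(gone$rel_path))
  expect_equal(nrow(repo_current(repo)), 0)
  # tombstone record retained
  expect_true(r2$logical_id %in% repo_history(repo)$logical_id)
  expect_error(remove_file(repo, "no|such|id", "archive"), "no current")
})

test_that("snapshots equal brute-force event replay for randomized histories", {
  dir <- withr::local_tempdir()
  repo <- repo_create(file.path(dir, "repo"))
  set.seed(77)
  barcodes <- sprintf("TCGA-A1-A%03d-01A-11D-A101-01", 1:5)
  history <- tibble::tibble(time = character(0), event = character(0),
                            lid = character(0), version = integer(0),
                            md5 = character(0))
  t <- 0
  # 20 random events: ingests (fresh or revising) and removals
  for (k in 1:20) {
    t <- t + sample(50:500, 1)
    now <- tcgavault:::iso_plus("2015-01-01T00:00:00Z", t)
    bc <- sample(barcodes, 1)
    f <- rig_fields(bc)
    lid <- logical_id(f)
    cur <- repo_current(repo)
    if (lid %in% cur$logical_id && runif(1) < 0.3) {
      remove_file(repo, lid, "archive", now = now)
      history <- dplyr::bind_rows(history, tibble::tibble(
        time = now, event = "remove", lid = lid, version = NA_integer_,
        md5 = NA_character_))
    } else {
      row <- ingest_file(repo, stage(dir, paste0("c", k)), f,
                         list(serial = k, original_name = "o.maf",
                              original_path = paste0("dcc/", bc)),
                         now = now)
      history <- dplyr::bind_rows(history, tibble::tibble(
        time = row$ingest_timestamp, event = "ingest", lid = lid,
        version = row$repo_version, md5 = row$md5))
    }
  }
  # 100 random probe instants across and beyond the history
  probes <- tcgavault:::iso_plus("2015-01-01T00:00:00Z",
                                 sort(sample(0:(t + 1000), 100)))
  for (p in probes) {
    snap <- repo_snapshot(repo, p)
    oracle <- oracle_snapshot(history, p)
    expect_equal(snap$logical_id, oracle$logical_id)
    expect_equal(snap$repo_version, oracle$repo_version)
    expect_equal(snap$md5, oracle$md5)
  }
  # boundary cases
  expect_equal(nrow(repo_snapshot(repo, "2014-12-31T23:59:59Z")), 0)
  now_snap <- repo_snapshot(repo)
  cur <- repo_current(repo)
  expect_setequal(now_snap$logical_id, cur$logical_id)
})

test_that("snapshot before a removal still lists the file", {
  dir <- withr::local_tempdir()
  repo <- repo_create(file.path(dir, "repo"))
  r <- ingest_file(repo, stage(dir, "x"), rig_fields(),
                   list(serial = 1, original_name = "o.maf",
                        original_path = "dcc/o"),
                   now = "2015-01-01T00:00:00Z")
  remove_file(repo, r$logical_id, "delete", now = "2015-06-01T00:00:00Z")
  expect_equal(nrow(repo_snapshot(repo, "2015-03-01T00:00:00Z")), 1)
  expect_equal(nrow(repo_snapshot(repo, "2015-06-01T00:00:00Z")), 0)
})

test_that("get_current honours filters and matches the now-snapshot", {
  dir <- withr::local_tempdir()
  repo <- repo_create(file.path(dir, "repo"))
  expect_equal(nrow(repo_current(repo)), 0)
  ingest_file(repo, stage(dir, "x"), rig_fields(),
              list(serial = 1, original_name = "o.maf",
                   original_path = "dcc/o"),
              now = "2015-01-01T00:00:00Z")
  f2 <- rig_fields("TCGA-A2-B001-01A-11R-A101-07", "RNASeqV2")
  f2$disease <- "GBM"
  ingest_file(repo, stage(dir, "y"), f2,
              list(serial = 1, original_name = "p.maf",
                   original_path = "dcc/p"),
              now = "2015-01-02T00:00:00Z")
  all_cur <- repo_current(repo)
  expect_equal(nrow(all_cur), 2)
  brca <- repo_current(repo, disease = "BRCA")
  expect_equal(nrow(brca), 1)
  expect_true(all(brca$logical_id %in% all_cur$logical_id))
  expect_setequal(repo_snapshot(repo)$logical_id, all_cur$logical_id)
})
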