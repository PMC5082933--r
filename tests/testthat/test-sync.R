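# Sync engine: change-list parsing, planning per source strategy,
# fetch retry, and the full run.

test_that("CHANGES parsing routes verbs and rejects malformed input", {
  expect_equal(nrow(parse_changes_file("# serial=2")), 0)
  cs <- parse_changes_file(c("# serial=2", "ADDED\tdcc/a", "ADDED\tdcc/b",
                             "DELETED\tdcc/c"))
  expect_equal(sum(cs$action == "added"), 2)
  expect_equal(sum(cs$action == "modified"), 0)
  expect_equal(sum(cs$action == "deleted"), 1)
  expect_error(parse_changes_file("RENAMED\tdcc/a"), "line 1")
  expect_error(parse_changes_file(c("ADDED\tdcc/a", "DELETED\tdcc/a")),
               "duplicate")
})

test_that("plan is empty when serials match, everything-added when local is empty", {
  rig <- sync_rig(seed = 301)
  cs <- plan_sync(rig$remote, rig$store, rig$config)
  expect_true(all(cs$action == "added"))
  expect_equal(nrow(cs), nrow(remote_metadata(rig$remote)))
  run_sync(rig$remote, rig$config, rig$repo, rig$store)
  expect_equal(nrow(plan_sync(rig$remote, rig$store, rig$config)), 0)
})

test_that("plan matches the fixture mutation counts", {
  rig <- sync_rig(seed = 302)
  run_sync(rig$remote, rig$config, rig$repo, rig$store)
  advance_release(rig$remote, mutation_spec(add = 2, modify = 1, delete = 1,
                                            seed = 5))
  cs <- plan_sync(rig$remote, rig$store, rig$config)
  expect_equal(sum(cs$action == "added"), 2)
  expect_equal(sum(cs$action == "modified"), 1)
  expect_equal(sum(cs$action == "deleted"), 1)
  # the four action lists are pairwise disjoint
  expect_false(any(duplicated(cs$path)))
})

test_that("a serial bump with no changes plans only metadata refreshes", {
  rig <- sync_rig(seed = 303)
  run_sync(rig$remote, rig$config, rig$repo, rig$store)
  advance_release(rig$remote, mutation_spec())  # all-zero mutation
  cs <- plan_sync(rig$remote, rig$store, rig$config)
  expect_true(all(cs$action == "serial_bump"))
  # the serial-numbered stores' files all get refreshed, none fetched
  n_serial <- sum(remote_metadata(rig$remote)$store %in%
                    c("dcc", "level4store"))
  expect_equal(nrow(cs), n_serial)
  rep <- run_sync(rig$remote, rig$config, rig$repo, rig$store)
  expect_equal(rep$downloads, 0)
  expect_equal(rep$n_messages, 0)
  expect_equal(rep$n_events, 0)
})

test_that("datatype selection restricts what is synced", {
  rig <- sync_rig(seed = 304)
  cfg <- sync_config(datatypes = "Somatic_Mutations")
  rep <- run_sync(rig$remote, cfg, rig$repo, rig$store)
  cur <- repo_current(rig$repo)
  expect_true(all(cur$datatype == "Somatic_Mutations"))
  expect_equal(nrow(cur),
               sum(remote_metadata(rig$remote)$datatype == "Somatic_Mutations"))
})

test_that("fetch retries until verification and logs every attempt", {
  rig <- sync_rig(seed = 305, datatypes = "Clinical")
  listing <- list_remote(rig$remote, "dcc")
  path <- listing$path[1]
  log <- file.path(rig$dir, "dl.log")
  # clean path: one attempt
  r <- fetch_file(rig$remote, path, listing$md5[1], retry_limit = 3,
                  staging_dir = file.path(rig$dir, "stage"), log_path = log)
  expect_equal(r$attempts, 1L)
  expect_true(r$verified)
  # fault below the limit: attempts = faults + 1
  inject_fault(rig$remote, path, 1)
  r2 <- fetch_file(rig$remote, path, listing$md5[1], retry_limit = 3,
                   staging_dir = file.path(rig$dir, "stage"), log_path = log)
  expect_equal(r2$attempts, 2L)
  expect_true(r2$verified)
  # at the limit: failed result, not an exception
  inject_fault(rig$remote, path, 3)
  r3 <- fetch_file(rig$remote, path, listing$md5[1], retry_limit = 3,
                   staging_dir = file.path(rig$dir, "stage"), log_path = log)
  expect_equal(r3$attempts, 3L)
  expect_false(r3$verified)
  # audit completeness: every attempt logged once; failure recoverable
  entries <- read_download_log(log)
  expect_equal(nrow(entries), 6)
  expect_equal(audit_download_log(log), path)
})

test_that("a failed download is contained and reported, not fatal", {
  rig <- sync_rig(seed = 306, datatypes = c("Clinical", "Somatic_Mutations"))
  path <- list_remote(rig$remote, "dcc")$path[1]
  inject_fault(rig$remote, path, 99)
  rep <- run_sync(rig$remote, rig$config, rig$repo, rig$store)
  expect_equal(rep$failed, path)
  expect_equal(sum(tidy(rep)$outcome == "ingested"),
               nrow(remote_metadata(rig$remote)) - 1)
  expect_equal(audit_download_log(file.path(rig$repo$root, "download.log")),
               path)
})

test_that("repeat run on a static remote is a no-op fixpoint", {
  rig <- sync_rig(seed = 307)
  run_sync(rig$remote, rig$config, rig$repo, rig$store)
  before <- tree_digest(rig$repo$root)
  rep <- run_sync(rig$remote, rig$config, rig$repo, rig$store)
  g <- glance(rep)
  expect_equal(g$downloads, 0)
  expect_equal(g$n_messages, 0)
  expect_equal(g$n_events, 0)
  expect_equal(g$n_planned, 0)
  expect_identical(tree_digest(rig$repo$root), before)
})

test_that("a modified remote file increments its repo version by exactly one", {
  rig <- sync_rig(seed = 308, datatypes = "Somatic_Mutations")
  run_sync(rig$remote, rig$config, rig$repo, rig$store)
  v_before <- repo_current(rig$repo)
  advance_release(rig$remote, mutation_spec(modify = 1, seed = 2))
  run_sync(rig$remote, rig$config, rig$repo, rig$store)
  v_after <- repo_current(rig$repo)
  changed <- dplyr::anti_join(v_after[, c("logical_id", "repo_version")],
                              v_before[, c("logical_id", "repo_version")],
                              by = c("logical_id", "repo_version"))
  expect_equal(nrow(changed), 1)
  old_v <- v_before$repo_version[v_before$logical_id == changed$logical_id]
  expect_equal(changed$repo_version, old_v + 1L)
})

test_that("catch-up over skipped releases converges to the ledger", {
  rig <- sync_rig(seed = 309)
  run_sync(rig$remote, rig$config, rig$repo, rig$store)
  # three releases between syncs, including a modify-then-delete
  advance_release(rig$remote, mutation_spec(add = 2, seed = 1))
  advance_release(rig$remote, mutation_spec(modify = 2, seed = 2))
  advance_release(rig$remote, mutation_spec(delete = 2, seed = 3))
  run_sync(rig$remote, rig$config, rig$repo, rig$store)
  cur <- repo_current(rig$repo)
  led <- ledger_replay(remote_ledger(rig$remote))
  expect_setequal(cur$original_path, led$path)
  m <- merge(cur[, c("original_path", "source_md5")], led,
             by.x = "original_path", by.y = "path")
  expect_equal(m$source_md5, m$md5)
})

test_that("deleted upstream files follow the delete policy", {
  for (policy in c("archive", "delete")) {
    rig <- sync_rig(seed = 310, datatypes = "Somatic_Mutations")
    cfg <- sync_config(datatypes = "Somatic_Mutations",
                       delete_policy = policy)
    run_sync(rig$remote, cfg, rig$repo, rig$store)
    advance_release(rig$remote, mutation_spec(delete = 1, seed = 4))
    run_sync(rig$remote, cfg, rig$repo, rig$store)
    hist <- repo_history(rig$repo)
    dead <- hist[hist$status == "deleted", ]
    expect_equal(nrow(dead), 1)
    if (policy == "archive") {
      expect_true(file.exists(file.path(rig$repo$root, dead$rel_path)))
    } else {
      expect_true(is.na(dead$rel_path))
    }
  }
})

test_that("sync ingests harmonized, sorted VCFs under grammar names", {
  rig <- sync_rig(seed = 311, datatypes = "Protected_Mutations")
  run_sync(rig$remote, rig$config, rig$repo, rig$store)
  cur <- repo_current(rig$repo)
  for (i in seq_len(nrow(cur))) {
    lines <- readLines(file.path(rig$repo$root, cur$rel_path[i]))
    keys <- sub("^##([^=]+)=.*$", "\\1", lines[1:8])
    expect_equal(keys, tcgavault:::harmonized_keys)
    expect_equal(check_vcf_sorted(lines)$severity, "ok")
    name <- basename(cur$rel_path[i])
    f <- parse_file_name(name)
    expect_equal(f$datatype, "Protected_Mutations")
    expect_equal(f$repo_version, 1L)
  }
})

test_that("non-serial sources keep original names; mass-spec gains the date prefix", {
  rig <- sync_rig(seed = 312,
                  datatypes = c("WXS_(cgHub)", "Expression_Protein"))
  run_sync(rig$remote, rig$config, rig$repo, rig$store)
  cur <- repo_current(rig$repo)
  bam <- cur[cur$datatype == "WXS_(cgHub)", ]
  expect_true(all(basename(bam$rel_path) == bam$original_name))
  ms <- cur[cur$datatype == "Expression_Protein", ]
  expect_true(all(grepl("^[0-9]{8}_", basename(ms$rel_path))))
  expect_equal(ms_strip_prefix(basename(ms$rel_path[1])),
               ms$original_name[1])
})

test_that("config files round through YAML", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("datatypes:", "  - Somatic_Mutations", "retry_limit: 5",
               "delete_policy: delete"), p)
  cfg <- read_sync_config(p)
  expect_equal(cfg$datatypes, "Somatic_Mutations")
  expect_equal(cfg$retry_limit, 5L)
  expect_equal(cfg$delete_policy, "delete")
  expect_error(sync_config(retry_limit = 0), "retry_limit")
})
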