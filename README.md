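# tcgavault

Versioned acquisition, harmonization and provenance management for
TCGA-style genomic archives.

## The problem

Consortium-scale genomic archives release data continuously across
heterogeneous upstream stores — serial-numbered archives of analysis
files with per-release change lists, BAM stores keyed by analysis UUID
and last-modified date, level-4 summary stores, dated
mass-spectrometry drops.  Files are added, modified and deleted
between releases, with no versioning at the source.  Groups that need
reproducible analyses over such data need a local mirror that detects
changes incrementally, verifies every transfer, harmonizes
heterogeneous payloads, versions each file under a stable identity,
and can answer "what did the repository look like on date *t*?".

`tcgavault` is that engine, for R. It provides:

* a **sync engine** — per-store change detection (serial comparison +
  `CHANGES_DCC.txt` replay for archive stores, last-modified dates for
  date-keyed stores), MD5-verified fetch with retry and an append-only
  download log, per-file failure containment;
* a **versioned repository** — participant/sample-oriented layout
  `disease/participant/sample/datatype/Level_n/`, gapless version
  numbers per logical file (datatype × barcode × level × portion),
  archive-or-delete policies, and date snapshots reconstructing any
  past state;
* a **naming grammar** — file names extending the TCGA barcode
  `TCGA-TSS-participant-sample·vial-portion·analyte-plate-center`
  with up to twelve ordered metadata components (access, disease,
  center, platform, level, experiment id, revisions, reference
  genome, portion name, portion number, repository version), fully
  invertible by `parse_file_name()`;
* a **VCF harmonizer** — fixed-order eight-entry header standard
  (`fileformat`, `filedate`, `center`, `platform`, `genome_ref.name`,
  `genome_ref.url`, `patient_id`, `specimen_id`) with all original
  header lines preserved, numeric within-chromosome position sorting,
  optional per-sample splitting;
* **validation** — barcode/UUID correspondence with correction,
  tissue-source-site name standardization, sortedness checks,
  checksum verification, download-log audit;
* a **metadata store** — tab-delimited system of record with
  controlled vocabularies, manifest queries, subscriptions with
  notification events, JSON change messages for downstream loaders,
  and an N-Triples export;
* a **deterministic fixture** (`generate_remote()`) emulating all four
  source dialects with a ground-truth event ledger, so the entire
  pipeline is testable offline.

Everything is tidyverse-native: data-frame-first functions returning
tibbles, `tidy()`/`glance()` on sync reports, `autoplot()` for a quick
look at a run.

## Worked example

```r
library(tcgavault)

td     <- tempfile(); dir.create(td)
remote <- generate_remote(remote_spec(n_participants = 2, seed = 7),
                          file.path(td, "remote"))
repo   <- repo_create(file.path(td, "repo"))
store  <- meta_create(file.path(td, "store"))
subscribe(store, "lab-a", list(disease = "BRCA",
                               datatype = "Somatic_Mutations"))

run_sync(remote, sync_config(), repo, store)
#> <tcgavault sync report run0001>
#>   planned:   16 change(s)
#>   downloads: 16 fetch attempt(s)
#>   ingested:  16
#>   deleted:   0
#>   refreshed: 0
#>   failed:    0
#>   messages:  16, events: 2
```

Sixteen remote files (two participants × eight datatypes) were
fetched, verified, harmonized where they were VCFs, renamed under the
grammar where they came from the serial archive, and ingested at
version 1; sixteen change messages were written and the two
Somatic_Mutations additions matched `lab-a`'s subscription.  Now the
remote evolves and we re-sync:

```r
advance_release(remote, mutation_spec(add = 1, modify = 2, delete = 1,
                                      seed = 2))
run_sync(remote, sync_config(), repo, store)
#> <tcgavault sync report run0002>
#>   planned:   16 change(s)
#>   downloads: 3 fetch attempt(s)
#>   ingested:  3
#>   deleted:   1
#>   refreshed: 12
#>   failed:    0
#>   messages:  4, events: 0
```

Only the one added and two modified files were downloaded (the
modified ones became version 2, their version-1 bytes archived); the
deleted file followed the delete policy; the twelve unchanged files
under the bumped archive serial had only their referenced serial
refreshed — no transfer.  Manifests and snapshots query the result:

```r
query_manifest(store, disease = "BRCA",
               datatype = "Somatic_Mutations")[, c("barcode", "repo_version")]
#> # A tibble: 2 × 2
#>   barcode                      repo_version
#> 1 TCGA-A1-A001-01A-11D-A101-01            1
#> 2 TCGA-A2-A002-01A-11D-A101-01            1

repo_snapshot(repo)[1:3, c("logical_id", "repo_version")]
#> # A tibble: 3 × 2
#>   logical_id                                             repo_version
#> 1 Protected_Mutations|TCGA-A1-A001-01A-11D-A101-01|2|-|1            1
#> 2 RNASeqV2|TCGA-A1-A001-01A-11R-A101-07|3|-|1                       1
#> 3 Somatic_Mutations|TCGA-A1-A001-01A-11D-A101-01|2|-|1              1
```

`repo_snapshot(repo, "2015-06-01T00:00:00Z")` would instead return the
exact file/version set the repository served at that instant — the
"data freeze" used to keep analyses comparable across upstream
updates.

A command-line wrapper ships at `inst/cli/tcgavault.R`
(`fixture generate`, `fixture advance`, `sync plan`, `sync run`,
`validate`, `manifest`, `snapshot --as-of`, `subscribe`,
`harmonize-vcf`), each command a thin veneer over the functions above.

## Package layout

| Area | Files |
|---|---|
| Fixture remote | `R/mock_remote.R` |
| Barcodes and naming | `R/barcode.R`, `R/naming.R` |
| VCF harmonization | `R/vcf.R` |
| Validation routines | `R/validation.R` |
| Sync engine | `R/sync_engine.R` |
| Versioned repository | `R/repository.R` |
| Metadata store | `R/metadata_store.R` |
| Vocabularies / registry | `R/vocab.R`, `inst/extdata/` |
| CLI | `R/cli.R`, `inst/cli/tcgavault.R` |

The methods vignette (`vignettes/data-management-model.Rmd`) documents
the model, its parameters, the fixture's realism limits, and the
design decisions in detail.
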