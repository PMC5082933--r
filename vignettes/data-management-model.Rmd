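---
title: "The tcgavault data-management model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The tcgavault data-management model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcgavault)
```

## The problem

Large consortium archives such as TCGA release data continuously across
several upstream stores with different conventions: a serial-numbered
archive of analysis files with per-release change lists, a store of
sequence alignments keyed by analysis UUID and last-modified date, a
store of level-4 cross-sample summaries, and a dated mass-spectrometry
file drop.  Files are added, modified and deleted between releases;
identical queries against public portals can return different answers,
and no portal offers versioning.  A research group that wants
reproducible analyses therefore needs a local mirror that (i) detects
changes incrementally per source strategy, (ii) verifies transfers,
(iii) harmonizes heterogeneous payloads, (iv) versions every file under
a stable identity, and (v) records enough provenance metadata to answer
"what did the repository look like on date X?".

`tcgavault` implements that engine end to end, together with a
deterministic fixture that emulates the four source dialects so the
entire pipeline is testable offline.

## The synthetic remote

`generate_remote()` materializes a four-store remote on disk from a
`remote_spec()`.  Its defaults model a small, representative archive:

* **Participants and files.** Four participants, one file per sample
  and datatype, over eight default datatypes chosen to cover all four
  stores and every payload family (VCF, MAF, tab-delimited matrix,
  idat stub, BAM stub, mass-spec TSV).  These sizes keep a full
  history-with-five-releases run in the seconds range while still
  exercising multi-datatype planning; nothing in the engine depends on
  them.
* **Payloads.** VCFs are small but well-formed VCFv4.1 text with the
  sample barcode as the genotype column and deliberately incomplete
  headers and unsorted positions, so harmonization and sorting do real
  work.  MAF/matrix payloads are tab-delimited with the barcode
  embedded.  BAM/idat/svs stand-ins are opaque seeded blobs: their
  content is never interpreted, only checksummed.
* **Clock.** Timestamps come from a synthetic monotonic clock starting
  2014-01-01T00:00:00Z, advancing seven seconds per file event and one
  day per release.  Together with payloads drawn from a seeded RNG this
  makes equal (spec, seed) produce byte-identical trees — the
  determinism contract the test suite and the command line rely on.
* **Ground truth.** Every event is appended to a ledger; replaying the
  ledger (`ledger_replay()`) reconstructs the current file set exactly,
  which is the oracle for all convergence tests.

What the fixture does *not* emulate: transport (HTTP/torrent),
credentials, real archive naming variance across centers, multi-sample
VCFs with more than a handful of records, and scale.  Tests passing
against the fixture therefore demonstrate the engine's bookkeeping —
change detection, verification, versioning, provenance — not its
behaviour under network failure modes or petabyte-scale I/O.

`advance_release()` applies a `mutation_spec()` (counts of files to
add, modify, delete), increments the release serial, and writes a
`CHANGES_DCC.txt` per serial-numbered store.  The change-list dialect
is one record per line, `ACTION<TAB>path` with ACTION in
ADDED/MODIFIED/DELETED after a `# serial=<n>` comment — the upstream
grammar is not published, so the dialect is isolated behind
`parse_changes_file()` and can be swapped.  Per-serial copies
(`CHANGES_DCC.<k>.txt`) are kept so a sync that skipped releases can
replay every intervening list.  A single release serial is shared by
both serial-numbered stores; per-archive serials would add bookkeeping
without changing any observable contract, since planning only ever
compares "local serial" with "remote serial" per store.

## Change detection

`plan_sync()` routes each store through one of two strategies:

* **Serial stores** (`dcc`, `level4store`): if the local serial equals
  the remote serial, nothing to do.  Otherwise the change lists of all
  intervening serials are replayed in order with *last action per path
  wins* — equivalent to applying the lists sequentially.  Files listed
  in no change list but present on both sides are routed to
  `serial_bump`: their referenced archive serial is refreshed in the
  metadata without any download, mirroring how unchanged analysis
  files are treated when an archive is re-released.  A remote serial
  *behind* the local one is a regression and errors.
* **Date stores** (`bamstore`, `msstore`): every file with a
  last-modified date after the recorded last sync date is planned as
  added or modified depending on whether it is already known locally;
  known files absent from the listing are planned as deleted.

An empty local repository plans everything as added.  The four action
lists are disjoint by construction.

## Transfer, validation, harmonization

`fetch_file()` stages a file and compares its MD5 against the remote
manifest, retrying up to `retry_limit` (default 3) attempts.  Every
attempt is appended to a tab-delimited download log;
`audit_download_log()` recovers the paths whose latest attempt failed,
so a failed run is recoverable from the log alone.  Verification
exhaustion produces a failed result in the report, never an exception:
per-file containment is the engine-wide failure policy, because a
single corrupt file must not abort a long sync.

Five validation routines run as pure checks returning findings
(`ok`/`corrected`/`flagged`/`error`), not exceptions: barcode/UUID
correspondence (the UUID map is authoritative — a mismatching barcode
is corrected to the map's value, an unknown UUID is only flagged, so
the system never invents identity), tissue-source-site name
standardization (trim, collapse whitespace, case-fold, then look up in
a curated mapping covering alternative names, hyphens, misspellings
and extra spaces; canonical names are fixpoints, making the operation
idempotent), VCF sortedness, checksum verification, and the log audit.

VCF harmonization rewrites the header to a fixed-order eight-entry
block — `fileformat`, `filedate`, `center`, `platform`,
`genome_ref.name`, `genome_ref.url`, `patient_id`, `specimen_id` —
followed by every remaining original header line in original order.
Values present in the original header win; metadata only fills gaps,
and a value available from neither side errors naming the key (the
alternative — silently overwriting original header values — would
destroy provenance).  The dotted key spelling is used because a space
is not legal in a VCF header key.  `sort_records()` orders positions
numerically within each chromosome block, keeping blocks in
first-appearance order and ties in input order: the operation is a
stable permutation, hence idempotent, and deliberately does *not*
impose a karyotypic chromosome order the source did not have.
`split_by_sample()` projects each genotype column into its own
single-sample file under the `split` policy; `no_split` is the
identity (the policy exists because protected-mutation files are
managed unsplit).

## Versioning and the repository

The repository's unit of identity is the *logical file*: the tuple
(datatype, barcode, level, portion name, portion number).  The
experiment id carried in names is `<datatype>_<serial>` and therefore
changes across re-releases of the same analysis; the serial-free part
of it (the datatype) participates in identity, the serial does not —
otherwise every archive re-release would spuriously mint new logical
files instead of new versions of existing ones.

`ingest_file()` implements three-way versioning semantics: a new
logical id enters at version 1; changed content archives the previous
version and becomes current at version+1 (versions are gapless by
construction); identical content creates no version and only refreshes
the referenced archive serial.  Archived bytes live under a parallel
`archive/` subtree and are never touched again.  Deletion follows the
configured policy: `archive` retains the bytes in the archive area,
`delete` removes them leaving a tombstone record.  Both are offered
because either retention behaviour is defensible; the default is
`archive` (keep everything).

Files from the serial-numbered archive are renamed with the
thirteen-component grammar (below); BAM stubs and level-4 bundles keep
their original names, and mass-spectrometry files — which carry no
upstream versioning — gain a `YYYYMMDD_` analysis-date prefix.

`repo_snapshot(as_of)` reconstructs the repository at an instant: for
each logical id, the version with the latest ingest timestamp at or
before `as_of`, excluded if removed at or before `as_of`.  Snapshots
key on the repository's own ingest clock (not source dates): a
"freeze" means *what this repository served on that date*, which is
the reproducibility question snapshots exist to answer.  Ingest
timestamps are kept strictly monotone per repository so snapshot
boundaries are well defined even for events in the same wall-clock
second.

## The naming grammar

Repository names begin with the TCGA barcode and append up to twelve
further components in fixed order: access type, disease study,
analysis center, platform, data level, experiment id, analysis
revision, TCGA revision, reference genome (optional), portion name
(optional, e.g. the `red`/`grn` idat portions), portion number
(default `1`, always emitted), and repository version; the extension
follows.  Components are joined with `.` while the barcode keeps its
internal hyphens, so a single split on `.` recovers everything;
metadata values are sanitized (dots and whitespace become `_`) before
naming.  Two parsing choices worth stating: the extension is
everything after the version component, so multi-dot suffixes like
`tar.gz` survive; and when only one optional label is present it is
classified by vocabulary — a known portion name (`red`/`grn`) is a
portion name, anything else a reference genome.  The TCGA revision
number is treated as an opaque integer carried from archive metadata.

```{r naming}
f <- file_name_fields(
  barcode = "TCGA-A1-A0SB-01A-11D-A141-01", access = "controlled",
  disease = "BRCA", center_name = "genome.wustl.edu",
  platform = "HumanMethylation450", level = "1",
  experiment_id = "DNA_Methylation_2", ref_genome = "GRCh37",
  portion_name = "red", portion_number = 2, repo_version = 3,
  extension = "idat")
build_file_name(f)
count_name_components(build_file_name(f))
build_directory_path(f)
```

The directory layout is participant/sample-oriented:
`<disease>/<participant>/<sample>/<datatype>/Level_<n>/`, a pure
function of the name fields.

## Metadata, manifests, subscriptions, messages

The metadata store is a directory of tab-delimited tables — records
keyed by (logical id, version), subscriptions, a per-store sync
cursor — plus an append-only notification outbox and per-run JSON
change-message documents.  A relational-style table store is the
single system of record; the RDF form is an export
(`export_triples()`/`import_triples()`, N-Triples with the file
identifier as subject and record field names as predicates), because
maintaining two live backends doubles surface area without adding
testable behaviour.

Five controlled vocabularies (disease study, tissue source site,
center, sample type, portion analyte) resolve codes into description
fields at upsert time; unknown codes error naming the table and code.
`query_manifest()` filters current records by conjunction (absent
filter matches all) with deterministic ordering, suitable for
command-line scripting.

Subscriptions pair a subscriber id with a manifest-style filter;
after each sync, one notification event is emitted per matching
(subscription × applied change).  "Meaningful difference" is
operationalized as content change — added, modified or deleted files;
serial-only refreshes emit nothing.  Event transport is out of scope:
events go to the outbox file.  Change messages — one JSON object per
content change, carrying logical id, action, version, local path,
checksum and run id — are validated against the schema shipped in
`inst/schema/` and are the hand-off point for loading repository
changes into downstream systems.

## Numerical and degenerate-input choices

* All timestamps are ISO-8601 UTC strings, so lexicographic order is
  temporal order and no timezone arithmetic exists anywhere.
* MD5 is the integrity hash throughout (matching upstream manifests);
  the empty-file digest is handled like any other value.
* Sorting ties (equal CHROM and POS) keep input order; repeated
  harmonization and sorting are fixpoints.
* A remote with zero participants yields empty stores, an empty
  ledger, and empty-but-valid manifests; syncing it is a no-op.
* Mutation specs are validated for satisfiability (cannot modify or
  delete more files than exist).
* Seeds are plain 32-bit integers; derived seeds stay below 2^31.

## Scale of the shipped checks

The test suite and `scripts/acceptance.R` exercise randomized
histories of roughly 5 releases over remotes of up to ~30 files
(20 histories in the suite, 8 in the script), 100 random snapshot
probes against a brute-force replay oracle, 30 random toy VCFs
against an independent quadratic sort oracle, and 500-case round
trips for names, barcodes, triples and change messages.  These sizes
were chosen to exercise every code path with comfortable margin;
the engine has no algorithmic step worse than sorting within a file,
so behaviour does not change qualitatively with size.

## Known limitations

* The CHANGES dialect and archive naming are the fixture's stand-ins;
  pointing the engine at a real archive requires an adapter
  implementing the same listing/fetch/change-list contract.
* Barcode/UUID validation trusts the shipped mapping tables; there is
  no live query against an authority.
* VCF handling is plain text only (no bgzip/tabix), and harmonization
  never rewrites conflicting original header values — it fills gaps.
* The metadata store is single-writer; concurrent syncs against one
  store are not supported.
* Scheduling is the caller's job: one invocation performs one sync.
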