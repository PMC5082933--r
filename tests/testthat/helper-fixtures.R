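# Shared fixtures and independent oracles, built in code at test time.

# ---- toy VCF builders -----------------------------------------------------

toy_vcf <- function(chrom, pos, samples = "S1",
                    extra_header = character(0),
                    header_keys = c(fileformat = "VCFv4.1",
                                    filedate = "20140601")) {
  chrom <- rep(chrom, length.out = length(pos))
  meta <- c(paste0("##", names(header_keys), "=", header_keys),
            extra_header)
  hdr <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", samples), collapse = "\t")
  recs <- vapply(seq_along(chrom), function(i) {
    paste(c(chrom[i], pos[i], ".", "A", "G", ".", "PASS", "NS=1", "GT",
            rep("0/1", length(samples))), collapse = "\t")
  }, character(1))
  c(meta, hdr, recs)
}

random_toy_vcf <- function(seed) {
  set.seed(seed)
  n <- sample(3:40, 1)
  chrom <- sample(c("1", "2", "7", "10", "X"), n, replace = TRUE)
  pos <- sample(1:10000, n, replace = TRUE)
  toy_vcf(chrom, pos,
          extra_header = c("##INFO=<ID=NS,Number=1,Type=Integer,Description=\"n\">",
                           "##source=toygen"))
}

# Full meta list satisfying every harmonized header key.
full_harmonize_meta <- function() {
  list(fileformat = "VCFv4.1", filedate = "20140601",
       center = "broad.mit.edu", platform = "IlluminaGA_DNASeq",
       "genome_ref.name" = "GRCh37",
       "genome_ref.url" = "http://example.org/GRCh37",
       patient_id = "TCGA-A1-A001",
       specimen_id = "TCGA-A1-A001-01A-11D-A101-01")
}

# Brute-force stable sort oracle: repeatedly pick, among remaining
# records, the first one from the first-appearing chromosome block with
# minimal POS.  O(n^2), independent of the implementation's order().
oracle_sort_vcf <- function(lines) {
  hdr_idx <- which(startsWith(lines, "#CHROM"))
  meta <- lines[seq_len(hdr_idx)]
  recs <- lines[-seq_len(hdr_idx)]
  recs <- recs[nzchar(recs)]
  if (length(recs) == 0) return(meta)
  chrom <- sub("\t.*$", "", recs)
  pos <- as.numeric(vapply(strsplit(recs, "\t"), `[`, character(1), 2))
  block_order <- unique(chrom)
  out <- integer(0)
  remaining <- seq_along(recs)
  for (b in block_order) {
    idx <- remaining[chrom[remaining] == b]
    while (length(idx) > 0) {
      best <- idx[which.min(pos[idx])][1]  # first minimal: stable
      out <- c(out, best)
      idx <- setdiff(idx, best)
    }
  }
  c(meta, recs[out])
}

# Brute-force sortedness verdict: pairwise scan within blocks.
oracle_is_sorted <- function(lines) {
  hdr_idx <- which(startsWith(lines, "#CHROM"))
  recs <- lines[-seq_len(hdr_idx)]
  recs <- recs[nzchar(recs)]
  if (length(recs) < 2) return(TRUE)
  chrom <- sub("\t.*$", "", recs)
  pos <- as.numeric(vapply(strsplit(recs, "\t"), `[`, character(1), 2))
  for (b in unique(chrom)) {
    p <- pos[chrom == b]
    for (i in seq_len(length(p) - 1)) if (p[i + 1] < p[i]) return(FALSE)
  }
  TRUE
}

# ---- random barcodes and name fields --------------------------------------

random_barcode <- function(depth = 7) {
  alnum <- c(LETTERS, 0:9)
  seg <- c("TCGA",
           paste(sample(alnum, 2, TRUE), collapse = ""),
           paste(sample(alnum, 4, TRUE), collapse = ""),
           paste0(sprintf("%02d", sample(0:19, 1)),
                  if (runif(1) < 0.8) sample(LETTERS, 1) else ""),
           paste0(sprintf("%02d", sample(0:19, 1)),
                  if (runif(1) < 0.8) sample(c("D", "R", "T", "W"), 1) else ""),
           paste(sample(alnum, 4, TRUE), collapse = ""),
           sprintf("%02d", sample(1:13, 1)))
  paste(seg[seq_len(depth)], collapse = "-")
}

random_name_fields <- function() {
  dt <- sample(tcga_datatypes()$datatype, 1)
  has_ref <- runif(1) < 0.5
  has_portion <- runif(1) < 0.3
  file_name_fields(
    barcode = random_barcode(sample(3:7, 1)),
    access = sample(c("public", "controlled"), 1),
    disease = sample(c("BRCA", "GBM", "OV", "LUAD"), 1),
    center_name = sample(c("broad.mit.edu", "unc.edu", "hms.harvard.edu"), 1),
    platform = sample(c("IlluminaGA_DNASeq", "Genome_Wide_SNP_6", "bio"), 1),
    level = as.character(sample(0:4, 1)),
    experiment_id = paste0(dt, "_", sample(1:30, 1)),
    analysis_revision = sample(1:9, 1), tcga_revision = sample(1:9, 1),
    ref_genome = if (has_ref) sample(c("GRCh37", "hg19", "GRCh38"), 1)
                 else NA_character_,
    portion_name = if (has_portion) sample(c("red", "grn"), 1)
                   else NA_character_,
    portion_number = sample(1:4, 1), repo_version = sample(1:9, 1),
    extension = sample(c("vcf", "maf", "txt", "tar.gz", "idat"), 1),
    datatype = dt)
}

# ---- small remote + sync rig ----------------------------------------------

small_datatypes <- c("Somatic_Mutations", "Protected_Mutations",
                     "WXS_(cgHub)", "Expression_Protein",
                     "CNV_(SNP_Array)")

sync_rig <- function(seed, n_participants = 2,
                     datatypes = small_datatypes, dir = withr::local_tempdir(
                       .local_envir = parent.frame())) {
  remote <- generate_remote(
    remote_spec(n_participants = n_participants, datatypes = datatypes,
                seed = seed),
    file.path(dir, "remote"))
  list(remote = remote,
       repo = repo_create(file.path(dir, "repo")),
       store = meta_create(file.path(dir, "store")),
       config = sync_config(),
       dir = dir)
}

# Hash every file of a tree (path-relative), for byte-identity checks.
tree_digest <- function(root) {
  fs <- sort(list.files(root, recursive = TRUE, all.files = TRUE))
  paste(fs, unname(tools::md5sum(file.path(root, fs))))
}

# Brute-force repository snapshot oracle: replay an explicit event
# history (tibble: time, event in ingest/remove, lid, version, md5,
# rel_path) truncated at t.
oracle_snapshot <- function(history, t) {
  hist <- history[history$time <= t, , drop = FALSE]
  out <- list()
  for (lid in unique(hist$lid)) {
    h <- hist[hist$lid == lid, , drop = FALSE]
    h <- h[order(h$time), , drop = FALSE]
    live <- NULL
    for (i in seq_len(nrow(h))) {
      if (h$event[i] == "ingest") live <- h[i, ] else live <- NULL
    }
    if (!is.null(live)) out[[lid]] <- live
  }
  if (length(out) == 0) {
    return(tibble::tibble(logical_id = character(0),
                          repo_version = integer(0), md5 = character(0)))
  }
  res <- dplyr::bind_rows(out)
  tibble::tibble(logical_id = res$lid, repo_version = res$version,
                 md5 = res$md5) |> dplyr::arrange(logical_id)
}
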