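# Controlled vocabularies and the datatype registry.
#
# The registry enumerates the managed TCGA datatypes, the upstream
# datastore each one is served from, the data level the corresponding
# code module handles, and the payload file type.  Four source dialects
# exist: a serial-numbered DCC-style archive ("dcc"), a BAM store keyed
# by analysis UUID and last-modified date ("bamstore"), a serial-numbered
# level-4 bundle store ("level4store"), and a dated mass-spectrometry
# store ("msstore").

#' Datatype registry
#'
#' One row per managed datatype: which of the four source stores serves
#' it, the data level generated for it, the payload file type, the code
#' module responsible, and whether multi-sample VCFs of that datatype
#' are split per sample.
#'
#' @return A tibble with columns `datatype`, `store`, `level`,
#'   `file_type`, `module`, `split_policy`.
#' @examples
#' tcga_datatypes()
#' @export
tcga_datatypes <- function() {
  tibble::tribble(
    ~datatype,                   ~store,        ~level, ~file_type, ~module,                    ~split_policy,
    "WGS_(cgHub)",               "bamstore",    "1",    "bam",      "BAMMetadataManager",        "no_split",
    "WXS_(cgHub)",               "bamstore",    "1",    "bam",      "BAMMetadataManager",        "no_split",
    "Protected_Mutations",       "dcc",         "2",    "vcf",      "ProtectedMutationsNoSplit", "no_split",
    "Protected_Mutations_MAF",   "dcc",         "2",    "maf",      "MafModule",                 "no_split",
    "Somatic_Mutations",         "dcc",         "2",    "maf",      "MafModule",                 "no_split",
    "RNA-Seq_(cgHub)",           "bamstore",    "1",    "bam",      "BAMMetadataManager",        "no_split",
    "RNASeq",                    "dcc",         "2",    "vcf",      "RNASeqLevel2Module",        "split",
    "RNASeqV2",                  "dcc",         "3",    "txt",      "RNASeqV2Level3Module",      "no_split",
    "CNV_(CN_Array)",            "dcc",         "3",    "txt",      "CNAModule",                 "no_split",
    "CNV_(SNP_Array)",           "level4store", "4",    "txt",      "CN_Level4",                 "no_split",
    "CNV_(Low_Pass_DNASeq)",     "dcc",         "2",    "vcf",      "ProtectedMutationsNoSplit", "no_split",
    "Expression_Exon",           "dcc",         "3",    "txt",      "ExpExonModule",             "no_split",
    "Expression_Gene",           "dcc",         "3",    "txt",      "ExpGeneModule",             "no_split",
    "Expression_Protein",        "msstore",     "4",    "tsv",      "MassSpecModule",            "no_split",
    "Bisulfite-Seq_(cgHub)",     "bamstore",    "1",    "bam",      "BAMMetadataManager",        "no_split",
    "DNA_Methylation",           "dcc",         "1",    "idat",     "MethylModule",              "no_split",
    "miRNA-Seq_(cgHub)",         "bamstore",    "1",    "bam",      "BAMMetadataManager",        "no_split",
    "miRNASeq",                  "dcc",         "3",    "txt",      "miRNASeqModule",            "no_split",
    "Fragment_Analysis_Result",  "dcc",         "1",    "txt",      "MSIModule",                 "no_split",
    "Diagnostic_images",         "dcc",         "1",    "svs",      "ImageModule",               "no_split",
    "Tissue_images",             "dcc",         "1",    "svs",      "ImageModule",               "no_split",
    "Clinical",                  "dcc",         "2",    "txt",      "ClinicalModule",            "no_split"
  )
}

#' Names of the upstream datastores
#'
#' The engine models four remote source dialects, mirroring the four
#' archives the acquisition modules were written against.
#'
#' @return Character vector of store names.
#' @export
source_stores <- function() c("dcc", "bamstore", "level4store", "msstore")

# Portion names that may appear as name component (11); used to
# disambiguate a single optional label during file-name parsing.
known_portion_names <- function() c("red", "grn")

assert_known_datatypes <- function(datatypes) {
  known <- tcga_datatypes()$datatype
  bad <- setdiff(datatypes, known)
  if (length(bad) > 0) {
    vault_abort(
      paste0("unknown datatype code(s): ", paste(bad, collapse = ", ")),
      class = "tcgavault_unknown_datatype"
    )
  }
  invisible(datatypes)
}

vocab_tables <- c("disease_study", "tissue_source_site", "center",
                  "sample_type", "portion_analyte")

#' Load the controlled vocabularies
#'
#' Reads the five metadata vocabularies (Disease Study, Tissue Source
#' Site, Center, Sample Type, Portion Analyte) shipped with the package,
#' or from a directory of overriding two-column tab-delimited files
#' (`code`, `name`) named after the tables.
#'
#' @param dir Optional directory holding `<table>.tsv` overrides.
#' @return Named list of tibbles, one per vocabulary table.
#' @export
load_vocabularies <- function(dir = NULL) {
  default_dir <- system.file("extdata", package = "tcgavault")
  out <- lapply(vocab_tables, function(tb) {
    path <- file.path(default_dir, paste0(tb, ".tsv"))
    if (!is.null(dir) && file.exists(file.path(dir, paste0(tb, ".tsv")))) {
      path <- file.path(dir, paste0(tb, ".tsv"))
    }
    v <- read_tsv_quiet(path)
    if (anyDuplicated(v$code)) {
      vault_abort(paste0("duplicate codes in vocabulary ", tb))
    }
    v
  })
  setNames(out, vocab_tables)
}

# Resolve one code against one vocabulary table, erroring with the table
# and code named when it cannot be resolved.
resolve_code <- function(vocab, table, code) {
  v <- vocab[[table]]
  hit <- v$name[v$code == code]
  if (length(hit) != 1) {
    vault_abort(
      paste0("unknown code '", code, "' in vocabulary table '", table, "'"),
      class = "tcgavault_unknown_code"
    )
  }
  hit
}
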