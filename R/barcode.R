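# TCGA barcode grammar.
#
# A barcode is a hyphen-delimited hierarchical sample identifier:
#
#   TCGA-<TSS>-<participant>-<sample_type><vial>-<portion><analyte>-<plate>-<center>
#   e.g. TCGA-A1-A0SB-01A-11D-A141-01
#
# and may be truncated from the right: participant depth (3 segments),
# sample depth (4), portion depth (5), plate (6) or full aliquot depth
# (7 segments).  The grammar is centralized here; everything else in
# the package round-trips through parse_barcode()/render_barcode().

# Per-segment patterns, anchored when used.
.bc_patterns <- list(
  project     = "TCGA",
  tss         = "[A-Z0-9]{2}",
  participant = "[A-Z0-9]{4}",
  sample      = "[0-9]{2}[A-Z]?",  # sample_type + optional vial
  portion     = "[0-9]{2}[A-Z]?",  # portion number + optional analyte
  plate       = "[A-Z0-9]{4}",
  center      = "[0-9]{2}"
)

#' Parse TCGA barcodes
#'
#' Splits hyphen-delimited barcodes into their hierarchical fields.
#' Truncated barcodes (stopping at participant, sample, portion or plate
#' depth) are accepted; fields beyond the truncation depth come back
#' `NA`.
#'
#' @param text Character vector of barcodes.
#' @return A tibble with one row per input and columns `barcode`,
#'   `project`, `tss`, `participant`, `sample_type`, `vial`, `portion`,
#'   `analyte`, `plate`, `center`, `depth` (number of segments).
#' @examples
#' parse_barcode("TCGA-A1-A0SB-01A-11D-A141-01")
#' parse_barcode("TCGA-A1-A0SB")
#' @export
parse_barcode <- function(text) {
  stopifnot(is.character(text), length(text) >= 1)
  rows <- lapply(text, parse_barcode_one)
  dplyr::bind_rows(rows)
}

parse_barcode_one <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    vault_abort("empty barcode", class = "tcgavault_barcode_error")
  }
  seg <- strsplit(x, "-", fixed = TRUE)[[1]]
  n <- length(seg)
  if (n < 3 || n > 7) {
    vault_abort(
      paste0("barcode '", x, "': expected 3-7 hyphen-delimited segments, got ", n),
      class = "tcgavault_barcode_error"
    )
  }
  names_by_pos <- c("project", "tss", "participant", "sample", "portion",
                    "plate", "center")
  for (i in seq_len(n)) {
    pat <- paste0("^", .bc_patterns[[names_by_pos[i]]], "$")
    if (!grepl(pat, seg[i])) {
      vault_abort(
        paste0("barcode '", x, "': segment ", i, " ('", seg[i],
               "') is not a valid ", names_by_pos[i], " field"),
        class = "tcgavault_barcode_error"
      )
    }
  }
  split_code_letter <- function(s) {
    # "01A" -> c("01", "A"); "01" -> c("01", NA)
    list(code = substr(s, 1, 2),
         letter = if (nchar(s) == 3) substr(s, 3, 3) else NA_character_)
  }
  samp <- if (n >= 4) split_code_letter(seg[4]) else list(code = NA_character_, letter = NA_character_)
  port <- if (n >= 5) split_code_letter(seg[5]) else list(code = NA_character_, letter = NA_character_)
  tibble::tibble(
    barcode = x,
    project = seg[1],
    tss = seg[2],
    participant = seg[3],
    sample_type = samp$code,
    vial = samp$letter,
    portion = port$code,
    analyte = port$letter,
    plate = if (n >= 6) seg[6] else NA_character_,
    center = if (n >= 7) seg[7] else NA_character_,
    depth = n
  )
}

#' Render barcodes back to text
#'
#' Inverse of [parse_barcode()]: joins populated fields with hyphens,
#' fusing vial and analyte letters to their numeric fields.
#' `render_barcode(parse_barcode(x))` is the identity on valid input.
#'
#' @param b A tibble as produced by [parse_barcode()] (extra columns
#'   are ignored).
#' @return Character vector of barcodes.
#' @export
render_barcode <- function(b) {
  stopifnot(is.data.frame(b))
  fuse <- function(code, letter) {
    ifelse(is.na(code), NA_character_,
           paste0(code, ifelse(is.na(letter), "", letter)))
  }
  segs <- cbind(b$project, b$tss, b$participant,
                fuse(b$sample_type, b$vial),
                fuse(b$portion, b$analyte),
                b$plate, b$center)
  apply(segs, 1, function(r) paste(r[!is.na(r)], collapse = "-"))
}

# Truncate a barcode string to a given depth (number of segments).
truncate_barcode <- function(x, depth) {
  seg <- strsplit(x, "-", fixed = TRUE)[[1]]
  paste(seg[seq_len(min(depth, length(seg)))], collapse = "-")
}
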