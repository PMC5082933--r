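# Internal helpers shared across modules.

#' MD5 checksum of a file
#'
#' Thin wrapper over [tools::md5sum()] returning an unnamed lowercase hex
#' string, or `NA` if the file does not exist.
#'
#' @param path Path to a file.
#' @return Character scalar (32 hex digits) or `NA_character_`.
#' @keywords internal
md5_file <- function(path) {
  if (!file.exists(path)) return(NA_character_)
  unname(tools::md5sum(path))
}

# ISO-8601 UTC instant; all timestamps in the package are carried as
# ISO strings so that lexicographic order equals temporal order.
iso_format <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

iso_now <- function() iso_format(Sys.time())

iso_parse <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

# Advance an ISO instant by n seconds.
iso_plus <- function(x, secs) iso_format(iso_parse(x) + secs)

is_iso_instant <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) &&
    grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}Z$", x)
}

# Deterministic local RNG scope: run `expr` under a seed without touching
# the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a child seed from a parent seed and a label, staying within
# 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587) + 1L
}

# Replace the naming delimiter (".") and whitespace inside metadata
# values so a single split on "." recovers file-name components.
# Hyphens are left alone: they are barcode-internal and harmless to the
# split rule, and datatype codes legitimately contain them.
sanitize_component <- function(x) {
  gsub("[.[:space:]]+", "_", as.character(x))
}

read_tsv_quiet <- function(path, col_types = NULL) {
  readr::read_tsv(path, col_types = col_types %||% readr::cols(.default = "c"),
                  progress = FALSE, show_col_types = FALSE)
}

write_tsv_quiet <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
}

# Stop with a classed condition; all package errors share the
# "tcgavault_error" class so callers can catch them uniformly.
vault_abort <- function(msg, class = "tcgavault_error", ...) {
  abort(msg, class = c(class, "tcgavault_error"), ...)
}
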