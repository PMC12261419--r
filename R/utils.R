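# Internal helpers shared across modules.

# Half-up rounding to integer percent for diagram labels.  base::round()
# rounds half to even, which would print 0.005 as "0%".
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

format_percent <- function(x) {
  paste0(round_half_up(100 * x), "%")
}

# Filesystem-safe token for a taxon name; the index keeps the original
# name so the mapping is reversible.
sanitize_token <- function(x) {
  tok <- gsub("[^A-Za-z0-9._-]+", "_", x)
  tok <- gsub("^_+|_+$", "", tok)
  ifelse(nzchar(tok), tok, "taxon")
}

# Unique tokens for a character vector (suffix duplicates deterministically).
unique_tokens <- function(x) {
  tok <- sanitize_token(x)
  make.unique(tok, sep = "-")
}

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

write_tsv_file <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

`%||%` <- rlang::`%||%`
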