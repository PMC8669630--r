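# Internal helpers shared across the package.

# Classed conditions: xtn_usage_error (bad arguments / CLI usage),
# xtn_input_error (malformed input files), xtn_contract_error (violated
# numerical preconditions). The CLI maps these to fixed exit codes.
abort_usage <- function(msg, ...) {
  abort(msg, class = "xtn_usage_error", ...)
}
abort_input <- function(msg, ...) {
  abort(msg, class = "xtn_input_error", ...)
}
abort_contract <- function(msg, ...) {
  abort(msg, class = "xtn_contract_error", ...)
}

# Deterministic sub-seed for a named pseudo-random substream, so that adding
# one generator never shifts the draws of another.  Plain 32-bit-safe integer
# arithmetic on the stream name's character codes.
sub_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.double(seed) * 7919 + h * 104729) %% 2147483629)
}

# Canonical gene key used for matching symbols across files: case-insensitive
# unless the caller asked for strict case.
gene_key <- function(symbol, strict_case = FALSE) {
  if (strict_case) symbol else toupper(symbol)
}

# Write a TSV with a single '#' header naming the columns and tool version.
write_xtsv <- function(df, path) {
  header <- paste0("# ", paste(names(df), collapse = "\t"),
                   "\txtalknet=", as.character(utils::packageVersion("xtalknet")))
  body <- if (nrow(df) == 0) character(0) else
    do.call(paste, c(lapply(df, as.character), sep = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

# Read text lines either from a file path or from a character vector that is
# already line-split (convenient in tests).
as_lines <- function(x) {
  if (length(x) == 1 && !grepl("[\t\n]", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
}
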