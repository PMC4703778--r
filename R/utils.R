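#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

#' Read a tab-separated file, skipping `#` comment lines
#' @noRd
read_tsv_lines <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' @noRd
split_tab <- function(x) strsplit(x, "\t", fixed = TRUE)

#' Format numbers for TSV output with stable round-trip precision
#' @noRd
fmt_num <- function(x) formatC(x, digits = 12, format = "g")

#' Deterministic seed stream: derive sub-seeds from a root seed
#' @noRd
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 1009L + as.integer(offset) * 9973L) %% 2147480000L
}
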