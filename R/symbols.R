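#' Harmonize gene symbols to a single namespace
#'
#' All identifiers used by the package (pathway gene sets, TF-target pairs,
#' PPI nodes, omics tables) are matched by symbol, so every reader funnels
#' its identifiers through this function: symbols are trimmed of surrounding
#' whitespace and upper-cased. An optional alias table maps known synonyms
#' (e.g. `ERK2`) to their preferred symbol (`MAPK1`); lookup is
#' case-insensitive and applied after syntactic normalization.
#'
#' @param x Character vector of raw identifiers.
#' @param alias_table Optional named character vector mapping alias to
#'   preferred symbol (names are the aliases). Values are harmonized too.
#' @return Character vector of harmonized symbols, same length as `x`.
#' @examples
#' harmonize_symbol(c("stat3", " Mapk1 "))
#' harmonize_symbol("ERK2", alias_table = c(ERK2 = "MAPK1"))
#' @export
harmonize_symbol <- function(x, alias_table = NULL) {
  if (length(x) == 0L) return(character())
  sym <- toupper(trimws(as.character(x)))
  if (any(is.na(sym) | !nzchar(sym))) {
    abort("empty or missing symbol cannot be harmonized")
  }
  if (!is.null(alias_table)) {
    assert_that(!is.null(names(alias_table)) && all(nzchar(names(alias_table))),
                "alias_table must be a named character vector (names are aliases)")
    al <- toupper(trimws(unname(alias_table)))
    names(al) <- toupper(trimws(names(alias_table)))
    hit <- match(sym, names(al))
    sym[!is.na(hit)] <- al[hit[!is.na(hit)]]
  }
  sym
}
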