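#' One layer's molecule-by-timepoint log2 fold-change series
#'
#' Container for a single measurement layer (phosphoprotein, protein or
#' transcript): a molecule x timepoint matrix of log2 fold changes versus
#' the unstimulated baseline (time 0), plus a parallel logical matrix of
#' significance calls. The baseline column is identically zero and never
#' significant.
#'
#' @param layer One of `"phosphoprotein"`, `"protein"`, `"transcript"`.
#' @param molecules Character vector of harmonized, unique gene symbols.
#' @param timepoints Strictly increasing numeric vector of hours, starting
#'   at 0.
#' @param logfc Numeric matrix, `length(molecules)` x `length(timepoints)`.
#' @param significant Logical matrix of the same shape (defaults to all
#'   `FALSE`; set with [call_significant_fc()] or file-supplied flags).
#' @return An `omics_ts` object.
#' @export
omics_time_series <- function(layer, molecules, timepoints, logfc,
                              significant = NULL) {
  layer <- match.arg(layer, c("phosphoprotein", "protein", "transcript"))
  molecules <- harmonize_symbol(molecules)
  assert_that(!anyDuplicated(molecules), "duplicate molecule symbols")
  timepoints <- as.numeric(timepoints)
  assert_that(length(timepoints) >= 1 && timepoints[1] == 0,
              "timepoints must start at baseline 0")
  assert_that(all(diff(timepoints) > 0), "timepoints must be strictly increasing")
  logfc <- as.matrix(logfc)
  assert_that(all(dim(logfc) == c(length(molecules), length(timepoints))),
              "logfc dimensions must be molecules x timepoints")
  assert_that(all(is.finite(logfc)), "logfc must be finite (missing values are not supported)")
  assert_that(all(logfc[, 1] == 0), "baseline logfc column must be all zeros")
  if (is.null(significant)) {
    significant <- matrix(FALSE, nrow(logfc), ncol(logfc))
  }
  significant <- as.matrix(significant)
  assert_that(all(dim(significant) == dim(logfc)) && is.logical(significant),
              "significant must be a logical matrix matching logfc")
  assert_that(!any(significant[, 1]), "baseline column must not be significant")
  dimnames(logfc) <- dimnames(significant) <- list(molecules, as.character(timepoints))
  structure(list(layer = layer, molecules = molecules, timepoints = timepoints,
                 logfc = logfc, significant = significant),
            class = "omics_ts")
}

#' @export
print.omics_ts <- function(x, ...) {
  cat("<omics_ts> layer=", x$layer, ", ", length(x$molecules), " molecules, ",
      length(x$timepoints), " timepoints (",
      paste(x$timepoints, collapse = ", "), " h)\n", sep = "")
  cat("  significant calls: ", sum(x$significant), "\n", sep = "")
  invisible(x)
}

#' @describeIn omics_time_series long-format view: one row per
#'   molecule/timepoint with `logfc` and `significant`.
#' @param x An `omics_ts` object.
#' @param ... Unused.
#' @export
tidy.omics_ts <- function(x, ...) {
  tibble::tibble(
    layer = x$layer,
    symbol = rep(x$molecules, times = length(x$timepoints)),
    time = rep(x$timepoints, each = length(x$molecules)),
    logfc = as.vector(x$logfc),
    significant = as.vector(x$significant)
  )
}

#' Molecules significant at a given timepoint
#' @param series An `omics_ts`.
#' @param timepoint Hour, must be one of `series$timepoints`.
#' @return Character vector of symbols.
#' @export
significant_at <- function(series, timepoint) {
  i <- match(timepoint, series$timepoints)
  assert_that(!is.na(i), paste0("timepoint ", timepoint, " not in series"))
  series$molecules[series$significant[, i]]
}

#' Load an omics time-course table
#'
#' Tab-separated, header `symbol` followed by time points in hours, with
#' optional parallel `sig_<t>` 0/1 columns carrying precomputed significance
#' flags. `ratio` tables are log2-transformed on load. A baseline column at
#' 0 h is inserted (all zeros) if absent.
#'
#' For the transcript layer, significance normally comes from the upstream
#' differential-expression pipeline as `sig_<t>` flags; when those are
#' absent the fold-change rule ([call_significant_fc()]) is applied as a
#' fallback with a warning.
#'
#' @param path Path to the TSV file.
#' @param layer Layer label (see [omics_time_series()]).
#' @param scale `"log2fc"` (values are already log2 fold changes) or
#'   `"ratio"` (fold ratios, log2-applied on load).
#' @param fold_threshold Fold-change threshold used when no `sig_` columns
#'   are present.
#' @return An `omics_ts` object.
#' @export
load_omics_table <- function(path, layer, scale = c("log2fc", "ratio"),
                             fold_threshold = 1.5) {
  scale <- match.arg(scale)
  tsv <- read_tsv_lines(path)
  fields <- split_tab(tsv$lines)
  header <- fields[[1]]
  assert_that(identical(tolower(header[1]), "symbol"),
              "first header column must be 'symbol'")
  cols <- header[-1]
  is_sig <- grepl("^sig_", cols)
  times <- suppressWarnings(as.numeric(cols[!is_sig]))
  assert_that(!anyNA(times), "non-numeric time column in header")
  sig_times <- suppressWarnings(as.numeric(sub("^sig_", "", cols[is_sig])))
  rows <- fields[-1]
  n <- length(rows)
  assert_that(n > 0, paste0("no data rows in ", path))
  bad <- which(purrr::map_int(rows, length) != length(header))
  if (length(bad)) {
    abort(paste0("parse error at line ", tsv$lineno[-1][bad[1]],
                 ": expected ", length(header), " fields"))
  }
  symbols <- harmonize_symbol(purrr::map_chr(rows, 1))
  assert_that(!anyDuplicated(symbols),
              paste0("duplicate symbol in ", path, ": ",
                     paste(unique(symbols[duplicated(symbols)]), collapse = ", ")))
  vals <- matrix(NA_real_, n, length(cols))
  for (i in seq_len(n)) {
    v <- suppressWarnings(as.numeric(rows[[i]][-1]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      abort(paste0("non-numeric cell at line ", tsv$lineno[-1][i],
                   ", column ", header[j + 1]))
    }
    vals[i, ] <- v
  }
  logfc <- vals[, !is_sig, drop = FALSE]
  if (scale == "ratio") {
    assert_that(all(logfc > 0), "ratio-scale values must be positive")
    logfc <- log2(logfc)
  }
  sig <- NULL
  if (any(is_sig)) {
    assert_that(all(sig_times %in% times) || all(sig_times %in% c(0, times)),
                "sig_ columns must match time columns")
    sig <- matrix(FALSE, n, length(times))
    sig[, match(sig_times, times)] <- vals[, is_sig, drop = FALSE] != 0
  }
  # insert baseline column if absent
  if (!any(times == 0)) {
    times <- c(0, times)
    logfc <- cbind(0, logfc)
    if (!is.null(sig)) sig <- cbind(FALSE, sig)
  }
  ord <- order(times)
  times <- times[ord]
  logfc <- logfc[, ord, drop = FALSE]
  if (!is.null(sig)) {
    sig <- sig[, ord, drop = FALSE]
    sig[, times == 0] <- FALSE
  }
  out <- omics_time_series(layer, symbols, times, logfc, sig)
  if (is.null(sig)) {
    if (layer == "transcript") {
      warn("transcript table has no sig_ columns; applying the fold-change rule as fallback")
    }
    out <- call_significant_fc(out, fold_threshold)
  }
  out
}

#' Write an omics time-course table (round-trips [load_omics_table()])
#' @param series An `omics_ts`.
#' @param path Output file.
#' @export
write_omics_table <- function(series, path) {
  tp <- series$timepoints
  header <- paste(c("symbol", tp, paste0("sig_", tp)), collapse = "\t")
  body <- vapply(seq_along(series$molecules), function(i) {
    paste(c(series$molecules[i], fmt_num(series$logfc[i, ]),
            as.integer(series$significant[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Call significance by fold change
#'
#' A molecule is significant at a post-baseline timepoint when its absolute
#' log2 fold change reaches `log2(fold_threshold)`; the rule is two-sided,
#' covering both a rise to `>= fold_threshold` and a drop to
#' `<= 1/fold_threshold`. Pre-existing flags are replaced; the baseline
#' stays `FALSE`.
#'
#' @param series An `omics_ts`.
#' @param fold_threshold Fold-change cutoff (> 1). Default 1.5.
#' @return The series with the `significant` matrix recomputed.
#' @export
call_significant_fc <- function(series, fold_threshold = 1.5) {
  assert_that(is.numeric(fold_threshold) && length(fold_threshold) == 1 &&
                fold_threshold > 1, "fold_threshold must be > 1")
  sig <- abs(series$logfc) >= log2(fold_threshold)
  sig[, series$timepoints == 0] <- FALSE
  series$significant <- sig
  series
}

#' Restrict two series to their shared time grid
#'
#' Both series are cut down to the sorted intersection of their time points
#' so coupled analyses see one common grid. An intersection containing only
#' the baseline is an error.
#'
#' @param a,b `omics_ts` objects (each must include baseline 0).
#' @return List with elements `a` and `b`, both on the common grid.
#' @export
restrict_to_common_timepoints <- function(a, b) {
  common <- sort(intersect(a$timepoints, b$timepoints))
  assert_that(length(common) >= 2 && common[1] == 0,
              "series share no post-baseline timepoints")
  list(a = subset_timepoints(a, common), b = subset_timepoints(b, common))
}

#' @noRd
subset_timepoints <- function(series, timepoints) {
  idx <- match(timepoints, series$timepoints)
  omics_time_series(series$layer, series$molecules, timepoints,
                    series$logfc[, idx, drop = FALSE],
                    series$significant[, idx, drop = FALSE])
}
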