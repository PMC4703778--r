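#' Phosphoprotein-anchored transcript/protein time-course integration
#'
#' For each measured phosphoprotein, collects its downstream consensus
#' transcripts - at every timepoint, the consensus genes that are targets
#' of the TFs of hit pathways containing that phosphoprotein - and maps
#' them to the proteome: transcripts whose protein is significantly
#' differentially abundant at at least one timepoint become matched
#' transcript/protein pairs carrying both logFC series; the rest are
#' reported as unmatched. A Pearson correlation between the two series is
#' attached to each matched pair as a descriptive summary of correlating
#' versus anti-correlating behavior.
#'
#' @param phospho Phosphoprotein `omics_ts` (anchors are its molecules).
#' @param down_results List of `downstream_result`, one per timepoint.
#' @param consensus_sets List of `consensus_set`, same timepoints.
#' @param transcripts Transcript `omics_ts` (source of transcript series).
#' @param proteome Protein `omics_ts` (source of protein series and
#'   significance).
#' @param kb A [knowledge_base()] (pathway membership and TF targets).
#' @return An `integration_result`: list with `anchors` (tibble: `anchor`,
#'   `symbol`, `matched`, `correlation`), `series` (long tibble: `anchor`,
#'   `symbol`, `layer`, `time`, `logfc`), and `timepoints`.
#' @export
integrate_time_courses <- function(phospho, down_results, consensus_sets,
                                   transcripts, proteome, kb) {
  tps_down <- purrr::map_dbl(down_results, "timepoint")
  tps_cons <- purrr::map_dbl(consensus_sets, "timepoint")
  assert_that(setequal(tps_down, tps_cons),
              "downstream results and consensus sets cover different timepoints")
  sig_any <- proteome$molecules[rowSums(proteome$significant) > 0]
  tf_tbl <- kb$tf_targets
  pw_genes <- kb$pathways$genes
  names(pw_genes) <- kb$pathways$pathway_id

  anchor_rows <- list()
  series_rows <- list()
  for (p in phospho$molecules) {
    downstream_transcripts <- character()
    for (i in seq_along(down_results)) {
      dr <- down_results[[i]]
      cs <- consensus_sets[[match(dr$timepoint, tps_cons)]]
      pw_with_p <- dr$pathway_hits[purrr::map_lgl(pw_genes[dr$pathway_hits],
                                                  function(g) p %in% g)]
      if (!length(pw_with_p)) next
      tfs_p <- intersect(dr$tfs,
                         unique(unlist(pw_genes[pw_with_p], use.names = FALSE)))
      targets_p <- unique(tf_tbl$target[tf_tbl$tf %in% tfs_p])
      downstream_transcripts <- union(downstream_transcripts,
                                      intersect(cs$genes, targets_p))
    }
    if (!length(downstream_transcripts)) next
    downstream_transcripts <- sort(downstream_transcripts)
    matched <- downstream_transcripts %in% sig_any
    corr <- rep(NA_real_, length(downstream_transcripts))
    for (j in which(matched)) {
      g <- downstream_transcripts[j]
      tr <- transcripts$logfc[g, ]
      pr <- proteome$logfc[g, ]
      corr[j] <- if (sd(tr) > 0 && sd(pr) > 0) stats::cor(tr, pr) else NA_real_
      series_rows[[length(series_rows) + 1]] <- tibble::tibble(
        anchor = p, symbol = g,
        layer = rep(c("transcript", "protein"), each = length(tr)),
        time = rep(transcripts$timepoints, 2),
        logfc = c(tr, pr)
      )
    }
    anchor_rows[[length(anchor_rows) + 1]] <- tibble::tibble(
      anchor = p, symbol = downstream_transcripts,
      matched = matched, correlation = corr
    )
  }
  anchors <- dplyr::bind_rows(anchor_rows)
  if (nrow(anchors) == 0) {
    anchors <- tibble::tibble(anchor = character(), symbol = character(),
                              matched = logical(), correlation = numeric())
  }
  series <- dplyr::bind_rows(series_rows)
  if (nrow(series) == 0) {
    series <- tibble::tibble(anchor = character(), symbol = character(),
                             layer = character(), time = numeric(),
                             logfc = numeric())
  }
  structure(list(anchors = anchors, series = series,
                 timepoints = transcripts$timepoints),
            class = "integration_result")
}

#' @export
print.integration_result <- function(x, ...) {
  cat("<integration_result> ", dplyr::n_distinct(x$anchors$anchor),
      " anchor phosphoprotein(s), ", sum(x$anchors$matched),
      " matched transcript/protein pair(s), ", sum(!x$anchors$matched),
      " unmatched transcript(s)\n", sep = "")
  invisible(x)
}

#' @describeIn integrate_time_courses the per-anchor match table.
#' @param x An `integration_result`.
#' @param ... Unused.
#' @export
tidy.integration_result <- function(x, ...) x$anchors

#' Write integration results as long-format TSV
#' @param x An `integration_result`.
#' @param path Output file.
#' @export
write_integration <- function(x, path) {
  a <- x$anchors
  matched_key <- paste(a$anchor, a$symbol)[a$matched]
  s <- x$series
  lines <- c("anchor\tsymbol\tlayer\ttime\tlogfc\tmatched")
  if (nrow(s)) {
    lines <- c(lines, paste(s$anchor, s$symbol, s$layer, fmt_num(s$time),
                            fmt_num(s$logfc),
                            as.integer(paste(s$anchor, s$symbol) %in% matched_key),
                            sep = "\t"))
  }
  if (any(!a$matched)) {
    un <- a[!a$matched, ]
    lines <- c(lines, paste(un$anchor, un$symbol, "transcript", "NA", "NA", 0L,
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
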