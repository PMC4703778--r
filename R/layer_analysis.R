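#' Downstream analysis of phosphoprotein data at one timepoint
#'
#' Maps the phosphoproteins significant at `timepoint` onto prior knowledge:
#' pathways are hit when their gene set contains a significant
#' phosphoprotein; the TFs of those pathways are the pathway members that
#' appear as TFs in the TF-target map; the potential target genes are the
#' union of those TFs' targets. Pathway membership is plain set
#' intersection - no enrichment statistic is computed.
#'
#' @param phospho Phosphoprotein `omics_ts`.
#' @param kb A [knowledge_base()].
#' @param timepoint Hour, must be present in the series.
#' @return A `downstream_result`: list with `timepoint`, `phosphoproteins`,
#'   `pathway_hits`, `tfs`, `target_genes` (all character vectors, sorted).
#' @export
run_downstream <- function(phospho, kb, timepoint) {
  sig <- significant_at(phospho, timepoint)
  hit <- purrr::map_lgl(kb$pathways$genes, function(g) any(sig %in% g))
  pathway_hits <- kb$pathways$pathway_id[hit]
  tf_universe <- unique(kb$tf_targets$tf)
  tfs <- sort(unique(unlist(purrr::map(kb$pathways$genes[hit],
                                       function(g) intersect(g, tf_universe)))))
  target_genes <- sort(unique(kb$tf_targets$target[kb$tf_targets$tf %in% tfs]))
  structure(list(timepoint = timepoint,
                 phosphoproteins = sort(sig),
                 pathway_hits = sort(pathway_hits),
                 tfs = tfs %||% character(),
                 target_genes = target_genes),
            class = "downstream_result")
}

#' @export
print.downstream_result <- function(x, ...) {
  cat("<downstream_result> t=", x$timepoint, "h: ",
      length(x$phosphoproteins), " phosphoproteins, ",
      length(x$pathway_hits), " pathways, ", length(x$tfs), " TFs, ",
      length(x$target_genes), " target genes\n", sep = "")
  invisible(x)
}

#' Upstream proteomic regulators of a TF set
#'
#' For each hit pathway, walks the pathway topology against the edge
#' direction, starting from every seed TF that is a member of that pathway,
#' up to `order` steps (default 10 orders of neighbors). Results are
#' unioned across pathways and seeds; the seed TFs themselves are excluded.
#' Edge sign is ignored for reachability.
#'
#' @param tfs Character vector of seed TF symbols.
#' @param pathways Pathway tibble rows (the hit pathways, with topology).
#' @param order Maximum traversal depth (>= 1). Default 10.
#' @return Sorted character vector of upstream protein symbols.
#' @export
upstream_regulators <- function(tfs, pathways, order = 10) {
  assert_that(is.numeric(order) && length(order) == 1 && order >= 1,
              "order must be >= 1")
  found <- character()
  for (i in seq_len(nrow(pathways))) {
    tp <- pathways$topology[[i]]
    if (nrow(tp) == 0) next
    seeds <- intersect(tfs, pathways$genes[[i]])
    if (!length(seeds)) next
    # predecessor adjacency: target -> sources
    preds <- split(tp$source, tp$target)
    for (s in seeds) {
      frontier <- s
      seen <- s
      depth <- 0
      while (length(frontier) && depth < order) {
        nxt <- setdiff(unique(unlist(preds[frontier], use.names = FALSE)), seen)
        seen <- c(seen, nxt)
        frontier <- nxt
        depth <- depth + 1
      }
      found <- union(found, setdiff(seen, s))
    }
  }
  sort(setdiff(found, tfs))
}

#' Upstream analysis of transcript data at one timepoint
#'
#' Identifies the TFs regulating the transcripts significant at `timepoint`
#' (a TF qualifies when at least one of its targets is significant), the
#' pathways containing at least `min_tfs` of those TFs, and the potential
#' upstream proteomic regulators reached by walking each hit pathway's
#' topology against the edge direction from its member TFs
#' ([upstream_regulators()]).
#'
#' @param transcripts_series Transcript `omics_ts`.
#' @param kb A [knowledge_base()].
#' @param timepoint Hour, must be present in the series.
#' @param min_tfs Minimum number of hit TFs a pathway must contain
#'   (default 1).
#' @param order Upstream traversal depth (default 10).
#' @return An `upstream_result`: list with `timepoint`, `transcripts`,
#'   `tfs`, `pathway_hits`, `regulators`.
#' @export
run_upstream <- function(transcripts_series, kb, timepoint, min_tfs = 1,
                         order = 10) {
  sig <- significant_at(transcripts_series, timepoint)
  tf_tbl <- kb$tf_targets
  tfs <- sort(unique(tf_tbl$tf[tf_tbl$target %in% sig]))
  hit <- purrr::map_lgl(kb$pathways$genes,
                        function(g) sum(tfs %in% g) >= min_tfs)
  pathway_hits <- kb$pathways$pathway_id[hit]
  regulators <- if (any(hit)) {
    upstream_regulators(tfs, kb$pathways[hit, , drop = FALSE], order = order)
  } else {
    character()
  }
  structure(list(timepoint = timepoint,
                 transcripts = sort(sig),
                 tfs = tfs,
                 pathway_hits = sort(pathway_hits),
                 regulators = regulators),
            class = "upstream_result")
}

#' @export
print.upstream_result <- function(x, ...) {
  cat("<upstream_result> t=", x$timepoint, "h: ",
      length(x$transcripts), " transcripts, ", length(x$tfs), " TFs, ",
      length(x$pathway_hits), " pathways, ",
      length(x$regulators), " regulators\n", sep = "")
  invisible(x)
}

#' @describeIn run_downstream long-format view: one row per molecule with
#'   its layer role.
#' @param x A `downstream_result`.
#' @param ... Unused.
#' @export
tidy.downstream_result <- function(x, ...) {
  tibble::tibble(
    timepoint = x$timepoint,
    role = rep(c("phosphoprotein", "pathway", "tf", "target_gene"),
               c(length(x$phosphoproteins), length(x$pathway_hits),
                 length(x$tfs), length(x$target_genes))),
    id = c(x$phosphoproteins, x$pathway_hits, x$tfs, x$target_genes)
  )
}

#' @describeIn run_upstream long-format view: one row per molecule with its
#'   layer role.
#' @param x An `upstream_result`.
#' @param ... Unused.
#' @export
tidy.upstream_result <- function(x, ...) {
  tibble::tibble(
    timepoint = x$timepoint,
    role = rep(c("transcript", "tf", "pathway", "regulator"),
               c(length(x$transcripts), length(x$tfs),
                 length(x$pathway_hits), length(x$regulators))),
    id = c(x$transcripts, x$tfs, x$pathway_hits, x$regulators)
  )
}
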