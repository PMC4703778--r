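#' Prior-knowledge container: pathways, TF targets, PPI network
#'
#' Bundles the three knowledge resources every analysis stage draws on:
#' pathway gene sets with optional per-pathway directed topology, a
#' transcription factor to target-gene map, and a confidence-scored
#' protein-protein interaction network. All symbols are assumed to live in
#' one harmonized namespace (see [harmonize_symbol()]); the constructor
#' validates the component invariants.
#'
#' @param pathways Pathway tibble as returned by [load_gene_sets()] /
#'   [load_topology()]: columns `pathway_id`, `name`, `source_db`,
#'   `genes` (list of character), `topology` (list of tibbles with columns
#'   `source`, `target`, `effect`).
#' @param tf_targets Tibble with columns `tf` and `target`, one row per
#'   TF-target interaction.
#' @param ppi Undirected `igraph` with edge attribute `score` in (0, 1],
#'   as returned by [load_ppi()].
#' @return A `knowledge_base` object (list with elements `pathways`,
#'   `tf_targets`, `ppi`).
#' @export
knowledge_base <- function(pathways, tf_targets, ppi) {
  validate_pathways(pathways)
  validate_tf_targets(tf_targets)
  validate_ppi(ppi)
  structure(list(pathways = pathways, tf_targets = tf_targets, ppi = ppi),
            class = "knowledge_base")
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("<knowledge_base>\n")
  cat("  pathways:   ", nrow(x$pathways), " (",
      sum(purrr::map_int(x$pathways$topology, nrow) > 0), " with topology)\n", sep = "")
  cat("  TF-targets: ", nrow(x$tf_targets), " pairs, ",
      dplyr::n_distinct(x$tf_targets$tf), " TFs\n", sep = "")
  cat("  PPI:        ", igraph::vcount(x$ppi), " proteins, ",
      igraph::ecount(x$ppi), " edges\n", sep = "")
  invisible(x)
}

#' @noRd
empty_topology <- function() {
  tibble::tibble(source = character(), target = character(), effect = character())
}

#' @noRd
validate_pathways <- function(pathways) {
  need <- c("pathway_id", "name", "source_db", "genes", "topology")
  assert_that(all(need %in% names(pathways)),
              paste0("pathway table must have columns: ", paste(need, collapse = ", ")))
  assert_that(!anyDuplicated(pathways$pathway_id), "duplicate pathway_id")
  assert_that(all(purrr::map_int(pathways$genes, length) > 0),
              "every pathway must have a non-empty gene set")
  ok <- purrr::map2_lgl(pathways$genes, pathways$topology, function(g, tp) {
    all(c(tp$source, tp$target) %in% g)
  })
  assert_that(all(ok), "topology endpoints must be members of the pathway gene set")
  invisible(pathways)
}

#' @noRd
validate_tf_targets <- function(tf_targets) {
  assert_that(all(c("tf", "target") %in% names(tf_targets)),
              "tf_targets must have columns tf, target")
  assert_that(nrow(tf_targets) > 0, "TF-target map must be non-empty")
  invisible(tf_targets)
}

#' @noRd
validate_ppi <- function(ppi) {
  assert_that(igraph::is_igraph(ppi) && !igraph::is_directed(ppi),
              "ppi must be an undirected igraph")
  if (igraph::ecount(ppi) > 0) {
    s <- igraph::E(ppi)$score
    assert_that(!is.null(s) && all(s > 0 & s <= 1), "PPI scores must lie in (0, 1]")
    assert_that(!any(igraph::which_loop(ppi)), "PPI must not contain self-loops")
  }
  assert_that(igraph::count_components(ppi) <= 1, "PPI must be connected")
  invisible(ppi)
}

# ---- readers -----------------------------------------------------------

#' Load pathway gene sets from a GMT file
#'
#' One pathway per line: `id<TAB>description<TAB>gene1<TAB>gene2...`.
#' Lines starting with `#` are skipped. Gene symbols are harmonized and
#' deduplicated; topology starts out empty (attach it with
#' [load_topology()]).
#'
#' @param path Path to a GMT file.
#' @param source_db Label recorded in the `source_db` column.
#' @param alias_table Optional alias mapping passed to [harmonize_symbol()].
#' @return Pathway tibble (see [knowledge_base()]).
#' @export
load_gene_sets <- function(path, source_db = "custom", alias_table = NULL) {
  tsv <- read_tsv_lines(path)
  fields <- split_tab(tsv$lines)
  bad <- which(purrr::map_int(fields, length) < 3L)
  if (length(bad)) {
    abort(paste0("GMT parse error at line ", tsv$lineno[bad[1]],
                 ": expected at least 3 tab-separated fields"))
  }
  out <- tibble::tibble(
    pathway_id = purrr::map_chr(fields, 1),
    name = purrr::map_chr(fields, 2),
    source_db = source_db,
    genes = purrr::map(fields, function(f) {
      unique(harmonize_symbol(f[-(1:2)], alias_table))
    }),
    topology = purrr::map(fields, function(f) empty_topology())
  )
  assert_that(!anyDuplicated(out$pathway_id),
              paste0("duplicate pathway_id in ", path))
  validate_pathways(out)
}

#' Attach directed topology edges to loaded pathways
#'
#' Reads a 4-column tab-separated edge list with header
#' `pathway_id<TAB>source<TAB>interaction<TAB>target` and attaches each edge
#' to its pathway. Interaction must be one of `activation`, `inhibition`,
#' `unknown`. Edge endpoints missing from the pathway's gene set are added
#' to it with a warning, keeping the membership invariant intact. Duplicate
#' `(source, target, effect)` rows are collapsed.
#'
#' @param path Path to the topology file.
#' @param pathways Pathway tibble from [load_gene_sets()].
#' @param alias_table Optional alias mapping passed to [harmonize_symbol()].
#' @return The pathway tibble with `topology` (and possibly `genes`) updated.
#' @export
load_topology <- function(path, pathways, alias_table = NULL) {
  validate_pathways(pathways)
  tsv <- read_tsv_lines(path)
  fields <- split_tab(tsv$lines)
  bad <- which(purrr::map_int(fields, length) != 4L)
  if (length(bad)) {
    abort(paste0("topology parse error at line ", tsv$lineno[bad[1]],
                 ": expected 4 tab-separated fields"))
  }
  df <- tibble::tibble(
    pathway_id = purrr::map_chr(fields, 1),
    source = purrr::map_chr(fields, 2),
    effect = tolower(trimws(purrr::map_chr(fields, 3))),
    target = purrr::map_chr(fields, 4)
  )
  # drop header row if present
  if (nrow(df) && identical(tolower(df$pathway_id[1]), "pathway_id")) {
    df <- df[-1, , drop = FALSE]
  }
  allowed <- c("activation", "inhibition", "unknown")
  bad_tok <- setdiff(unique(df$effect), allowed)
  if (length(bad_tok)) {
    abort(paste0("unknown interaction token(s): ", paste(bad_tok, collapse = ", "),
                 "; allowed: ", paste(allowed, collapse = ", ")))
  }
  unknown_pw <- setdiff(unique(df$pathway_id), pathways$pathway_id)
  if (length(unknown_pw)) {
    abort(paste0("topology refers to unknown pathway_id: ",
                 paste(unknown_pw, collapse = ", ")))
  }
  df$source <- harmonize_symbol(df$source, alias_table)
  df$target <- harmonize_symbol(df$target, alias_table)
  for (pw in unique(df$pathway_id)) {
    i <- match(pw, pathways$pathway_id)
    edges <- dplyr::distinct(df[df$pathway_id == pw, c("source", "target", "effect")])
    extra <- setdiff(unique(c(edges$source, edges$target)), pathways$genes[[i]])
    if (length(extra)) {
      warn(paste0("pathway ", pw, ": topology endpoint(s) not in gene set, added: ",
                  paste(extra, collapse = ", ")))
      pathways$genes[[i]] <- c(pathways$genes[[i]], extra)
    }
    pathways$topology[[i]] <- edges
  }
  validate_pathways(pathways)
}

#' Load a TF to target-gene map
#'
#' Two tab-separated columns `(TF symbol, target symbol)`; `#` comment lines
#' and an optional `tf<TAB>target` header are skipped; duplicate rows are
#' collapsed after symbol harmonization.
#'
#' @inheritParams load_gene_sets
#' @return Tibble with columns `tf`, `target`.
#' @export
load_tf_targets <- function(path, alias_table = NULL) {
  tsv <- read_tsv_lines(path)
  fields <- split_tab(tsv$lines)
  bad <- which(purrr::map_int(fields, length) < 2L)
  if (length(bad)) {
    abort(paste0("TF-target parse error at line ", tsv$lineno[bad[1]],
                 ": expected 2 tab-separated fields"))
  }
  df <- tibble::tibble(tf = purrr::map_chr(fields, 1),
                       target = purrr::map_chr(fields, 2))
  if (nrow(df) && identical(tolower(df$tf[1]), "tf")) df <- df[-1, , drop = FALSE]
  assert_that(nrow(df) > 0, paste0("TF-target file is empty: ", path))
  df$tf <- harmonize_symbol(df$tf, alias_table)
  df$target <- harmonize_symbol(df$target, alias_table)
  validate_tf_targets(dplyr::arrange(dplyr::distinct(df), .data$tf, .data$target))
}

#' Load a scored protein-protein interaction network
#'
#' Three tab-separated columns `(node, node, score)`. Scores on a 0-1000
#' scale (any score > 1, STRING convention) are divided by 1000. Edges below
#' `min_score` and self-loops are dropped, duplicate node pairs keep the
#' highest score, and only the largest connected component is retained (the
#' number of dropped nodes is reported).
#'
#' @inheritParams load_gene_sets
#' @param min_score Minimum combined confidence score kept, on the (0, 1]
#'   scale. Default 0.4, the usual medium-confidence cutoff.
#' @return Undirected `igraph`; edge attributes `score` (confidence) and
#'   `weight` (`1 - score`, the shortest-path length used downstream).
#' @export
load_ppi <- function(path, min_score = 0.4, alias_table = NULL) {
  tsv <- read_tsv_lines(path)
  fields <- split_tab(tsv$lines)
  bad <- which(purrr::map_int(fields, length) < 3L)
  if (length(bad)) {
    abort(paste0("PPI parse error at line ", tsv$lineno[bad[1]],
                 ": expected 3 tab-separated fields"))
  }
  df <- tibble::tibble(a = purrr::map_chr(fields, 1),
                       b = purrr::map_chr(fields, 2),
                       score = purrr::map_chr(fields, 3))
  if (nrow(df) && is.na(suppressWarnings(as.numeric(df$score[1])))) {
    df <- df[-1, , drop = FALSE]  # header row
  }
  score <- suppressWarnings(as.numeric(df$score))
  if (anyNA(score)) {
    abort(paste0("non-numeric PPI score at line ",
                 tsv$lineno[which(is.na(score))[1]]))
  }
  if (any(score > 1)) score <- score / 1000
  assert_that(all(score > 0 & score <= 1), "PPI scores must lie in (0, 1] after scaling")
  df <- tibble::tibble(a = harmonize_symbol(df$a, alias_table),
                       b = harmonize_symbol(df$b, alias_table),
                       score = score)
  df <- df[df$score >= min_score & df$a != df$b, , drop = FALSE]
  assert_that(nrow(df) > 0, "PPI network is empty after score filtering")
  # canonical undirected key; keep best-scoring duplicate
  key_a <- pmin(df$a, df$b); key_b <- pmax(df$a, df$b)
  df <- tibble::tibble(a = key_a, b = key_b, score = df$score) |>
    dplyr::group_by(.data$a, .data$b) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop") |>
    dplyr::arrange(.data$a, .data$b)
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  dropped <- igraph::vcount(g) - length(keep)
  if (dropped > 0) {
    inform(paste0("load_ppi: dropped ", dropped,
                  " node(s) outside the largest connected component"))
  }
  g <- igraph::induced_subgraph(g, keep)
  igraph::E(g)$weight <- 1 - igraph::E(g)$score
  assert_that(igraph::vcount(g) > 0, "PPI network is empty")
  g
}

# ---- writers (round-trip the reader formats) ---------------------------

#' Write pathway gene sets as GMT
#' @param pathways Pathway tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(pathways, path) {
  lines <- purrr::pmap_chr(pathways[c("pathway_id", "name", "genes")],
                           function(pathway_id, name, genes) {
                             paste(c(pathway_id, name, genes), collapse = "\t")
                           })
  writeLines(lines, path)
  invisible(path)
}

#' Write pathway topology as 4-column TSV
#' @inheritParams write_gene_sets
#' @export
write_topology <- function(pathways, path) {
  rows <- purrr::map2(pathways$pathway_id, pathways$topology, function(id, tp) {
    if (nrow(tp) == 0) return(character())
    paste(id, tp$source, tp$effect, tp$target, sep = "\t")
  })
  writeLines(c("pathway_id\tsource\tinteraction\ttarget", unlist(rows)), path)
  invisible(path)
}

#' Write a TF-target map as 2-column TSV
#' @param tf_targets Tibble with columns `tf`, `target`.
#' @param path Output file.
#' @export
write_tf_targets <- function(tf_targets, path) {
  writeLines(c("tf\ttarget", paste(tf_targets$tf, tf_targets$target, sep = "\t")), path)
  invisible(path)
}

#' Write a PPI network as 3-column TSV
#' @param ppi Undirected igraph with edge attribute `score`.
#' @param path Output file.
#' @export
write_ppi <- function(ppi, path) {
  el <- igraph::as_edgelist(ppi)
  writeLines(c("protein_a\tprotein_b\tscore",
               paste(el[, 1], el[, 2], fmt_num(igraph::E(ppi)$score), sep = "\t")),
             path)
  invisible(path)
}
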