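#' Layer-wise consensus molecules at one timepoint
#'
#' Intersects the downstream and upstream analysis results on each cellular
#' layer: consensus proteins are the phosphoproteins significant at the
#' timepoint that also appear among the upstream proteomic regulators;
#' consensus TFs are found by both analyses; consensus genes are downstream
#' target genes that are also significantly regulated transcripts.
#'
#' @param down A `downstream_result`.
#' @param up An `upstream_result` at the same timepoint.
#' @param phospho Phosphoprotein `omics_ts`.
#' @return A `consensus_set`: list with `timepoint`, `proteins`, `tfs`,
#'   `genes` (sorted character vectors).
#' @export
intersect_layers <- function(down, up, phospho) {
  assert_that(identical(down$timepoint, up$timepoint),
              "downstream and upstream results are for different timepoints")
  sig <- significant_at(phospho, down$timepoint)
  structure(list(
    timepoint = down$timepoint,
    proteins = sort(intersect(sig, up$regulators)),
    tfs = sort(intersect(down$tfs, up$tfs)),
    genes = sort(intersect(down$target_genes, up$transcripts))
  ), class = "consensus_set")
}

#' @export
print.consensus_set <- function(x, ...) {
  cat("<consensus_set> t=", x$timepoint, "h: P={",
      paste(x$proteins, collapse = ","), "} TF={",
      paste(x$tfs, collapse = ","), "} T={",
      paste(x$genes, collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' @describeIn intersect_layers one row per consensus molecule with its
#'   layer.
#' @param x A `consensus_set`.
#' @param ... Unused.
#' @export
tidy.consensus_set <- function(x, ...) {
  tibble::tibble(
    timepoint = x$timepoint,
    layer = rep(c("protein", "tf", "gene"),
                c(length(x$proteins), length(x$tfs), length(x$genes))),
    symbol = c(x$proteins, x$tfs, x$genes)
  )
}

#' Static consensus graph for one timepoint
#'
#' Maps the consensus proteins and TFs onto the PPI network and connects
#' them with the Steiner-tree approximation ([steiner_tree()]); non-terminal
#' connector nodes become `steiner`-layer nodes. The graph is completed with
#' directed `tf_target` edges between consensus TFs and the consensus genes
#' they regulate, and with a directed `feedback` edge from a gene-layer node
#' to the protein-layer node of the same symbol whenever both are present.
#' Consensus molecules that end up without any edge are kept as isolated
#' nodes, so graph membership always reflects consensus membership.
#'
#' @param cs A `consensus_set`.
#' @param kb A [knowledge_base()].
#' @param weighted Passed to [steiner_tree()].
#' @return A `consensus_graph`: directed `igraph` whose vertices carry
#'   `symbol` and `layer` (`protein`, `tf`, `gene`, `steiner`) and whose
#'   edges carry `kind` (`ppi_steiner`, stored once per undirected PPI edge;
#'   `tf_target`; `feedback`) and `weight`. The timepoint is stored as a
#'   graph attribute.
#' @export
build_consensus_graph <- function(cs, kb, weighted = TRUE) {
  terminals <- sort(union(cs$proteins, cs$tfs))
  st <- if (length(terminals)) steiner_tree(kb$ppi, terminals, weighted = weighted)
        else igraph::make_empty_graph(0, directed = FALSE)
  st_names <- if (igraph::vcount(st)) igraph::V(st)$name else character()
  steiner_nodes <- setdiff(st_names, terminals)

  layer_of <- function(s) {
    out <- rep("steiner", length(s))
    out[s %in% cs$proteins] <- "protein"
    out[s %in% cs$tfs] <- "tf"
    out
  }
  ppi_syms <- sort(union(terminals, st_names))
  nodes <- tibble::tibble(symbol = ppi_syms, layer = layer_of(ppi_syms))
  nodes <- dplyr::bind_rows(
    nodes,
    tibble::tibble(symbol = cs$genes, layer = "gene")
  )
  nodes$id <- paste(nodes$layer, nodes$symbol, sep = ":")
  nodes <- dplyr::arrange(
    nodes,
    factor(.data$layer, levels = c("protein", "tf", "gene", "steiner")),
    .data$symbol
  )

  edges <- tibble::tibble(from = character(), to = character(),
                          kind = character(), weight = numeric())
  if (igraph::ecount(st) > 0) {
    el <- igraph::as_edgelist(st)
    id_of <- function(s) nodes$id[match(s, nodes$symbol)]
    edges <- dplyr::bind_rows(edges, tibble::tibble(
      from = id_of(el[, 1]), to = id_of(el[, 2]),
      kind = "ppi_steiner", weight = igraph::E(st)$weight
    ))
  }
  tt <- kb$tf_targets[kb$tf_targets$tf %in% cs$tfs &
                        kb$tf_targets$target %in% cs$genes, , drop = FALSE]
  if (nrow(tt)) {
    edges <- dplyr::bind_rows(edges, tibble::tibble(
      from = paste0("tf:", tt$tf), to = paste0("gene:", tt$target),
      kind = "tf_target", weight = 1
    ))
  }
  fb <- intersect(cs$genes, cs$proteins)
  fb <- fb[paste0("protein:", fb) %in% nodes$id]
  if (length(fb)) {
    edges <- dplyr::bind_rows(edges, tibble::tibble(
      from = paste0("gene:", sort(fb)), to = paste0("protein:", sort(fb)),
      kind = "feedback", weight = 1
    ))
  }
  edges <- dplyr::arrange(edges, .data$kind, .data$from, .data$to)

  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = nodes$id, symbol = nodes$symbol,
                          layer = nodes$layer)
  )
  g$timepoint <- cs$timepoint
  g$steiner_nodes <- sort(steiner_nodes)
  class(g) <- c("consensus_graph", class(g))
  g
}

#' @export
print.consensus_graph <- function(x, ...) {
  kinds <- if (igraph::ecount(x)) table(igraph::E(x)$kind) else table(character())
  cat("<consensus_graph> t=", x$timepoint, "h: ", igraph::vcount(x),
      " nodes (", sum(igraph::V(x)$layer == "steiner"), " steiner), edges: ",
      paste(names(kinds), as.integer(kinds), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Static consensus profiles across timepoints
#'
#' Boolean presence matrix of every `(symbol, layer)` node over the
#' analyzed timepoints: a cell is `TRUE` when that molecule is part of the
#' consensus graph at that timepoint. Steiner nodes appear as
#' `steiner`-layer rows.
#'
#' @param graphs List of `consensus_graph` objects at distinct timepoints.
#' @return A `consensus_profiles` tibble: columns `symbol`, `layer`, then
#'   one logical column per timepoint (named by the hour); rows sorted by
#'   layer then symbol. An empty graph list gives a zero-column matrix.
#' @export
consensus_profiles <- function(graphs) {
  tps <- purrr::map_dbl(graphs, function(g) g$timepoint)
  assert_that(!anyDuplicated(tps), "duplicate timepoints in graph list")
  ord <- order(tps)
  graphs <- graphs[ord]
  tps <- tps[ord]
  if (length(graphs) == 0) {
    out <- tibble::tibble(symbol = character(), layer = character())
    attr(out, "timepoints") <- numeric()
    class(out) <- c("consensus_profiles", class(out))
    return(out)
  }
  node_tbl <- purrr::map2(graphs, tps, function(g, tp) {
    if (igraph::vcount(g) == 0) {
      return(tibble::tibble(symbol = character(), layer = character(),
                            timepoint = numeric()))
    }
    tibble::tibble(symbol = igraph::V(g)$symbol, layer = igraph::V(g)$layer,
                   timepoint = tp)
  }) |> dplyr::bind_rows()
  rows <- dplyr::distinct(node_tbl[c("symbol", "layer")])
  rows <- dplyr::arrange(
    rows,
    factor(.data$layer, levels = c("protein", "tf", "gene", "steiner")),
    .data$symbol
  )
  out <- rows
  for (tp in tps) {
    present <- node_tbl[node_tbl$timepoint == tp, ]
    out[[as.character(tp)]] <- paste(rows$symbol, rows$layer) %in%
      paste(present$symbol, present$layer)
  }
  attr(out, "timepoints") <- tps
  class(out) <- c("consensus_profiles", class(out))
  out
}

#' Write a consensus graph as GraphML or SIF
#' @param graph A `consensus_graph`.
#' @param path Output file.
#' @param format `"graphml"` or `"sif"`.
#' @export
write_consensus_graph <- function(graph, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- graph
    class(g) <- "igraph"
    # graphml holds scalar attributes only
    g <- igraph::set_graph_attr(g, "steiner_nodes",
                                paste(igraph::graph_attr(g, "steiner_nodes"),
                                      collapse = ","))
    igraph::write_graph(g, path, format = "graphml")
  } else {
    if (igraph::ecount(graph) == 0) {
      writeLines(igraph::V(graph)$name, path)
    } else {
      el <- igraph::as_edgelist(graph)
      iso <- setdiff(igraph::V(graph)$name, c(el[, 1], el[, 2]))
      writeLines(c(paste(el[, 1], igraph::E(graph)$kind, el[, 2], sep = "\t"),
                   iso), path)
    }
  }
  invisible(path)
}

#' Write consensus profiles as a 0/1 TSV
#' @param profiles A `consensus_profiles` tibble.
#' @param path Output file.
#' @export
write_profiles <- function(profiles, path) {
  df <- as.data.frame(profiles)
  for (j in seq(3, ncol(df))) df[[j]] <- as.integer(df[[j]])
  lines <- c(paste(colnames(df), collapse = "\t"),
             apply(df, 1, paste, collapse = "\t"))
  writeLines(gsub(" ", "", lines, fixed = TRUE), path)
  invisible(path)
}
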