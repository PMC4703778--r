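# Shortest-paths (metric closure) 2-approximation of the Steiner tree
# connecting a terminal set in the scored PPI network. All tie-breaks are
# lexicographic so identical inputs give identical trees.

#' Steiner-tree approximation on the PPI network
#'
#' Connects a set of terminal proteins in the PPI network with the
#' metric-closure 2-approximation: (1) all-pairs shortest paths between
#' terminals (edge length `1 - score`, or 1 in unweighted mode); (2) minimum
#' spanning tree of that terminal closure; (3) expansion of each closure
#' edge into its underlying shortest path; (4) minimum spanning tree of the
#' expanded subgraph; (5) iterative pruning of non-terminal leaves.
#' Non-terminal nodes of the result are the Steiner nodes. Terminals lying
#' in different connected components yield a forest (one tree per group).
#'
#' Shortest-path ties are broken toward the lexicographically smallest node
#' sequence and spanning-tree ties by sorted edge key, so the result is
#' deterministic. The returned tree weight is at most
#' `2 * (1 - 1/k)` times the optimum for `k` terminals.
#'
#' @param ppi Undirected `igraph` with edge attribute `weight`
#'   (`1 - score`; see [load_ppi()]).
#' @param terminals Character vector of terminal symbols. Terminals absent
#'   from the network are dropped with a warning.
#' @param weighted Use confidence-derived edge lengths (`TRUE`, default) or
#'   unit lengths (`FALSE`).
#' @return Undirected `igraph` (a tree or forest) with logical vertex
#'   attribute `terminal`; no terminals present gives an empty graph with a
#'   warning.
#' @export
steiner_tree <- function(ppi, terminals, weighted = TRUE) {
  terminals <- unique(harmonize_symbol(terminals))
  present <- intersect(terminals, igraph::V(ppi)$name)
  missing <- setdiff(terminals, present)
  if (length(missing)) {
    warn(paste0("steiner_tree: terminal(s) not in PPI, dropped: ",
                paste(missing, collapse = ", ")))
  }
  if (!length(present)) {
    warn("steiner_tree: no terminal present in the PPI network")
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(g)
  }
  w <- if (weighted) igraph::E(ppi)$weight else rep(1, igraph::ecount(ppi))
  comp <- igraph::components(ppi)
  groups <- split(present, comp$membership[match(present, igraph::V(ppi)$name)])

  trees <- purrr::map(groups, function(term) steiner_one_component(ppi, term, w))
  nodes <- unique(unlist(purrr::map(trees, "nodes")))
  edges <- dplyr::bind_rows(purrr::map(trees, "edges"))
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(sort(nodes))
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(edges$a, edges$b))
    igraph::E(g)$weight <- edges$w
  }
  igraph::V(g)$terminal <- igraph::V(g)$name %in% present
  g
}

#' @noRd
steiner_one_component <- function(ppi, term, w) {
  term <- sort(term)
  if (length(term) == 1L) {
    return(list(nodes = term,
                edges = tibble::tibble(a = character(), b = character(),
                                       w = numeric())))
  }
  dmat <- igraph::distances(ppi, v = term, to = term, weights = w)
  # (2) MST of the terminal metric closure
  k <- length(term)
  closure <- tibble::tibble(
    a = term[rep(seq_len(k - 1), times = (k - 1):1)],
    b = term[unlist(lapply(2:k, function(i) i:k))],
    w = dmat[cbind(rep(seq_len(k - 1), times = (k - 1):1),
                   unlist(lapply(2:k, function(i) i:k)))]
  )
  mst_closure <- kruskal_mst(closure, term)
  # (3) expand closure edges into lexicographically smallest shortest paths
  path_edges <- purrr::map2(mst_closure$a, mst_closure$b, function(a, b) {
    lex_shortest_path_edges(ppi, a, b, w_all = w)
  })
  sub <- dplyr::distinct(dplyr::bind_rows(path_edges))
  # (4) MST of the expanded subgraph, (5) prune non-terminal leaves
  nodes <- sort(unique(c(sub$a, sub$b, term)))
  tree <- kruskal_mst(sub, nodes)
  prune_nonterminal_leaves(tree, term, nodes)
}

#' Lexicographically smallest shortest path a -> b, as an edge tibble
#' @noRd
lex_shortest_path_edges <- function(g, a, b, w_all) {
  w <- w_all %||% igraph::E(g)$weight
  d_to_b <- igraph::distances(g, v = b, weights = w)[1, ]
  path <- a
  u <- a
  tol <- 1e-9
  while (u != b) {
    inc <- igraph::incident(g, u)
    nb <- igraph::V(g)$name[igraph::ends(g, inc, names = FALSE)]
    nb <- matrix(nb, ncol = 2)
    other <- ifelse(nb[, 1] == u, nb[, 2], nb[, 1])
    wc <- w[as.integer(inc)]
    ok <- abs(wc + d_to_b[other] - d_to_b[u]) <= tol * (1 + abs(d_to_b[u]))
    cand <- other[ok]
    assert_that(length(cand) > 0, "internal: shortest-path reconstruction failed")
    v <- sort(cand)[1]
    path <- c(path, v)
    u <- v
  }
  tibble::tibble(a = pmin(path[-length(path)], path[-1]),
                 b = pmax(path[-length(path)], path[-1]),
                 w = w[igraph::get_edge_ids(g, rbind(path[-length(path)], path[-1]))])
}

#' Deterministic Kruskal MST over an edge tibble (a, b, w)
#' @noRd
kruskal_mst <- function(edges, nodes) {
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  edges <- dplyr::arrange(edges, .data$w, .data$a, .data$b)
  keep <- logical(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    ra <- find(match(edges$a[e], nodes))
    rb <- find(match(edges$b[e], nodes))
    if (ra != rb) {
      parent[ra] <- rb
      keep[e] <- TRUE
    }
  }
  edges[keep, , drop = FALSE]
}

#' @noRd
prune_nonterminal_leaves <- function(edges, term, nodes) {
  repeat {
    deg <- table(c(edges$a, edges$b))
    leaves <- setdiff(names(deg)[deg == 1], term)
    if (!length(leaves)) break
    edges <- edges[!(edges$a %in% leaves | edges$b %in% leaves), , drop = FALSE]
  }
  list(nodes = sort(unique(c(term, edges$a, edges$b))), edges = edges)
}
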