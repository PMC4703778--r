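# Shared builders and independent oracles used across the suite.

# small undirected scored graph from a 2-column edge matrix
mk_ppi <- function(edges, scores = NULL) {
  g <- igraph::graph_from_data_frame(as.data.frame(edges), directed = FALSE)
  igraph::E(g)$score <- if (is.null(scores)) rep(0.5, igraph::ecount(g)) else scores
  igraph::E(g)$weight <- 1 - igraph::E(g)$score
  g
}

mk_pathway_tbl <- function(ids, gene_sets, topologies = NULL) {
  tibble::tibble(
    pathway_id = ids,
    name = ids,
    source_db = "test",
    genes = gene_sets,
    topology = topologies %||%
      purrr::map(ids, ~ tibble::tibble(source = character(),
                                       target = character(),
                                       effect = character()))
  )
}

mk_series <- function(layer, molecules, timepoints, logfc) {
  call_significant_fc(omics_time_series(layer, molecules, timepoints, logfc))
}

mk_dense <- function(Y, standardize = TRUE) {
  if (standardize) Y <- (Y - rowMeans(Y)) / apply(Y, 1, sd)
  structure(list(molecules = rownames(Y), grid = seq_len(ncol(Y)),
                 values = Y, standardized = standardize, smoothing = "gcv",
                 times_measured = NULL),
            class = "dense_ts")
}

# simulate a stationary VAR(1) y_t = D y_{t-1} + N(0, sd^2)
sim_var1 <- function(D, T_, sd = 1, seed = 1, burn = 50) {
  set.seed(seed)
  P <- nrow(D)
  y <- matrix(0, P, T_ + burn)
  y[, 1] <- rnorm(P, sd = sd)
  for (t in 2:(T_ + burn)) y[, t] <- D %*% y[, t - 1] + rnorm(P, sd = sd)
  out <- y[, (burn + 1):(burn + T_), drop = FALSE]
  rownames(out) <- paste0("m", seq_len(P))
  out
}

# exhaustive Steiner optimum: try every subset of non-terminal vertices
steiner_opt_weight <- function(g, terminals) {
  vs <- igraph::V(g)$name
  others <- setdiff(vs, terminals)
  best <- Inf
  for (mask in 0:(2^length(others) - 1)) {
    extra <- others[bitwAnd(mask, 2^(seq_along(others) - 1)) > 0]
    sub <- igraph::induced_subgraph(g, c(terminals, extra))
    if (igraph::count_components(sub) != 1) next
    mst <- igraph::mst(sub, weights = igraph::E(sub)$weight)
    w <- sum(igraph::E(mst)$weight)
    if (w < best) best <- w
  }
  best
}

# brute-force set-comprehension oracle for the downstream analysis
oracle_downstream <- function(phospho, kb, timepoint) {
  ti <- which(phospho$timepoints == timepoint)
  sig <- phospho$molecules[phospho$significant[, ti]]
  hits <- character(); tfs <- character(); targets <- character()
  for (i in seq_len(nrow(kb$pathways))) {
    if (length(intersect(kb$pathways$genes[[i]], sig)) > 0) {
      hits <- c(hits, kb$pathways$pathway_id[i])
      for (g in kb$pathways$genes[[i]]) {
        if (g %in% kb$tf_targets$tf) tfs <- c(tfs, g)
      }
    }
  }
  tfs <- unique(tfs)
  for (tf in tfs) targets <- c(targets, kb$tf_targets$target[kb$tf_targets$tf == tf])
  list(phosphoproteins = sort(sig), pathway_hits = sort(hits),
       tfs = sort(tfs), target_genes = sort(unique(targets)))
}

# brute-force oracle for the upstream analysis (reachability by matrix power)
oracle_upstream <- function(transcripts, kb, timepoint, min_tfs = 1, order = 10) {
  ti <- which(transcripts$timepoints == timepoint)
  sig <- transcripts$molecules[transcripts$significant[, ti]]
  tfs <- sort(unique(kb$tf_targets$tf[kb$tf_targets$target %in% sig]))
  hits <- character(); regulators <- character()
  for (i in seq_len(nrow(kb$pathways))) {
    if (length(intersect(tfs, kb$pathways$genes[[i]])) >= min_tfs) {
      hits <- c(hits, kb$pathways$pathway_id[i])
      tp <- kb$pathways$topology[[i]]
      nodes <- kb$pathways$genes[[i]]
      if (nrow(tp) == 0) next
      A <- matrix(0, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
      A[cbind(tp$source, tp$target)] <- 1   # source -> target
      reach <- A
      acc <- A
      if (order > 1) {
        for (k in 2:order) {
          reach <- (reach %*% A) > 0
          acc <- acc + reach
        }
      }
      for (tf in intersect(tfs, nodes)) {
        regulators <- c(regulators, nodes[acc[, tf] > 0])
      }
    }
  }
  list(transcripts = sort(sig), tfs = tfs, pathway_hits = sort(hits),
       regulators = sort(setdiff(unique(regulators), tfs)))
}

# random connected scored graph for Steiner property tests
random_connected_graph <- function(n, p, seed) {
  set.seed(seed)
  repeat {
    pairs <- utils::combn(paste0("N", seq_len(n)), 2)
    keep <- runif(ncol(pairs)) < p
    if (sum(keep) < n - 1) next
    g <- mk_ppi(t(pairs[, keep, drop = FALSE]),
                scores = round(runif(sum(keep), 0.1, 0.9), 3))
    if (igraph::count_components(g) == 1 && igraph::vcount(g) == n) return(g)
  }
}

`%||%` <- rlang::`%||%`
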