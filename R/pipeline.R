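# Orchestration: one config object drives the full integration analysis
# (individual downstream/upstream analyses per timepoint -> consensus sets,
# graphs and profiles -> dynamic network -> clustering -> time-course
# integration), writing every artifact plus a JSON manifest. Stage
# functions are exported so the stages can be composed manually; composing
# them in order reproduces `run_pipeline()` byte for byte.

#' Pipeline configuration
#'
#' Paths to the knowledge-base and omics inputs plus every tunable
#' parameter. Defaults follow the analysis conventions: at least one TF
#' per pathway (`min_tfs = 1`), 10 orders of upstream neighbors
#' (`order = 10`), a 1.5-fold significance threshold, PPI confidence cutoff
#' 0.4, 50-point spline grid, automatic hidden-dimension selection,
#' chance-edge probability 0.15, and 4 fuzzy clusters with fuzzifier 2.
#'
#' @param gene_sets,tf_targets,ppi,phospho,transcript Paths to the
#'   required input files (GMT / TSV, see the `load_*` readers).
#' @param topology Optional pathway-topology TSV (required for upstream
#'   regulator identification to find anything).
#' @param protein Optional proteome TSV (enables the integration stage).
#' @param out_dir Output directory for artifacts.
#' @param min_tfs,order,fold_threshold,min_score,n_grid,K,alpha,c,m
#'   Stage parameters; see the stage functions.
#' @param smoothing Spline mode for [densify()].
#' @param seed Root seed for all randomness.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(gene_sets, tf_targets, ppi, phospho, transcript,
                            topology = NULL, protein = NULL,
                            out_dir = "pathconsensus_out",
                            min_tfs = 1, order = 10, fold_threshold = 1.5,
                            min_score = 0.4, n_grid = 50, K = "auto",
                            alpha = 0.15, c = 4, m = 2,
                            smoothing = "gcv", seed = 1) {
  cfg <- list(gene_sets = gene_sets, tf_targets = tf_targets, ppi = ppi,
              phospho = phospho, transcript = transcript,
              topology = topology, protein = protein, out_dir = out_dir,
              min_tfs = min_tfs, order = order,
              fold_threshold = fold_threshold, min_score = min_score,
              n_grid = n_grid, K = K, alpha = alpha, c = c, m = m,
              smoothing = match.arg(smoothing, c("gcv", "interpolate")),
              seed = seed)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

#' @noRd
validate_config <- function(cfg) {
  for (f in c("gene_sets", "tf_targets", "ppi", "phospho", "transcript")) {
    assert_that(is.character(cfg[[f]]) && file.exists(cfg[[f]]),
                paste0("config: input file for '", f, "' not found: ", cfg[[f]]))
  }
  for (f in c("topology", "protein")) {
    if (!is.null(cfg[[f]])) {
      assert_that(file.exists(cfg[[f]]),
                  paste0("config: input file for '", f, "' not found: ", cfg[[f]]))
    }
  }
  assert_that(cfg$order >= 1, "config: order must be >= 1")
  assert_that(cfg$min_tfs >= 1, "config: min_tfs must be >= 1")
  assert_that(cfg$fold_threshold > 1, "config: fold_threshold must be > 1")
  assert_that(cfg$min_score > 0 && cfg$min_score <= 1,
              "config: min_score must lie in (0, 1]")
  assert_that(cfg$alpha > 0 && cfg$alpha <= 1,
              "config: alpha must lie in (0, 1]")
  assert_that(identical(cfg$K, "auto") || (is.numeric(cfg$K) && cfg$K >= 0),
              "config: K must be 'auto' or a non-negative integer")
  assert_that(cfg$c >= 1, "config: c must be >= 1")
  assert_that(cfg$m > 1, "config: fuzzifier m must be > 1")
  assert_that(cfg$n_grid >= 10, "config: n_grid must be >= 10")
  invisible(cfg)
}

#' Load a pipeline configuration from a YAML file
#'
#' Relative input paths are resolved against the YAML file's directory.
#'
#' @param path YAML file whose keys match the [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  assert_that(file.exists(path), paste0("config file not found: ", path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  assert_that(length(bad) == 0,
              paste0("invalid config key(s): ", paste(bad, collapse = ", ")))
  base <- dirname(normalizePath(path))
  for (f in c("gene_sets", "tf_targets", "ppi", "phospho", "transcript",
              "topology", "protein")) {
    if (!is.null(vals[[f]]) && !file.exists(vals[[f]])) {
      vals[[f]] <- file.path(base, vals[[f]])
    }
  }
  do.call(pipeline_config, vals)
}

#' Initialize pipeline state: load and harmonize all inputs
#'
#' @param config A `pipeline_config`.
#' @return A `pipeline_state` carrying the knowledge base, the omics
#'   series restricted to their common grid, and the (created) output
#'   directory.
#' @export
pipeline_state <- function(config) {
  validate_config(config)
  pathways <- load_gene_sets(config$gene_sets, source_db = "user")
  if (!is.null(config$topology)) {
    pathways <- load_topology(config$topology, pathways)
  }
  kb <- knowledge_base(pathways,
                       load_tf_targets(config$tf_targets),
                       load_ppi(config$ppi, min_score = config$min_score))
  phospho <- load_omics_table(config$phospho, "phosphoprotein",
                              fold_threshold = config$fold_threshold)
  transcript <- load_omics_table(config$transcript, "transcript",
                                 fold_threshold = config$fold_threshold)
  phospho <- call_significant_fc(phospho, config$fold_threshold)
  shared <- restrict_to_common_timepoints(phospho, transcript)
  protein <- NULL
  if (!is.null(config$protein)) {
    protein <- load_omics_table(config$protein, "protein",
                                fold_threshold = config$fold_threshold)
    protein <- call_significant_fc(protein, config$fold_threshold)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  structure(list(config = config, kb = kb, phospho = shared$a,
                 transcript = shared$b, protein = protein,
                 artifacts = character()),
            class = "pipeline_state")
}

#' @noRd
add_artifact <- function(state, path) {
  state$artifacts <- c(state$artifacts, path)
  state
}

#' @describeIn pipeline_state per-timepoint downstream and upstream
#'   analyses; writes `individual/downstream.tsv` and
#'   `individual/upstream.tsv`.
#' @param state A `pipeline_state`.
#' @export
stage_individual <- function(state) {
  cfg <- state$config
  tps <- setdiff(state$phospho$timepoints, 0)
  state$down <- purrr::map(tps, function(t) {
    run_downstream(state$phospho, state$kb, t)
  })
  state$up <- purrr::map(tps, function(t) {
    run_upstream(state$transcript, state$kb, t,
                 min_tfs = cfg$min_tfs, order = cfg$order)
  })
  for (i in seq_along(tps)) {
    inform(paste0("[individual] t=", tps[i], "h: ",
                  length(state$down[[i]]$phosphoproteins), " phospho / ",
                  length(state$down[[i]]$pathway_hits), " pathways / ",
                  length(state$up[[i]]$transcripts), " transcripts / ",
                  length(state$up[[i]]$regulators), " regulators"))
  }
  dir.create(file.path(cfg$out_dir, "individual"), showWarnings = FALSE)
  p1 <- file.path(cfg$out_dir, "individual", "downstream.tsv")
  p2 <- file.path(cfg$out_dir, "individual", "upstream.tsv")
  write_tidy_tsv(dplyr::bind_rows(purrr::map(state$down, tidy)), p1)
  write_tidy_tsv(dplyr::bind_rows(purrr::map(state$up, tidy)), p2)
  add_artifact(state, c(p1, p2))
}

#' @describeIn pipeline_state consensus sets, static graphs and profiles;
#'   writes `consensus/sets.tsv`, per-timepoint GraphML/SIF and
#'   `consensus/profiles.tsv`.
#' @export
stage_consensus <- function(state) {
  assert_that(!is.null(state$down), "run stage_individual first")
  cfg <- state$config
  state$consensus <- purrr::map2(state$down, state$up, function(d, u) {
    intersect_layers(d, u, state$phospho)
  })
  state$graphs <- purrr::map(state$consensus, function(cs) {
    build_consensus_graph(cs, state$kb)
  })
  state$profiles <- consensus_profiles(state$graphs)
  dir.create(file.path(cfg$out_dir, "consensus"), showWarnings = FALSE)
  paths <- file.path(cfg$out_dir, "consensus", "sets.tsv")
  write_tidy_tsv(dplyr::bind_rows(purrr::map(state$consensus, tidy)), paths)
  for (g in state$graphs) {
    base <- file.path(cfg$out_dir, "consensus",
                      paste0("graph_", g$timepoint, "h"))
    write_consensus_graph(g, paste0(base, ".graphml"), "graphml")
    write_consensus_graph(g, paste0(base, ".sif"), "sif")
    paths <- c(paths, paste0(base, ".graphml"), paste0(base, ".sif"))
    inform(paste0("[consensus] t=", g$timepoint, "h: ",
                  igraph::vcount(g), " nodes, ", igraph::ecount(g), " edges"))
  }
  pp <- file.path(cfg$out_dir, "consensus", "profiles.tsv")
  write_profiles(state$profiles, pp)
  add_artifact(state, c(paths, pp))
}

#' @describeIn pipeline_state spline densification and empirical-Bayes
#'   network inference on all consensus molecules; writes `dynamic/dense.tsv`,
#'   `dynamic/network.sif`, `dynamic/network.graphml`, `dynamic/fit.json`.
#' @export
stage_dynamic <- function(state) {
  assert_that(!is.null(state$consensus), "run stage_consensus first")
  cfg <- state$config
  dir.create(file.path(cfg$out_dir, "dynamic"), showWarnings = FALSE)
  mat <- consensus_timecourse_matrix(state$consensus, state$phospho,
                                     state$transcript)
  assert_that(nrow(mat) >= 2,
              "dynamic stage needs at least 2 consensus molecules")
  dense <- densify(mat, n_grid = cfg$n_grid, smoothing = cfg$smoothing)
  K <- if (identical(cfg$K, "auto")) NULL else as.integer(cfg$K)
  fit <- fit_dbn(dense, K = K, seed = derive_seed(cfg$seed, 11L))
  state$dbn <- threshold_edges(fit, alpha = cfg$alpha)
  inform(paste0("[dynamic] ", nrow(mat), " molecules, K=", fit$K,
                ", ", nrow(state$dbn$edges), " edges at alpha=", cfg$alpha))
  p <- file.path(cfg$out_dir, "dynamic",
                 c("dense.tsv", "network.sif", "network.graphml", "fit.json"))
  write_dense_ts(dense, p[1])
  write_dbn_network(state$dbn, p[2], "sif")
  write_dbn_network(state$dbn, p[3], "graphml")
  jsonlite::write_json(
    list(K = fit$K, iterations = fit$iterations, converged = fit$converged,
         n_molecules = length(fit$molecules), alpha = cfg$alpha,
         n_edges = nrow(state$dbn$edges)),
    p[4], auto_unbox = TRUE, pretty = TRUE, digits = NA)
  add_artifact(state, p)
}

#' @describeIn pipeline_state fuzzy c-means clustering of consensus
#'   molecule profiles; writes `clustering/membership.tsv`,
#'   `clustering/centroids.tsv`, `clustering/summary.json`.
#' @export
stage_cluster <- function(state) {
  assert_that(!is.null(state$consensus), "run stage_consensus first")
  cfg <- state$config
  dir.create(file.path(cfg$out_dir, "clustering"), showWarnings = FALSE)
  mat <- consensus_timecourse_matrix(state$consensus, state$phospho,
                                     state$transcript)
  X <- standardize_rows(mat)
  cc <- min(cfg$c, nrow(X))
  if (cc < cfg$c) {
    warn(paste0("clustering: reduced c to ", cc, " (only ", nrow(X),
                " consensus profiles)"))
  }
  state$clustering <- fuzzy_cmeans(X, cc, m = cfg$m,
                                   seed = derive_seed(cfg$seed, 13L))
  inform(paste0("[cluster] c=", cc, ", ", nrow(X), " profiles"))
  p <- file.path(cfg$out_dir, "clustering",
                 c("membership.tsv", "centroids.tsv", "summary.json"))
  write_clustering(state$clustering, p[1], p[2])
  jsonlite::write_json(as.list(glance(state$clustering)), p[3],
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  add_artifact(state, p)
}

#' @describeIn pipeline_state phosphoprotein-anchored time-course
#'   integration (requires the proteome input); writes
#'   `integration/integration.tsv`.
#' @export
stage_integrate <- function(state) {
  assert_that(!is.null(state$consensus), "run stage_consensus first")
  cfg <- state$config
  if (is.null(state$protein)) {
    inform("[integrate] no proteome input; stage skipped")
    return(state)
  }
  dir.create(file.path(cfg$out_dir, "integration"), showWarnings = FALSE)
  shared <- restrict_to_common_timepoints(state$transcript, state$protein)
  state$integration <- integrate_time_courses(
    state$phospho, state$down, state$consensus,
    shared$a, shared$b, state$kb)
  inform(paste0("[integrate] ", sum(state$integration$anchors$matched),
                " matched transcript/protein pair(s)"))
  p <- file.path(cfg$out_dir, "integration", "integration.tsv")
  write_integration(state$integration, p)
  add_artifact(state, p)
}

#' Run the full integration pipeline
#'
#' Executes every stage in order on the inputs named by `config` and
#' writes all artifacts plus `manifest.json` (input hashes, parameters,
#' package version, artifact list) under `config$out_dir`. Reruns with an
#' identical config produce byte-identical artifacts.
#'
#' @param config A [pipeline_config()] (or path to a YAML config).
#' @return The final `pipeline_state`, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_pipeline_config(config)
  state <- pipeline_state(config)
  state <- stage_individual(state)
  state <- stage_consensus(state)
  state <- stage_dynamic(state)
  state <- stage_cluster(state)
  state <- stage_integrate(state)
  state <- write_manifest(state)
  invisible(state)
}

#' @noRd
write_manifest <- function(state) {
  cfg <- state$config
  inputs <- purrr::compact(cfg[c("gene_sets", "topology", "tf_targets", "ppi",
                                 "phospho", "transcript", "protein")])
  hashes <- as.list(tools::md5sum(unlist(inputs)))
  names(hashes) <- names(inputs)
  params <- cfg[c("min_tfs", "order", "fold_threshold", "min_score", "n_grid",
                  "K", "alpha", "c", "m", "smoothing", "seed")]
  manifest <- list(
    package = "pathconsensus",
    version = as.character(utils::packageVersion("pathconsensus")),
    inputs = hashes,
    parameters = params,
    artifacts = sort(unname(vapply(
      state$artifacts, function(p) sub(paste0("^", cfg$out_dir, "/?"), "", p),
      character(1))))
  )
  p <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  add_artifact(state, p)
}

#' @noRd
write_tidy_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]])
  lines <- c(paste(colnames(df), collapse = "\t"),
             do.call(paste, c(as.list(df), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}
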