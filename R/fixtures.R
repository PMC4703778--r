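# Synthetic knowledge bases and coupled time courses with a planted
# signaling cascade (upstream regulator -> kinase -> TF -> target genes ->
# proteins), emulating the wave-like immediate/delayed transcriptional
# response to growth-factor stimulation and the transcript-to-protein lag.
# Every stage of the pipeline can be exercised against known ground truth.

#' Specification of a synthetic fixture
#'
#' Defines the knowledge-base dimensions, the measurement grid, the noise
#' level and the planted cascade used by [make_knowledge_base()] and
#' [make_coupled_timecourses()]. Defaults follow the coupled EGF-response
#' design: seven time points (0, 1, 4, 8, 13, 18, 24 h), a handful of
#' measured phosphoproteins, immediate-onset targets at 1 h and
#' delayed-onset targets at 8 h, with proteins lagging their transcripts
#' by 4 h.
#'
#' @param n_pathways Number of pathways (>= 1; the first carries the
#'   planted cascade).
#' @param genes_per_pathway Genes per pathway.
#' @param n_tfs Number of TFs in the TF-target map (>= 1; the first is the
#'   planted TF).
#' @param targets_per_tf Targets per background TF.
#' @param ppi_extra_edge_prob Probability of a random PPI edge between any
#'   two symbols, on top of the planted path.
#' @param timepoints Measurement grid in hours (must include 0).
#' @param noise_sd Gaussian noise sd on logFC for unplanted molecules.
#' @param seed Root seed; all generation is deterministic given it.
#' @param kinase,tf,upstream Symbols of the planted cascade
#'   (`upstream -> kinase -> tf` in the pathway topology and PPI).
#' @param immediate_targets,delayed_targets Planted target-gene symbols.
#' @param immediate_onset,delayed_onset Transcript onset hours.
#' @param protein_lag Transcript-to-protein lag in hours.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_pathways = 6, genes_per_pathway = 8, n_tfs = 4,
                         targets_per_tf = 4, ppi_extra_edge_prob = 0.05,
                         timepoints = c(0, 1, 4, 8, 13, 18, 24),
                         noise_sd = 0.2, seed = 1,
                         kinase = "K0", tf = "TF0", upstream = "X0",
                         immediate_targets = c("GI1", "GI2"),
                         delayed_targets = c("GD1", "GD2"),
                         immediate_onset = 1, delayed_onset = 8,
                         protein_lag = 4) {
  assert_that(n_pathways >= 1 && genes_per_pathway >= 1 && n_tfs >= 1 &&
                targets_per_tf >= 1, "all counts must be >= 1")
  assert_that(ppi_extra_edge_prob >= 0 && ppi_extra_edge_prob <= 1,
              "ppi_extra_edge_prob must lie in [0, 1]")
  assert_that(0 %in% timepoints, "timepoints must include baseline 0")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  structure(list(
    n_pathways = n_pathways, genes_per_pathway = genes_per_pathway,
    n_tfs = n_tfs, targets_per_tf = targets_per_tf,
    ppi_extra_edge_prob = ppi_extra_edge_prob,
    timepoints = sort(unique(as.numeric(timepoints))), noise_sd = noise_sd,
    seed = seed, kinase = kinase, tf = tf, upstream = upstream,
    immediate_targets = immediate_targets, delayed_targets = delayed_targets,
    immediate_onset = immediate_onset, delayed_onset = delayed_onset,
    protein_lag = protein_lag
  ), class = "fixture_spec")
}

#' @noRd
background_pool <- function(spec) {
  paste0("B", seq_len(spec$n_pathways * spec$genes_per_pathway))
}

#' Generate a synthetic knowledge base
#'
#' Pathway `P0` carries the planted cascade: it contains the upstream
#' regulator, the kinase and the TF, with topology
#' `upstream -> kinase -> tf` (activation). Remaining pathways draw random
#' background genes with a random activation-chain topology. The TF-target
#' map holds the planted TF's targets plus random background TFs. The PPI
#' contains the planted path as high-confidence edges plus random edges at
#' `ppi_extra_edge_prob`, restricted to the connected component of the
#' planted cascade (the largest component under the default densities).
#'
#' @param spec A [fixture_spec()].
#' @return A [knowledge_base()].
#' @export
make_knowledge_base <- function(spec) {
  set.seed(derive_seed(spec$seed, 1L))
  pool <- background_pool(spec)
  targets <- c(spec$immediate_targets, spec$delayed_targets)
  planted_genes <- unique(c(spec$upstream, spec$kinase, spec$tf))

  n_fill <- max(0, spec$genes_per_pathway - length(planted_genes))
  p0_genes <- c(planted_genes, sample(pool, min(n_fill, length(pool))))
  pw_ids <- paste0("P", seq_len(spec$n_pathways) - 1)
  genes_list <- vector("list", spec$n_pathways)
  topo_list <- vector("list", spec$n_pathways)
  genes_list[[1]] <- p0_genes
  topo_list[[1]] <- tibble::tibble(
    source = c(spec$upstream, spec$kinase),
    target = c(spec$kinase, spec$tf),
    effect = "activation"
  )
  for (i in seq_len(spec$n_pathways - 1) + 1) {
    g <- sample(pool, min(spec$genes_per_pathway, length(pool)))
    genes_list[[i]] <- g
    topo_list[[i]] <- if (length(g) >= 2) {
      tibble::tibble(source = g[-length(g)], target = g[-1],
                     effect = "activation")
    } else {
      empty_topology()
    }
  }
  pathways <- tibble::tibble(
    pathway_id = pw_ids,
    name = paste("synthetic pathway", pw_ids),
    source_db = "synthetic",
    genes = genes_list,
    topology = topo_list
  )

  tf_rows <- tibble::tibble(tf = spec$tf, target = targets)
  if (spec$n_tfs > 1) {
    for (i in seq_len(spec$n_tfs - 1)) {
      tf_rows <- dplyr::bind_rows(tf_rows, tibble::tibble(
        tf = paste0("TF", i),
        target = sample(pool, min(spec$targets_per_tf, length(pool)))
      ))
    }
  }
  tf_targets <- dplyr::arrange(dplyr::distinct(tf_rows), .data$tf, .data$target)

  all_syms <- unique(c(planted_genes, pool, targets))
  edges <- tibble::tibble(
    a = c(spec$upstream, spec$kinase),
    b = c(spec$kinase, spec$tf),
    score = 0.9
  )
  if (spec$ppi_extra_edge_prob > 0) {
    pairs <- utils::combn(sort(all_syms), 2)
    keep <- runif(ncol(pairs)) < spec$ppi_extra_edge_prob
    if (any(keep)) {
      extra <- tibble::tibble(a = pairs[1, keep], b = pairs[2, keep],
                              score = round(runif(sum(keep), 0.4, 0.95), 3))
      edges <- dplyr::bind_rows(edges, extra)
    }
  }
  key_a <- pmin(edges$a, edges$b); key_b <- pmax(edges$a, edges$b)
  edges <- tibble::tibble(a = key_a, b = key_b, score = edges$score) |>
    dplyr::group_by(.data$a, .data$b) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop") |>
    dplyr::arrange(.data$a, .data$b)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(g)
  kin_comp <- comp$membership[spec$kinase]
  if (kin_comp != which.max(comp$csize)) {
    inform("make_knowledge_base: planted component is not the largest; retaining it")
  }
  g <- igraph::induced_subgraph(g, which(comp$membership == kin_comp))
  igraph::E(g)$weight <- 1 - igraph::E(g)$score
  knowledge_base(pathways, tf_targets, g)
}

#' @noRd
kinase_curve <- function(t) 2 * (1 - exp(-t / 0.5)) * exp(-t / 30)

#' @noRd
target_curve <- function(t, onset) {
  ifelse(t >= onset, 1.5 * (1 - exp(-(t - onset + 1) / 1.5)), 0)
}

#' Generate coupled phospho/transcript/protein time courses
#'
#' The planted kinase's phosphorylation follows a rapid-rise/slow-decay
#' curve that crosses the 1.5-fold threshold from the first post-baseline
#' timepoint. Planted target transcripts rise after their onset (immediate
#' or delayed) and their proteins follow the same curve shifted by the
#' transcript-to-protein lag. Every other measured molecule is Gaussian
#' noise with `noise_sd` around zero. Significance flags are computed with
#' [call_significant_fc()] at the default 1.5-fold threshold.
#'
#' @param kb Knowledge base from [make_knowledge_base()] (planted molecules
#'   must be present).
#' @param spec The [fixture_spec()] used to build `kb`.
#' @return List with elements `phospho`, `transcript`, `protein`
#'   (`omics_ts` objects on the spec's grid).
#' @export
make_coupled_timecourses <- function(kb, spec) {
  assert_that(spec$kinase %in% igraph::V(kb$ppi)$name,
              "planted kinase not present in knowledge base PPI")
  set.seed(derive_seed(spec$seed, 2L))
  tp <- spec$timepoints
  pool <- background_pool(spec)
  targets <- c(spec$immediate_targets, spec$delayed_targets)
  onsets <- rep(c(spec$immediate_onset, spec$delayed_onset),
                c(length(spec$immediate_targets), length(spec$delayed_targets)))

  noise_mat <- function(n) {
    m <- matrix(rnorm(n * length(tp), sd = spec$noise_sd), n, length(tp))
    m[, tp == 0] <- 0
    m
  }
  # phosphoproteins: the planted kinase plus a few unplanted ones
  n_bg_phospho <- min(4L, length(pool))
  phospho_bg <- sort(sample(pool, n_bg_phospho))
  phospho_mols <- c(spec$kinase, phospho_bg)
  phospho_mat <- rbind(kinase_curve(tp) * (tp > 0), noise_mat(n_bg_phospho))

  # transcripts: planted targets plus background pool
  tr_mols <- c(targets, pool)
  tr_mat <- rbind(t(vapply(onsets, function(o) target_curve(tp, o),
                           numeric(length(tp)))),
                  noise_mat(length(pool)))

  # proteins: planted targets (lagged) plus background pool
  pr_mols <- c(targets, pool)
  pr_mat <- rbind(t(vapply(onsets, function(o) target_curve(tp - spec$protein_lag, o),
                           numeric(length(tp)))),
                  noise_mat(length(pool)))
  pr_mat[, tp == 0] <- 0

  list(
    phospho = call_significant_fc(
      omics_time_series("phosphoprotein", phospho_mols, tp, phospho_mat)),
    transcript = call_significant_fc(
      omics_time_series("transcript", tr_mols, tp, tr_mat)),
    protein = call_significant_fc(
      omics_time_series("protein", pr_mols, tp, pr_mat))
  )
}

#' Planted ground truth per layer and timepoint
#'
#' The consensus sets a noiseless fixture must recover: the planted kinase
#' on the protein layer and the planted TF on the TF layer wherever the
#' kinase curve is significant, and on the gene layer every planted target
#' whose transcript curve is significant at that timepoint.
#'
#' @param spec A [fixture_spec()].
#' @return List of `consensus_set`-shaped lists, one per post-baseline
#'   timepoint.
#' @export
planted_truth <- function(spec) {
  thr <- log2(1.5)
  tp <- setdiff(spec$timepoints, 0)
  targets <- c(spec$immediate_targets, spec$delayed_targets)
  onsets <- rep(c(spec$immediate_onset, spec$delayed_onset),
                c(length(spec$immediate_targets), length(spec$delayed_targets)))
  purrr::map(tp, function(t) {
    kin_on <- abs(kinase_curve(t)) >= thr
    list(timepoint = t,
         proteins = if (kin_on) spec$kinase else character(),
         tfs = if (kin_on) spec$tf else character(),
         genes = sort(targets[abs(target_curve(t, onsets)) >= thr]))
  })
}

#' Labeled co-regulation profiles from sign-by-onset archetypes
#'
#' Draws time profiles from the four archetypes (up/down regulation crossed
#' with immediate/delayed onset) on the default 7-point grid, plus i.i.d.
#' Gaussian noise, and returns the matrix together with the true labels.
#' Archetypes use the same exponential-rise response family and amplitude
#' (1.5 log2 units, a ~2.8-fold change) as the planted cascade in
#' [make_coupled_timecourses()], with onsets at 1 h (immediate) and 8 h
#' (delayed).
#'
#' @param n_per_pattern Profiles per archetype (>= 1).
#' @param noise_sd Noise standard deviation. Default 0.2.
#' @param seed Seed.
#' @param timepoints Time grid (default `c(0, 1, 4, 8, 13, 18, 24)`).
#' @return List with `profiles` (matrix, `4 * n_per_pattern` rows),
#'   `labels` (factor with levels `up_immediate`, `up_delayed`,
#'   `down_immediate`, `down_delayed`), `times`.
#' @export
make_coregulation_profiles <- function(n_per_pattern, noise_sd = 0.2, seed = 1,
                                       timepoints = c(0, 1, 4, 8, 13, 18, 24)) {
  assert_that(n_per_pattern >= 1, "n_per_pattern must be >= 1")
  templates <- rbind(
    up_immediate = target_curve(timepoints, 1),
    up_delayed = target_curve(timepoints, 8),
    down_immediate = -target_curve(timepoints, 1),
    down_delayed = -target_curve(timepoints, 8)
  )
  labels <- factor(rep(rownames(templates), each = n_per_pattern),
                   levels = rownames(templates))
  set.seed(derive_seed(seed, 3L))
  profiles <- templates[rep(seq_len(4), each = n_per_pattern), , drop = FALSE] +
    matrix(rnorm(4 * n_per_pattern * length(timepoints), sd = noise_sd),
           4 * n_per_pattern, length(timepoints))
  rownames(profiles) <- paste0("M", seq_len(nrow(profiles)))
  colnames(profiles) <- timepoints
  list(profiles = profiles, labels = labels, times = timepoints)
}

#' Standardize profile rows to zero mean, unit variance
#' @param X Numeric matrix.
#' @return Matrix of the same shape.
#' @export
standardize_rows <- function(X) {
  sds <- apply(X, 1, sd)
  assert_that(all(sds > 0), "cannot standardize constant rows")
  (X - rowMeans(X)) / sds
}

#' Write a fixture to disk in the loader formats
#'
#' Emits GMT gene sets, topology TSV, TF-target TSV, PPI TSV and one omics
#' TSV per layer, exactly as the `load_*` readers expect (round-trip
#' tested).
#'
#' @param kb A [knowledge_base()].
#' @param series List with `phospho`, `transcript`, `protein` `omics_ts`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths.
#' @export
write_fixture <- function(kb, series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    gene_sets = file.path(dir, "pathways.gmt"),
    topology = file.path(dir, "topology.tsv"),
    tf_targets = file.path(dir, "tf_targets.tsv"),
    ppi = file.path(dir, "ppi.tsv"),
    phospho = file.path(dir, "phospho.tsv"),
    transcript = file.path(dir, "transcript.tsv"),
    protein = file.path(dir, "protein.tsv")
  )
  write_gene_sets(kb$pathways, paths["gene_sets"])
  write_topology(kb$pathways, paths["topology"])
  write_tf_targets(kb$tf_targets, paths["tf_targets"])
  write_ppi(kb$ppi, paths["ppi"])
  write_omics_table(series$phospho, paths["phospho"])
  write_omics_table(series$transcript, paths["transcript"])
  write_omics_table(series$protein, paths["protein"])
  paths
}
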