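test_that("intersect_layers intersects each cellular layer", {
  down <- structure(list(timepoint = 1, phosphoproteins = c("K0"),
                         pathway_hits = "PW1", tfs = c("TF0", "TF1"),
                         target_genes = c("G1", "G2")),
                    class = "downstream_result")
  up <- structure(list(timepoint = 1, transcripts = c("G2", "G3"),
                       tfs = c("TF1", "TF2"), pathway_hits = "PW1",
                       regulators = c("K0", "X")),
                  class = "upstream_result")
  ph <- mk_series("phosphoprotein", c("K0", "Q"), c(0, 1),
                  rbind(c(0, 1), c(0, 1)))
  cs <- intersect_layers(down, up, ph)
  expect_equal(cs$proteins, "K0")
  expect_equal(cs$tfs, "TF1")
  expect_equal(cs$genes, "G2")
  up$timepoint <- 4
  expect_error(intersect_layers(down, up, ph), "different timepoints")
})

test_that("steiner_tree recovers a connecting path with its steiner node", {
  g <- mk_ppi(cbind(c("A", "B"), c("B", "C")))
  st <- steiner_tree(g, c("A", "C"), weighted = FALSE)
  el <- igraph::as_edgelist(st)
  expect_equal(nrow(el), 2)
  expect_setequal(igraph::V(st)$name, c("A", "B", "C"))
  expect_equal(igraph::V(st)$name[!igraph::V(st)$terminal], "B")
})

test_that("steiner_tree handles single terminals, ties, missing terminals, forests", {
  g <- mk_ppi(cbind(c("A", "B"), c("B", "C")))
  st1 <- steiner_tree(g, "A")
  expect_equal(igraph::vcount(st1), 1)
  expect_equal(igraph::ecount(st1), 0)
  # 4-cycle: both 2-edge paths optimal; lexicographic tie-break picks A-B-C
  g4 <- mk_ppi(cbind(c("A", "B", "C", "D"), c("B", "C", "D", "A")))
  st4 <- steiner_tree(g4, c("A", "C"), weighted = FALSE)
  expect_setequal(igraph::V(st4)$name, c("A", "B", "C"))
  expect_warning(st_m <- steiner_tree(g, c("A", "ZZ")), "ZZ")
  expect_setequal(igraph::V(st_m)$name, "A")
  expect_warning(expect_warning(st0 <- steiner_tree(g, "QQ"), "dropped"),
                 "no terminal")
  expect_equal(igraph::vcount(st0), 0)
  gf <- mk_ppi(cbind(c("A", "D"), c("B", "E")))
  stf <- steiner_tree(gf, c("A", "B", "D", "E"), weighted = FALSE)
  expect_equal(igraph::count_components(stf), 2)
  expect_true(igraph::is_forest(stf))
})

test_that("approximation stays within 2(1 - 1/k) of the exhaustive optimum", {
  for (s in 1:25) {
    g <- random_connected_graph(n = sample(5:10, 1), p = 0.4, seed = 300 + s)
    k <- sample(2:4, 1)
    terminals <- sample(igraph::V(g)$name, k)
    st <- steiner_tree(g, terminals)
    expect_true(all(terminals %in% igraph::V(st)$name))
    expect_true(igraph::is_forest(st))
    w <- sum(igraph::E(st)$weight)
    opt <- steiner_opt_weight(g, terminals)
    expect_lte(w, 2 * (1 - 1 / k) * opt + 1e-9)
  }
})

test_that("build_consensus_graph composes steiner, TF-target and feedback edges", {
  pw <- mk_pathway_tbl("PW1", list(c("K0", "TF0")))
  tt <- tibble::tibble(tf = "TF0", target = c("G1", "G9"))
  ppi <- mk_ppi(cbind("K0", "TF0"), scores = 0.8)
  kb <- knowledge_base(pw, tt, ppi)
  cs <- structure(list(timepoint = 1, proteins = "K0", tfs = "TF0",
                       genes = "G1"), class = "consensus_set")
  g <- build_consensus_graph(cs, kb)
  kinds <- igraph::E(g)$kind
  el <- igraph::as_edgelist(g)
  expect_setequal(paste(el[, 1], kinds, el[, 2]),
                  c("protein:K0 ppi_steiner tf:TF0", "tf:TF0 tf_target gene:G1"))
  # feedback: same symbol on gene and protein layer
  cs2 <- structure(list(timepoint = 1, proteins = "K0", tfs = "TF0",
                        genes = c("G1", "K0")), class = "consensus_set")
  g2 <- build_consensus_graph(cs2, kb)
  el2 <- igraph::as_edgelist(g2)
  fb <- el2[igraph::E(g2)$kind == "feedback", , drop = FALSE]
  expect_equal(unname(fb), cbind("gene:K0", "protein:K0"))
  # no tf_target edge when the gene is not a target of the consensus TF
  cs3 <- structure(list(timepoint = 1, proteins = character(), tfs = "TF0",
                        genes = "G7"), class = "consensus_set")
  g3 <- suppressWarnings(build_consensus_graph(cs3, kb))
  expect_false(any(igraph::E(g3)$kind == "tf_target"))
})

test_that("build_consensus_graph is deterministic and keeps every ppi edge real", {
  spec <- fixture_spec(noise_sd = 0, seed = 3)
  kb <- make_knowledge_base(spec)
  ser <- make_coupled_timecourses(kb, spec)
  d <- run_downstream(ser$phospho, kb, 4)
  u <- run_upstream(ser$transcript, kb, 4)
  cs <- intersect_layers(d, u, ser$phospho)
  g1 <- build_consensus_graph(cs, kb)
  g2 <- build_consensus_graph(cs, kb)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  expect_identical(igraph::V(g1)$name, igraph::V(g2)$name)
  el <- igraph::as_edgelist(g1)
  ppi_e <- el[igraph::E(g1)$kind == "ppi_steiner", , drop = FALSE]
  if (nrow(ppi_e)) {
    ids <- igraph::get_edge_ids(kb$ppi, t(cbind(sub("^[a-z]+:", "", ppi_e[, 1]),
                                                sub("^[a-z]+:", "", ppi_e[, 2]))))
    expect_true(all(ids > 0))
  }
})

test_that("consensus_profiles builds a sorted boolean presence matrix", {
  pw <- mk_pathway_tbl("PW1", list(c("K0", "TF0")))
  tt <- tibble::tibble(tf = "TF0", target = "G1")
  kb <- knowledge_base(pw, tt, mk_ppi(cbind("K0", "TF0")))
  cs_a <- structure(list(timepoint = 1, proteins = "K0", tfs = "TF0",
                         genes = "G1"), class = "consensus_set")
  cs_b <- structure(list(timepoint = 4, proteins = "K0", tfs = "TF0",
                         genes = character()), class = "consensus_set")
  cs_c <- structure(list(timepoint = 8, proteins = character(),
                         tfs = character(), genes = character()),
                    class = "consensus_set")
  graphs <- purrr::map(list(cs_a, cs_b, cs_c),
                       function(cs) suppressWarnings(build_consensus_graph(cs, kb)))
  prof <- consensus_profiles(graphs)
  g1row <- prof[prof$symbol == "G1" & prof$layer == "gene", ]
  expect_equal(unname(unlist(g1row[c("1", "4", "8")])), c(TRUE, FALSE, FALSE))
  lv <- factor(prof$layer, levels = c("protein", "tf", "gene", "steiner"))
  expect_false(is.unsorted(lv))  # rows ordered by layer, then symbol
  expect_error(consensus_profiles(graphs[c(1, 1)]), "duplicate")
  empty <- consensus_profiles(list())
  expect_equal(nrow(empty), 0)
})

test_that("steiner nodes appear as steiner-layer profile rows", {
  # terminals A and C connect through B, which is not a consensus molecule
  pw <- mk_pathway_tbl("PW1", list(c("A", "C")))
  tt <- tibble::tibble(tf = "C", target = "G1")
  ppi <- mk_ppi(cbind(c("A", "B"), c("B", "C")))
  kb <- knowledge_base(pw, tt, ppi)
  cs <- structure(list(timepoint = 1, proteins = "A", tfs = "C",
                       genes = character()), class = "consensus_set")
  g <- build_consensus_graph(cs, kb)
  prof <- consensus_profiles(list(g))
  expect_true(any(prof$layer == "steiner" & prof$symbol == "B"))
})
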