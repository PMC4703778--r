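test_that("harmonize_symbol trims, upper-cases, applies aliases, and is idempotent", {
  expect_equal(harmonize_symbol("stat3"), "STAT3")
  expect_equal(harmonize_symbol(" Mapk1 "), "MAPK1")
  expect_equal(harmonize_symbol("ERK2", alias_table = c(ERK2 = "MAPK1")), "MAPK1")
  expect_equal(harmonize_symbol("erk2", alias_table = c(ERK2 = "MAPK1")), "MAPK1")
  expect_error(harmonize_symbol("  "), "empty")
  expect_error(harmonize_symbol(c("A", "")), "empty")
  syms <- c("a1", " b2 ", "C3")
  expect_identical(harmonize_symbol(harmonize_symbol(syms)), harmonize_symbol(syms))
})

test_that("load_gene_sets parses GMT, harmonizes and deduplicates", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("# comment",
               "PW1\tdesc\tEGFR\tMAPK1\tSTAT3",
               "PW2\tdesc\tegfr\tEGFR"), f)
  pw <- load_gene_sets(f, source_db = "db1")
  expect_equal(pw$pathway_id, c("PW1", "PW2"))
  expect_setequal(pw$genes[[1]], c("EGFR", "MAPK1", "STAT3"))
  expect_equal(pw$genes[[2]], "EGFR")
  expect_equal(unique(pw$source_db), "db1")
})

test_that("load_gene_sets rejects short lines and duplicate ids", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("PW1\tdesc\tA", "PW3\tdesc"), f)
  expect_error(load_gene_sets(f), "line 2")
  writeLines(c("PW1\tdesc\tA", "PW1\tdesc\tB"), f)
  expect_error(load_gene_sets(f), "duplicate")
})

test_that("gene sets round-trip through GMT", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("PW1\tfirst\tEGFR\tMAPK1", "PW2\tsecond\tSTAT3"), f)
  pw <- load_gene_sets(f, source_db = "x")
  f2 <- withr::local_tempfile(fileext = ".gmt")
  write_gene_sets(pw, f2)
  expect_identical(load_gene_sets(f2, source_db = "x"), pw)
})

test_that("load_topology attaches edges and grows gene sets with a warning", {
  pw <- mk_pathway_tbl("PW1", list(c("EGFR", "MAPK1")))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pathway_id\tsource\tinteraction\ttarget",
               "PW1\tEGFR\tactivation\tMAPK1"), f)
  out <- load_topology(f, pw)
  expect_equal(out$topology[[1]],
               tibble::tibble(source = "EGFR", target = "MAPK1",
                              effect = "activation"))
  writeLines(c("pathway_id\tsource\tinteraction\ttarget",
               "PW1\tEGFR\tactivation\tJAK2"), f)
  expect_warning(out2 <- load_topology(f, pw), "JAK2")
  expect_true("JAK2" %in% out2$genes[[1]])
  expect_true(all(c(out2$topology[[1]]$source, out2$topology[[1]]$target) %in%
                    out2$genes[[1]]))
})

test_that("load_topology rejects unknown pathways and interaction tokens", {
  pw <- mk_pathway_tbl("PW1", list(c("A", "B")))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("PW9\tA\tactivation\tB", f)
  expect_error(load_topology(f, pw), "PW9")
  writeLines("PW1\tA\tbinds\tB", f)
  expect_error(load_topology(f, pw), "activation, inhibition, unknown")
})

test_that("load_tf_targets harmonizes, collapses duplicates, rejects empty files", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("stat3\tjak2", "STAT3\tJAK2", "STAT3\tCCND1"), f)
  tt <- load_tf_targets(f)
  expect_equal(nrow(tt), 2)
  expect_setequal(tt$target[tt$tf == "STAT3"], c("JAK2", "CCND1"))
  writeLines("# only a comment", f)
  expect_error(load_tf_targets(f), "empty")
})

test_that("load_ppi filters, rescales, drops self-loops, keeps the largest component", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t900", "B\tC\t800", "D\tE\t700", "A\tA\t950", "A\tB\t400"),
             f)
  expect_message(g <- load_ppi(f, min_score = 0.4), "dropped 2")
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(g), 2)
  ab <- igraph::E(g)$score[igraph::get_edge_ids(g, c("A", "B"))]
  expect_equal(ab, 0.9)  # 0-1000 scale divided, best duplicate kept
  expect_false(any(igraph::which_loop(g)))
  expect_equal(igraph::count_components(g), 1)
})

test_that("load_ppi drops edges below min_score and errors when nothing is left", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t0.3", "B\tC\t0.35"), f)
  expect_error(load_ppi(f, min_score = 0.4), "empty")
})

test_that("knowledge_base validates cross-component invariants", {
  pw <- mk_pathway_tbl("PW1", list(c("A", "B")))
  tt <- tibble::tibble(tf = "A", target = "G1")
  ppi <- mk_ppi(cbind("A", "B"))
  expect_s3_class(knowledge_base(pw, tt, ppi), "knowledge_base")
  bad <- mk_pathway_tbl("PW1", list(c("A", "B")),
                        list(tibble::tibble(source = "Z", target = "A",
                                            effect = "activation")))
  expect_error(knowledge_base(bad, tt, ppi), "endpoints")
  expect_error(knowledge_base(pw, tt[0, ], ppi), "non-empty")
})
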