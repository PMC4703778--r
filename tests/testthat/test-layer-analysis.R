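kb_small <- function() {
  pw <- mk_pathway_tbl(
    c("PW1", "PW2"),
    list(c("K0", "TF0", "X"), c("Y", "Z")),
    list(tibble::tibble(source = c("X", "K0"), target = c("K0", "TF0"),
                        effect = "activation"),
         tibble::tibble(source = character(), target = character(),
                        effect = character()))
  )
  tt <- tibble::tibble(tf = c("TF0", "TF0", "TF9"),
                       target = c("G1", "G2", "G3"))
  ppi <- mk_ppi(cbind(c("X", "K0"), c("K0", "TF0")), scores = c(0.9, 0.9))
  knowledge_base(pw, tt, ppi)
}

test_that("run_downstream maps significant phosphoproteins to pathways, TFs, targets", {
  kb <- kb_small()
  ph <- mk_series("phosphoprotein", c("K0", "Q"), c(0, 1, 4),
                  rbind(c(0, 1, 1), c(0, 0, 0)))
  d <- run_downstream(ph, kb, 1)
  expect_equal(d$phosphoproteins, "K0")
  expect_equal(d$pathway_hits, "PW1")
  expect_equal(d$tfs, "TF0")
  expect_equal(d$target_genes, c("G1", "G2"))
})

test_that("run_downstream returns empty fields when nothing is significant or mapped", {
  kb <- kb_small()
  ph0 <- mk_series("phosphoprotein", "K0", c(0, 1), matrix(c(0, 0), 1))
  d0 <- run_downstream(ph0, kb, 1)
  expect_length(d0$phosphoproteins, 0)
  expect_length(d0$pathway_hits, 0)
  expect_length(d0$tfs, 0)
  expect_length(d0$target_genes, 0)
  phz <- mk_series("phosphoprotein", "ZZ", c(0, 1), matrix(c(0, 1), 1))
  dz <- run_downstream(phz, kb, 1)
  expect_equal(dz$phosphoproteins, "ZZ")
  expect_length(dz$pathway_hits, 0)
})

test_that("upstream_regulators walks against edge direction up to the given order", {
  chain <- paste0("P", 12:1)
  topo <- tibble::tibble(source = chain,
                         target = c(chain[-1], "TF0"),
                         effect = "activation")
  pw <- mk_pathway_tbl("PW1", list(c(chain, "TF0")), list(topo))
  reg10 <- upstream_regulators("TF0", pw, order = 10)
  expect_setequal(reg10, paste0("P", 1:10))  # 12 ancestors, depth caps at 10
  reg1 <- upstream_regulators("TF0", pw, order = 1)
  expect_equal(reg1, "P1")
  expect_length(upstream_regulators("TF_ABSENT", pw, order = 10), 0)
  expect_error(upstream_regulators("TF0", pw, order = 0), ">= 1")
})

test_that("upstream_regulators at large order equals transitive-closure reachability", {
  set.seed(11)
  for (rep in 1:5) {
    nodes <- paste0("N", 1:8)
    edges <- tibble::tibble(
      source = sample(nodes, 10, replace = TRUE),
      target = sample(nodes, 10, replace = TRUE),
      effect = "activation"
    )
    edges <- dplyr::distinct(edges[edges$source != edges$target, ])
    pw <- mk_pathway_tbl("PW1", list(nodes), list(edges))
    seed_tf <- sample(nodes, 1)
    got <- upstream_regulators(seed_tf, pw, order = 100)
    A <- matrix(0, 8, 8, dimnames = list(nodes, nodes))
    A[cbind(edges$source, edges$target)] <- 1
    acc <- A
    reach <- A
    for (k in 2:8) {
      reach <- (reach %*% A) > 0
      acc <- acc + reach
    }
    want <- setdiff(nodes[acc[, seed_tf] > 0], seed_tf)
    expect_setequal(got, want)
  }
})

test_that("run_upstream identifies TFs, pathways and regulators; min_tfs gates pathways", {
  kb <- kb_small()
  tr <- mk_series("transcript", c("G1", "B"), c(0, 1), rbind(c(0, 1), c(0, 0)))
  u <- run_upstream(tr, kb, 1)
  expect_equal(u$transcripts, "G1")
  expect_equal(u$tfs, "TF0")
  expect_equal(u$pathway_hits, "PW1")
  expect_setequal(u$regulators, c("K0", "X"))
  u2 <- run_upstream(tr, kb, 1, min_tfs = 2)
  expect_length(u2$pathway_hits, 0)
  expect_length(u2$regulators, 0)
  tr0 <- mk_series("transcript", "G1", c(0, 1), matrix(c(0, 0), 1))
  u0 <- run_upstream(tr0, kb, 1)
  expect_length(u0$transcripts, 0)
  expect_length(u0$tfs, 0)
})

test_that("downstream and upstream agree with brute-force oracles on random knowledge bases", {
  for (s in 1:6) {
    set.seed(100 + s)
    genes <- paste0("G", 1:20)
    n_pw <- sample(3:8, 1)
    pw <- mk_pathway_tbl(
      paste0("PW", seq_len(n_pw)),
      purrr::map(seq_len(n_pw), ~ sample(genes, sample(3:8, 1))),
      purrr::map(seq_len(n_pw), function(i) {
        e <- tibble::tibble(source = sample(genes, 6, replace = TRUE),
                            target = sample(genes, 6, replace = TRUE),
                            effect = "activation")
        e <- dplyr::distinct(e[e$source != e$target, ])
        e
      })
    )
    # keep topology endpoints inside the gene sets
    pw$genes <- purrr::map2(pw$genes, pw$topology,
                            ~ unique(c(.x, .y$source, .y$target)))
    tt <- dplyr::distinct(tibble::tibble(
      tf = sample(genes, 10, replace = TRUE),
      target = sample(genes, 10, replace = TRUE)
    ))
    ppi <- mk_ppi(cbind(genes[1:19], genes[2:20]))
    kb <- knowledge_base(pw, tt, ppi)
    lfc <- cbind(0, matrix(rnorm(40), 20, 2))
    ph <- mk_series("phosphoprotein", genes, c(0, 1, 4), lfc)
    tr <- mk_series("transcript", genes, c(0, 1, 4), lfc[, c(1, 3, 2)])

    d <- run_downstream(ph, kb, 1)
    od <- oracle_downstream(ph, kb, 1)
    expect_equal(d[names(od)], od)

    u <- run_upstream(tr, kb, 4, order = 10)
    ou <- oracle_upstream(tr, kb, 4, order = 10)
    expect_equal(u[names(ou)], ou)
  }
})

test_that("enlarging the significant set never shrinks analysis results", {
  kb <- kb_small()
  ph_small <- mk_series("phosphoprotein", c("K0", "Y"), c(0, 1),
                        rbind(c(0, 1), c(0, 0)))
  ph_big <- mk_series("phosphoprotein", c("K0", "Y"), c(0, 1),
                      rbind(c(0, 1), c(0, 1)))
  d1 <- run_downstream(ph_small, kb, 1)
  d2 <- run_downstream(ph_big, kb, 1)
  for (f in c("phosphoproteins", "pathway_hits", "tfs", "target_genes")) {
    expect_true(all(d1[[f]] %in% d2[[f]]))
  }
})
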