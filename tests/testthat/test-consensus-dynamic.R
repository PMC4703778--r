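test_that("densify reproduces linear and cubic series exactly in interpolate mode", {
  tm <- c(0, 1, 4, 8, 13, 18, 24)
  vals <- rbind(L = 2 * tm + 1, Q = 0.1 * tm^3 - tm + 2)
  d <- densify(vals, times = tm, n_grid = 50, smoothing = "interpolate",
               standardize = FALSE)
  expect_lt(max(abs(d$values["L", ] - (2 * d$grid + 1))), 1e-8)
  expect_lt(max(abs(d$values["Q", ] - (0.1 * d$grid^3 - d$grid + 2))), 1e-6)
  # exact at the measured knots (25-point grid over [0, 24] contains them)
  d2 <- densify(vals, times = tm, n_grid = 25, smoothing = "interpolate",
                standardize = FALSE)
  knot_idx <- match(tm, d2$grid)
  expect_false(anyNA(knot_idx))
  expect_equal(unname(d2$values["Q", knot_idx]),
               unname(vals["Q", ]), tolerance = 1e-8)
})

test_that("densify standardizes, records flags, and rejects bad input", {
  tm <- c(0, 1, 4, 8)
  vals <- rbind(A = c(0, 1, 2, 1.5), B = c(0, 0, 0, 0))
  expect_error(densify(vals, times = tm), "constant.*B")
  d <- densify(vals[1, , drop = FALSE], times = tm, n_grid = 12)
  expect_equal(mean(d$values[1, ]), 0, tolerance = 1e-12)
  expect_equal(sd(d$values[1, ]), 1, tolerance = 1e-12)
  expect_true(d$standardized)
  expect_error(densify(vals[1, 1:3, drop = FALSE], times = tm[1:3]),
               "4 measured")
  expect_error(densify(vals[1, , drop = FALSE], times = tm, n_grid = 3),
               "n_grid")
})

test_that("select_hidden_dim finds a rank-1 latent process and degenerate cases", {
  set.seed(1)
  Tn <- 80
  x <- numeric(Tn); x[1] <- 1
  for (t in 2:Tn) x[t] <- 0.9 * x[t - 1] + 0.02 * rnorm(1)
  Y <- rbind(a = x, b = 0.7 * x, c = -0.5 * x)
  expect_equal(select_hidden_dim(mk_dense(Y)), 1L)
  Y0 <- matrix(0, 3, 40, dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(select_hidden_dim(mk_dense(Y0, standardize = FALSE)), 0L)
  set.seed(2)
  Yr <- matrix(rnorm(5 * 60), 5, 60, dimnames = list(paste0("m", 1:5), NULL))
  expect_lte(select_hidden_dim(mk_dense(Yr), max_K = 3), 3L)
})

test_that("fit_dbn recovers a known feedback matrix and separates true from null edges", {
  D <- rbind(c(0.8, 0), c(0.5, 0.3))
  Y <- sim_var1(D, T_ = 200, sd = 0.3, seed = 2)
  f <- fit_dbn(mk_dense(Y), K = 0, seed = 1)
  expect_true(f$converged)
  expect_lt(max(abs(f$D - D)), 0.1)
  z_true <- abs(f$z[cbind(c(1, 2, 2), c(1, 1, 2))])
  z_null <- abs(f$z[1, 2])
  expect_true(all(z_true > z_null))
})

test_that("fit_dbn handles a single molecule as a scalar AR(1)", {
  set.seed(3)
  y <- matrix(0, 1, 100, dimnames = list("solo", NULL))
  for (t in 2:100) y[1, t] <- 0.7 * y[1, t - 1] + rnorm(1, sd = 0.5)
  f <- fit_dbn(mk_dense(y), K = 0, seed = 1)
  expect_true(is.finite(f$z[1, 1]))
  expect_gt(f$z[1, 1], 2)
})

test_that("fit_dbn with hidden states runs and returns consistent dimensions", {
  D <- diag(0.4, 4)
  Y <- sim_var1(D, T_ = 60, sd = 0.5, seed = 5)
  f <- suppressWarnings(fit_dbn(mk_dense(Y), K = 2, seed = 1))
  expect_equal(dim(f$A), c(2, 2))
  expect_equal(dim(f$B), c(2, 4))
  expect_equal(dim(f$C), c(4, 2))
  expect_equal(dim(f$D), c(4, 4))
  expect_true(all(is.finite(f$z)))
  expect_true(all(unlist(f$hyper) > 0))
})

test_that("fit_dbn is deterministic given data, K and seed", {
  Y <- sim_var1(diag(0.5, 3), T_ = 80, sd = 0.5, seed = 9)
  f1 <- fit_dbn(mk_dense(Y), K = 0, seed = 4)
  f2 <- fit_dbn(mk_dense(Y), K = 0, seed = 4)
  expect_identical(f1$D, f2$D)
  expect_identical(f1$z, f2$z)
  expect_identical(f1$hyper, f2$hyper)
})

test_that("threshold_edges applies the two-sided normal quantile and signs edges", {
  f <- structure(list(
    K = 0L, D = matrix(c(0, 1, -2, 0), 2, 2,
                       dimnames = list(c("A", "B"), c("A", "B"))),
    z = matrix(c(0, 1, 2, 0), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B"))),
    molecules = c("A", "B"), hyper = list(lambda = 1),
    iterations = 1L, converged = TRUE, seed = 1
  ), class = "ss_fit")
  # alpha = 0.15: quantile ~ 1.4395; only |z| = 2 passes (edge B -> A)
  res <- threshold_edges(f, alpha = 0.15)
  expect_equal(res$threshold, qnorm(1 - 0.15 / 2))
  expect_equal(nrow(res$edges), 1)
  expect_equal(res$edges$from, "B")
  expect_equal(res$edges$to, "A")
  expect_equal(res$edges$sign, "inhibition")  # D entry is -2
  # alpha = 1: every entry with nonzero z becomes an edge
  res_all <- threshold_edges(f, alpha = 1)
  expect_equal(nrow(res_all$edges), 2)
  # alpha -> 0: no edges
  res_none <- threshold_edges(f, alpha = 1e-12)
  expect_equal(nrow(res_none$edges), 0)
  expect_error(threshold_edges(f, alpha = 0), "0, 1")
})

test_that("edge sets are nested as alpha increases", {
  Y <- sim_var1(rbind(c(0.6, 0, 0), c(0.4, 0.2, 0), c(0, -0.5, 0.3)),
                T_ = 150, sd = 0.5, seed = 12)
  f <- fit_dbn(mk_dense(Y), K = 0, seed = 1)
  alphas <- c(0.01, 0.05, 0.15, 0.5, 1)
  sets <- purrr::map(alphas, function(a) {
    e <- threshold_edges(f, a)$edges
    paste(e$from, e$to)
  })
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  }
})

test_that("empirical-Bayes shrinkage keeps the white-noise null edge rate at or below alpha", {
  # under an exact null the precision hyperparameters grow, z-scores are
  # under-dispersed, and the flagged fraction falls below the nominal rate
  fracs <- purrr::map_dbl(1:5, function(s) {
    set.seed(500 + s)
    Y <- matrix(rnorm(8 * 50), 8, 50, dimnames = list(paste0("m", 1:8), NULL))
    f <- suppressWarnings(fit_dbn(mk_dense(Y), K = 0, seed = s))
    e <- threshold_edges(f, alpha = 0.15)
    nrow(e$edges) / 64
  })
  expect_lte(mean(fracs), 0.15)
})
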