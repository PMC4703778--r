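# Dynamic consensus analysis: cubic smoothing-spline densification of the
# measured time courses, hidden-dimension selection from a block-Hankel
# matrix of autocovariances, and empirical-Bayes estimation of the linear
# feedback state-space model
#   x_t = A x_{t-1} + B y_{t-1} + w_t,   w_t ~ N(0, I)
#   y_t = C x_t + D y_{t-1} + v_t,       v_t ~ N(0, lambda^-1 I)
# whose observed-feedback matrix D is the inferred network.

#' Assemble consensus-molecule time courses
#'
#' Collects the full measured time course of every molecule that is a
#' consensus protein or consensus gene at any timepoint: proteins come from
#' the phosphoprotein layer, genes from the transcript layer. Row names are
#' `layer:symbol`.
#'
#' @param consensus_sets List of `consensus_set` objects.
#' @param phospho Phosphoprotein `omics_ts`.
#' @param transcripts Transcript `omics_ts` (same time grid).
#' @return Numeric matrix (molecule x measured timepoint) with attribute
#'   `times`.
#' @export
consensus_timecourse_matrix <- function(consensus_sets, phospho, transcripts) {
  assert_that(identical(phospho$timepoints, transcripts$timepoints),
              "layers must share one time grid (restrict_to_common_timepoints)")
  prot <- sort(unique(unlist(purrr::map(consensus_sets,
                                        function(cs) union(cs$proteins, cs$tfs)))))
  gene <- sort(unique(unlist(purrr::map(consensus_sets, "genes"))))
  prot <- intersect(prot, phospho$molecules)
  gene <- intersect(gene, transcripts$molecules)
  vals <- rbind(phospho$logfc[prot, , drop = FALSE],
                transcripts$logfc[gene, , drop = FALSE])
  rownames(vals) <- c(paste0("protein:", prot), paste0("gene:", gene))
  attr(vals, "times") <- phospho$timepoints
  vals
}

#' Densify time courses with cubic splines
#'
#' Fits one cubic spline per molecule through its measured `(time, logFC)`
#' pairs and evaluates it on an equally spaced grid spanning the measured
#' range, under the working assumption that signaling changes gradually
#' between samples. `gcv` mode uses a smoothing spline whose penalty is
#' chosen by generalized cross-validation; `interpolate` mode passes
#' exactly through the measured points. Each densified series is
#' standardized to zero mean and unit variance unless `standardize = FALSE`.
#'
#' @param values Numeric matrix (molecule x measured timepoint) with row
#'   names; e.g. from [consensus_timecourse_matrix()].
#' @param times Measured times in hours (>= 4 points); defaults to the
#'   matrix's `times` attribute.
#' @param n_grid Number of grid points (>= number of measured points).
#'   Default 50.
#' @param smoothing `"gcv"` or `"interpolate"`.
#' @param standardize Standardize each densified series (default `TRUE`).
#' @return A `dense_ts`: list with `molecules`, `grid`, `values`
#'   (molecule x grid), `standardized`, `smoothing`, `times_measured`.
#' @export
densify <- function(values, times = attr(values, "times"), n_grid = 50,
                    smoothing = c("gcv", "interpolate"), standardize = TRUE) {
  smoothing <- match.arg(smoothing)
  values <- as.matrix(values)
  assert_that(!is.null(rownames(values)), "values must have row names")
  assert_that(length(times) == ncol(values), "times must match columns of values")
  assert_that(length(times) >= 4,
              "densify needs at least 4 measured timepoints per molecule")
  assert_that(n_grid >= length(times), "n_grid must be >= number of measured points")
  grid <- seq(min(times), max(times), length.out = n_grid)
  dense <- matrix(NA_real_, nrow(values), n_grid,
                  dimnames = list(rownames(values), NULL))
  for (i in seq_len(nrow(values))) {
    y <- values[i, ]
    if (max(y) - min(y) == 0) {
      abort(paste0("constant (zero-variance) series: ", rownames(values)[i]))
    }
    dense[i, ] <- if (smoothing == "gcv") {
      fit <- smooth.spline(times, y, cv = FALSE)
      predict(fit, grid)$y
    } else {
      spline(times, y, xout = grid, method = "fmm")$y
    }
  }
  if (standardize) {
    sds <- apply(dense, 1, sd)
    if (any(sds == 0)) {
      abort(paste0("zero-variance densified series: ",
                   rownames(values)[which(sds == 0)[1]]))
    }
    dense <- (dense - rowMeans(dense)) / sds
  }
  structure(list(molecules = rownames(values), grid = grid, values = dense,
                 standardized = standardize, smoothing = smoothing,
                 times_measured = times),
            class = "dense_ts")
}

#' @export
print.dense_ts <- function(x, ...) {
  cat("<dense_ts> ", length(x$molecules), " molecules on ", length(x$grid),
      " grid points over [", min(x$grid), ", ", max(x$grid), "] h (",
      x$smoothing, if (x$standardized) ", standardized" else "", ")\n", sep = "")
  invisible(x)
}

#' Select the hidden-state dimension
#'
#' Builds the block-Hankel matrix of sample autocovariances of the observed
#' series and returns the smallest number of singular values whose
#' cumulative mass reaches `cutoff`, capped at `max_K`. A numerically zero
#' Hankel matrix gives `K = 0`.
#'
#' @param dense A `dense_ts`.
#' @param max_K Cap on the hidden dimension (and Hankel block depth).
#'   Default 5.
#' @param cutoff Cumulative singular-value mass required. Default 0.90.
#' @return Integer `K` in `0..max_K`.
#' @export
select_hidden_dim <- function(dense, max_K = 5, cutoff = 0.90) {
  Y <- dense$values
  P <- nrow(Y); T_ <- ncol(Y)
  m <- max(1L, as.integer(max_K))
  Yc <- Y - rowMeans(Y)
  gam <- lapply(seq_len(2 * m), function(l) {
    if (l >= T_) matrix(0, P, P)
    else Yc[, (1 + l):T_, drop = FALSE] %*% t(Yc[, 1:(T_ - l), drop = FALSE]) / T_
  })
  H <- matrix(0, m * P, m * P)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      H[((i - 1) * P + 1):(i * P), ((j - 1) * P + 1):(j * P)] <- gam[[i + j - 1]]
    }
  }
  s <- svd(H, nu = 0, nv = 0)$d
  if (sum(s) <= 1e-12) return(0L)
  K <- which(cumsum(s) / sum(s) >= cutoff)[1]
  as.integer(min(K, max_K))
}

#' Fit the empirical-Bayes linear feedback state-space model
#'
#' EM estimation of the model matrices A (hidden transition), B (input to
#' hidden), C (hidden to observed) and D (observed feedback - the network),
#' with hierarchical zero-mean Gaussian priors on the rows of each matrix
#' whose precision hyperparameters are updated by empirical Bayes at every
#' iteration, alongside the shared observation precision. Hidden-state
#' posteriors come from Kalman forward-backward recursions. With `K = 0`
#' the model reduces to the feedback-only form `y_t = D y_{t-1} + v_t`.
#' The per-edge z-score is the posterior mean of a D entry over its
#' posterior standard deviation.
#'
#' Convergence is declared when the maximum relative change of all
#' precision hyperparameters drops below `tol`; otherwise the fit is
#' returned with `converged = FALSE` and a warning.
#'
#' @param dense A `dense_ts` with standardized values (grid length >= 10).
#' @param K Hidden dimension (>= 0); `NULL` selects it with
#'   [select_hidden_dim()].
#' @param max_iter Maximum EM iterations. Default 100.
#' @param tol Relative hyperparameter change declaring convergence.
#'   Default 1e-3.
#' @param seed Seed for the random initialization of the model matrices.
#' @return An `ss_fit`: list with `K`, `A`, `B`, `C`, `D`, `z`,
#'   `hyper` (row precisions and observation precision), `iterations`,
#'   `converged`, `molecules`, `seed`.
#' @export
fit_dbn <- function(dense, K = NULL, max_iter = 100, tol = 1e-3, seed = 1) {
  Y <- dense$values
  P <- nrow(Y); T_ <- ncol(Y)
  assert_that(T_ >= 10, "fit_dbn needs a grid of length >= 10 (densify first)")
  if (is.null(K)) K <- select_hidden_dim(dense)
  K <- as.integer(K)
  assert_that(K >= 0, "K must be >= 0")

  set.seed(derive_seed(seed, 17L))
  A <- matrix(rnorm(K * K, sd = 0.1), K, K)
  B <- matrix(rnorm(K * P, sd = 0.1), K, P)
  C <- matrix(rnorm(P * K, sd = 0.1), P, K)
  D <- matrix(rnorm(P * P, sd = 0.1), P, P)
  alpha <- rep(1, K); beta <- rep(1, K)
  gamma_ <- rep(1, P); delta <- rep(1, P)
  lambda <- 1
  n <- T_ - 1

  Yprev <- Y[, -T_, drop = FALSE]   # y_{t-1}, t = 2..T
  Ycur <- Y[, -1, drop = FALSE]     # y_t
  S_yy_prev <- Yprev %*% t(Yprev)
  S_yprev_ycur <- Yprev %*% t(Ycur)
  sum_y2 <- rowSums(Ycur^2)

  converged <- FALSE
  it <- 0
  D_sd <- matrix(NA_real_, P, P)
  while (it < max_iter) {
    it <- it + 1
    hyper_old <- c(alpha, beta, gamma_, delta, lambda)

    if (K > 0) {
      sm <- kalman_smoother(Y, A, B, C, D, lambda)
      S_x_prev <- sm$S_x_prev; S_xy_prev <- sm$S_xy_prev
      S_xx_cross <- sm$S_xx_cross; S_x_cur <- sm$S_x_cur
      S_xy_cur_prev <- sm$S_xy_cur_prev; S_x_ycur <- sm$S_x_ycur
      # hidden-equation rows (state noise precision fixed at 1)
      Szz <- rbind(cbind(S_x_prev, S_xy_prev),
                   cbind(t(S_xy_prev), S_yy_prev))
      for (k in seq_len(K)) {
        rhs <- c(S_xx_cross[k, ], S_xy_cur_prev[k, ])
        Prec <- Szz + diag(c(rep(alpha[k], K), rep(beta[k], P)),
                           nrow = K + P)
        Sig <- chol2inv(chol(Prec))
        mk <- Sig %*% rhs
        A[k, ] <- mk[seq_len(K)]
        B[k, ] <- mk[K + seq_len(P)]
        alpha[k] <- K / (sum(mk[seq_len(K)]^2) +
                           sum(diag(Sig)[seq_len(K)]))
        beta[k] <- P / (sum(mk[K + seq_len(P)]^2) +
                          sum(diag(Sig)[K + seq_len(P)]))
      }
      Sww <- rbind(cbind(S_x_cur, S_xy_cur_prev),
                   cbind(t(S_xy_cur_prev), S_yy_prev))
      rhs_all <- rbind(S_x_ycur, S_yprev_ycur)  # (K+P) x P, column j
    } else {
      Sww <- S_yy_prev
      rhs_all <- S_yprev_ycur
    }
    rss <- 0
    for (j in seq_len(P)) {
      rhs <- rhs_all[, j]
      Prec <- lambda * Sww + diag(c(rep(gamma_[j], K), rep(delta[j], P)),
                                  nrow = K + P)
      Sig <- chol2inv(chol(Prec))
      mj <- Sig %*% (lambda * rhs)
      if (K > 0) {
        C[j, ] <- mj[seq_len(K)]
        gamma_[j] <- K / (sum(mj[seq_len(K)]^2) + sum(diag(Sig)[seq_len(K)]))
      }
      D[j, ] <- mj[K + seq_len(P)]
      D_sd[j, ] <- sqrt(diag(Sig)[K + seq_len(P)])
      delta[j] <- P / (sum(mj[K + seq_len(P)]^2) +
                         sum(diag(Sig)[K + seq_len(P)]))
      rss <- rss + sum_y2[j] - 2 * sum(mj * rhs) +
        drop(t(mj) %*% Sww %*% mj) + sum(Sww * Sig)
    }
    rss <- max(rss, 1e-12)
    lambda <- (P * n) / rss

    hyper_new <- c(alpha, beta, gamma_, delta, lambda)
    if (!all(is.finite(hyper_new)) || !all(is.finite(D))) {
      abort(paste0("non-finite values during EM at iteration ", it))
    }
    if (max(abs(hyper_new - hyper_old) / pmax(abs(hyper_old), 1e-12)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(paste0("fit_dbn did not converge within ", max_iter, " iterations"))
  }
  z <- D / D_sd
  dimnames(D) <- dimnames(z) <- list(dense$molecules, dense$molecules)
  structure(list(K = K, A = A, B = B, C = C, D = D, z = z,
                 hyper = list(alpha = alpha, beta = beta, gamma = gamma_,
                              delta = delta, lambda = lambda),
                 iterations = it, converged = converged,
                 molecules = dense$molecules, seed = seed),
            class = "ss_fit")
}

#' Kalman forward-backward (RTS) recursions for the E-step
#' @noRd
kalman_smoother <- function(Y, A, B, C, D, lambda) {
  P <- nrow(Y); T_ <- ncol(Y); K <- nrow(A)
  IK <- diag(K)
  R <- diag(1 / lambda, P)
  xf <- matrix(0, K, T_); Pf <- array(0, c(K, K, T_))
  xp <- matrix(0, K, T_); Pp <- array(0, c(K, K, T_))
  xf[, 1] <- 0; Pf[, , 1] <- IK
  for (t in 2:T_) {
    xp[, t] <- A %*% xf[, t - 1] + B %*% Y[, t - 1]
    Pp[, , t] <- A %*% Pf[, , t - 1] %*% t(A) + IK
    S <- C %*% Pp[, , t] %*% t(C) + R
    Kg <- Pp[, , t] %*% t(C) %*% solve(S)
    innov <- Y[, t] - C %*% xp[, t] - D %*% Y[, t - 1]
    xf[, t] <- xp[, t] + Kg %*% innov
    Pf[, , t] <- (IK - Kg %*% C) %*% Pp[, , t]
  }
  xs <- xf; Ps <- Pf
  Pcross <- array(0, c(K, K, T_))  # Ps_{t, t-1} stored at t
  for (t in T_:2) {
    J <- Pf[, , t - 1] %*% t(A) %*% solve(Pp[, , t])
    xs[, t - 1] <- xf[, t - 1] + J %*% (xs[, t] - xp[, t])
    Ps[, , t - 1] <- Pf[, , t - 1] +
      J %*% (Ps[, , t] - Pp[, , t]) %*% t(J)
    Pcross[, , t] <- Ps[, , t] %*% t(J)
  }
  idx_prev <- 1:(T_ - 1); idx_cur <- 2:T_
  S_x_prev <- matrix(0, K, K); S_x_cur <- matrix(0, K, K)
  S_xx_cross <- matrix(0, K, K)
  for (t in idx_cur) {
    S_x_prev <- S_x_prev + Ps[, , t - 1] + tcrossprod(xs[, t - 1])
    S_x_cur <- S_x_cur + Ps[, , t] + tcrossprod(xs[, t])
    S_xx_cross <- S_xx_cross + Pcross[, , t] + tcrossprod(xs[, t], xs[, t - 1])
  }
  list(
    S_x_prev = S_x_prev,
    S_x_cur = S_x_cur,
    S_xx_cross = S_xx_cross,
    S_xy_prev = xs[, idx_prev, drop = FALSE] %*% t(Y[, idx_prev, drop = FALSE]),
    S_xy_cur_prev = xs[, idx_cur, drop = FALSE] %*% t(Y[, idx_prev, drop = FALSE]),
    S_x_ycur = xs[, idx_cur, drop = FALSE] %*% t(Y[, idx_cur, drop = FALSE])
  )
}

#' Threshold the inferred network at a chance-edge probability
#'
#' Retains the directed edge `i -> j` when `|z(j, i)|` exceeds the
#' two-sided standard-normal quantile for `alpha`, the probability of an
#' edge being present by chance. Retained edges are signed by the
#' corresponding D entry: activating when positive, inhibiting when
#' negative. Self-loops (self-activation / self-inhibition) are allowed.
#'
#' @param fit An `ss_fit` from [fit_dbn()].
#' @param alpha Chance-edge probability in (0, 1]. Default 0.15.
#' @return A `dbn_result`: list with `fit`, `z`, `alpha`, `threshold` and
#'   `edges` (tibble: `from`, `to`, `z`, `coefficient`, `sign`).
#' @export
threshold_edges <- function(fit, alpha = 0.15) {
  assert_that(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha <= 1,
              "alpha must lie in (0, 1]")
  q <- qnorm(1 - alpha / 2)
  keep <- which(abs(fit$z) > q, arr.ind = TRUE)  # rows j (target), cols i (source)
  mols <- fit$molecules
  edges <- tibble::tibble(
    from = mols[keep[, 2]],
    to = mols[keep[, 1]],
    z = fit$z[keep],
    coefficient = fit$D[keep],
    sign = ifelse(fit$D[keep] > 0, "activation", "inhibition")
  )
  edges <- dplyr::arrange(edges, .data$from, .data$to)
  structure(list(fit = fit, z = fit$z, alpha = alpha, threshold = q,
                 edges = edges),
            class = "dbn_result")
}

#' @export
print.dbn_result <- function(x, ...) {
  cat("<dbn_result> ", length(x$fit$molecules), " molecules, alpha=",
      x$alpha, " (|z| > ", round(x$threshold, 4), "): ",
      nrow(x$edges), " edges (", sum(x$edges$sign == "activation"),
      " activating)\n", sep = "")
  invisible(x)
}

#' @describeIn fit_dbn one row per ordered molecule pair with its
#'   feedback coefficient and z-score.
#' @param x An `ss_fit`.
#' @param ... Unused.
#' @export
tidy.ss_fit <- function(x, ...) {
  mols <- x$molecules
  P <- length(mols)
  tibble::tibble(
    from = rep(mols, each = P),
    to = rep(mols, times = P),
    coefficient = as.vector(t(x$D)),
    z = as.vector(t(x$z))
  )
}

#' @describeIn fit_dbn one-row model summary.
#' @export
glance.ss_fit <- function(x, ...) {
  tibble::tibble(K = x$K, n_molecules = length(x$molecules),
                 iterations = x$iterations, converged = x$converged,
                 obs_precision = x$hyper$lambda)
}

#' @describeIn threshold_edges the thresholded edge table.
#' @param x A `dbn_result`.
#' @param ... Unused.
#' @export
tidy.dbn_result <- function(x, ...) x$edges

#' Write dense series as TSV
#' @param dense A `dense_ts`.
#' @param path Output file.
#' @export
write_dense_ts <- function(dense, path) {
  header <- paste(c("molecule", fmt_num(dense$grid)), collapse = "\t")
  body <- vapply(seq_along(dense$molecules), function(i) {
    paste(c(dense$molecules[i], fmt_num(dense$values[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a thresholded dynamic network as SIF or GraphML
#' @param result A `dbn_result`.
#' @param path Output file.
#' @param format `"sif"` or `"graphml"`.
#' @export
write_dbn_network <- function(result, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  e <- result$edges
  if (format == "sif") {
    writeLines(paste(e$from, e$sign, e$to, sep = "\t"), path)
  } else {
    g <- igraph::graph_from_data_frame(
      data.frame(from = e$from, to = e$to, z = e$z, sign = e$sign,
                 alpha = result$alpha),
      directed = TRUE,
      vertices = data.frame(name = result$fit$molecules)
    )
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
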