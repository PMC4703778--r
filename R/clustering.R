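# Fuzzy c-means time-profile clustering of consensus molecules. The
# alternating membership/centroid updates, restart policy and objective
# trace are implemented here because downstream selection and diagnostics
# depend on them.

#' Fuzzy c-means clustering of time profiles
#'
#' Soft-clusters standardized time profiles by alternating the classic
#' updates
#' `u(i,k) = 1 / sum_j (d(i,k)/d(i,j))^(2/(m-1))` and
#' `centroid_k = sum_i u(i,k)^m x_i / sum_i u(i,k)^m`
#' until the largest membership change falls below `tol`. The best of
#' `restarts` seeded random initializations by final objective
#' `sum u^m d^2` is returned. A profile at zero distance from a centroid is
#' hard-assigned (membership 1) to it.
#'
#' @param X Numeric matrix (molecule x timepoint); rows should be
#'   standardized so shape, not magnitude, drives the clustering.
#' @param c Number of clusters (1 <= c <= rows).
#' @param m Fuzzifier (> 1). Default 2; values near 1 approach hard
#'   clustering.
#' @param tol Convergence tolerance on memberships. Default 1e-6.
#' @param max_iter Iterations per restart. Default 200.
#' @param restarts Random initializations. Default 10.
#' @param seed Seed for the initializations.
#' @return A `fuzzy_clustering`: list with `membership` (molecule x c),
#'   `centroids` (c x timepoint), `objective` (per-iteration trace of the
#'   best restart), `c`, `m`, `seed`.
#' @export
fuzzy_cmeans <- function(X, c, m = 2, tol = 1e-6, max_iter = 200,
                         restarts = 10, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  assert_that(c >= 1 && c == round(c), "c must be a positive integer")
  assert_that(c <= n, paste0("c (", c, ") exceeds the number of rows (", n, ")"))
  assert_that(m > 1, "fuzzifier m must be > 1")
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(derive_seed(seed, r))
    U <- matrix(runif(n * c), n, c)
    U <- U / rowSums(U)
    run <- fcm_run(X, U, c, m, tol, max_iter)
    if (is.null(best) || run$objective[length(run$objective)] <
        best$objective[length(best$objective)]) {
      best <- run
    }
  }
  structure(list(membership = best$U, centroids = best$centroids,
                 objective = best$objective, c = c, m = m, seed = seed),
            class = "fuzzy_clustering")
}

#' @noRd
fcm_run <- function(X, U, c, m, tol, max_iter) {
  n <- nrow(X)
  Cent <- matrix(0, c, ncol(X))
  trace_ <- numeric()
  for (it in seq_len(max_iter)) {
    Um <- U^m
    wsum <- colSums(Um)
    ok <- wsum > 1e-12
    Cent[ok, ] <- (t(Um[, ok, drop = FALSE]) %*% X) / wsum[ok]
    D2 <- pmax(outer(rowSums(X^2), rep(1, c)) +
                 outer(rep(1, n), rowSums(Cent^2)) - 2 * X %*% t(Cent), 0)
    Unew <- matrix(0, n, c)
    for (i in seq_len(n)) {
      zero <- which(D2[i, ] < 1e-12)
      if (length(zero)) {
        Unew[i, zero[1]] <- 1
      } else {
        d <- D2[i, ]^(1 / (m - 1))
        Unew[i, ] <- (1 / d) / sum(1 / d)
      }
    }
    delta <- max(abs(Unew - U))
    U <- Unew
    trace_ <- c(trace_, sum((U^m) * D2))
    if (delta < tol) break
  }
  dimnames(U) <- list(rownames(X), paste0("cluster", seq_len(c)))
  dimnames(Cent) <- list(paste0("cluster", seq_len(c)), colnames(X))
  list(U = U, centroids = Cent, objective = trace_)
}

#' @export
print.fuzzy_clustering <- function(x, ...) {
  sizes <- table(factor(max.col(x$membership), levels = seq_len(x$c)))
  cat("<fuzzy_clustering> c=", x$c, ", m=", x$m, ", ",
      nrow(x$membership), " profiles; hard sizes: ",
      paste(as.integer(sizes), collapse = "/"), "; objective ",
      signif(x$objective[length(x$objective)], 6), "\n", sep = "")
  invisible(x)
}

#' @describeIn fuzzy_cmeans one row per molecule with its max-membership
#'   cluster and membership values.
#' @param x A `fuzzy_clustering`.
#' @param ... Unused.
#' @export
tidy.fuzzy_clustering <- function(x, ...) {
  U <- x$membership
  tibble::tibble(
    molecule = rownames(U) %||% as.character(seq_len(nrow(U))),
    cluster = max.col(U),
    membership = U[cbind(seq_len(nrow(U)), max.col(U))]
  )
}

#' @describeIn fuzzy_cmeans one-row summary (cluster count, objective,
#'   iterations).
#' @export
glance.fuzzy_clustering <- function(x, ...) {
  tibble::tibble(c = x$c, m = x$m,
                 objective = x$objective[length(x$objective)],
                 iterations = length(x$objective))
}

#' Choose the cluster count from centroid separation
#'
#' Runs [fuzzy_cmeans()] for every candidate `c` and tracks the minimum
#' pairwise centroid distance. Splitting a real co-regulation pattern makes
#' two centroids nearly coincide, so this distance collapses once `c`
#' exceeds the number of distinct patterns; the rule returns the largest
#' `c` whose minimum centroid separation still exceeds `drop_frac` times
#' the separation at the smallest candidate.
#'
#' @param X Standardized profile matrix (rows >= 3).
#' @param c_range Candidate cluster counts, within `[2, rows - 1]`.
#'   Default `2:8`.
#' @param m Fuzzifier. Default 2.
#' @param seed Seed passed to each [fuzzy_cmeans()] run.
#' @param drop_frac Fraction of the initial centroid separation below
#'   which the structure is considered collapsed. Default 0.3.
#' @return Selected integer cluster count.
#' @export
select_cluster_count <- function(X, c_range = 2:8, m = 2, seed = 1,
                                 drop_frac = 0.3) {
  X <- as.matrix(X)
  assert_that(nrow(X) >= 3, "need at least 3 profiles to select a cluster count")
  c_range <- sort(unique(as.integer(c_range)))
  assert_that(min(c_range) >= 2 && max(c_range) <= nrow(X) - 1,
              "c_range must lie within [2, rows - 1]")
  md <- vapply(c_range, function(cc) {
    fit <- fuzzy_cmeans(X, cc, m = m, seed = seed)
    min(stats::dist(fit$centroids))
  }, numeric(1))
  thr <- drop_frac * md[1]
  below <- which(md < thr)
  if (!length(below)) return(max(c_range))
  if (below[1] == 1) return(c_range[1])
  c_range[below[1] - 1]
}

#' Write clustering outputs as TSV
#' @param x A `fuzzy_clustering`.
#' @param membership_path,centroid_path Output files.
#' @export
write_clustering <- function(x, membership_path, centroid_path) {
  U <- x$membership
  writeLines(c(paste(c("molecule", colnames(U)), collapse = "\t"),
               vapply(seq_len(nrow(U)), function(i) {
                 paste(c(rownames(U)[i], fmt_num(U[i, ])), collapse = "\t")
               }, character(1))), membership_path)
  Cm <- x$centroids
  writeLines(c(paste(c("cluster", colnames(Cm) %||% seq_len(ncol(Cm))),
                     collapse = "\t"),
               vapply(seq_len(nrow(Cm)), function(i) {
                 paste(c(rownames(Cm)[i], fmt_num(Cm[i, ])), collapse = "\t")
               }, character(1))), centroid_path)
  invisible(membership_path)
}
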