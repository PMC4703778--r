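# ggplot2 views of the main result types.

#' @describeIn consensus_profiles presence/absence heatmap of consensus
#'   membership over time.
#' @param object A `consensus_profiles` tibble.
#' @param ... Unused.
#' @export
autoplot.consensus_profiles <- function(object, ...) {
  tps <- attr(object, "timepoints")
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = dplyr::all_of(as.character(tps)),
                              names_to = "time", values_to = "present")
  long$time <- factor(as.numeric(long$time), levels = tps)
  long$row <- paste0(long$symbol, " (", long$layer, ")")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$row,
                                     fill = .data$present)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "white", `TRUE` = "#2c7fb8"),
                               name = "in consensus") +
    ggplot2::labs(x = "time after stimulation [h]", y = NULL,
                  title = "Static consensus profiles") +
    ggplot2::theme_minimal()
}

#' @describeIn fuzzy_cmeans cluster centroid curves over time.
#' @param object A `fuzzy_clustering`.
#' @export
autoplot.fuzzy_clustering <- function(object, ...) {
  Cm <- object$centroids
  times <- suppressWarnings(as.numeric(colnames(Cm)))
  if (anyNA(times)) times <- seq_len(ncol(Cm))
  long <- tibble::tibble(
    cluster = rep(rownames(Cm), times = ncol(Cm)),
    time = rep(times, each = nrow(Cm)),
    value = as.vector(Cm)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     color = .data$cluster)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(x = "time [h]", y = "standardized logFC",
                  title = "Fuzzy c-means cluster centroids") +
    ggplot2::theme_minimal()
}

#' @describeIn threshold_edges signed edge map of the inferred dynamic
#'   network (z-scores, retained edges outlined).
#' @param object A `dbn_result`.
#' @export
autoplot.dbn_result <- function(object, ...) {
  z <- object$z
  mols <- object$fit$molecules
  long <- tibble::tibble(
    from = rep(mols, times = nrow(z)),
    to = rep(mols, each = ncol(z)),
    z = as.vector(t(z))
  )
  long$retained <- abs(long$z) > object$threshold
  ggplot2::ggplot(long, ggplot2::aes(x = .data$from, y = .data$to,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = long[long$retained, , drop = FALSE],
                       fill = NA, color = "black", linewidth = 0.6) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", name = "z") +
    ggplot2::labs(x = "regulator", y = "target",
                  title = paste0("Dynamic consensus network (alpha = ",
                                 object$alpha, ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @describeIn integrate_time_courses matched transcript/protein time
#'   courses per anchor phosphoprotein.
#' @param object An `integration_result`.
#' @export
autoplot.integration_result <- function(object, ...) {
  s <- object$series
  ggplot2::ggplot(s, ggplot2::aes(x = .data$time, y = .data$logfc,
                                  color = .data$symbol,
                                  linetype = .data$layer)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~anchor) +
    ggplot2::labs(x = "time after stimulation [h]", y = "log2 fold change",
                  title = "Time-course integration",
                  subtitle = "solid: transcript, dashed: protein") +
    ggplot2::scale_linetype_manual(values = c(transcript = "solid",
                                              protein = "dashed")) +
    ggplot2::theme_minimal()
}
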