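#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a metric time series with its spread band
#'
#' @param object A `series_stat` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.series_stat <- function(object, ...) {
  lab <- attr(object, "label")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$spread,
                                      ymax = .data$mean + .data$spread),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [ns]", y = lab %||% "value") +
    ggplot2::theme_minimal()
}

#' Plot a contact-occupancy matrix with chain-boundary gridlines
#'
#' @param object An `occupancy_matrix`.
#' @param mask_near_diagonal Hide the diagonal and sequence-adjacent
#'   intra-chain pairs (default FALSE; the raw map keeps them).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.occupancy_matrix <- function(object, mask_near_diagonal = FALSE,
                                      ...) {
  m <- unclass(object)
  attrs <- attributes(object)
  n <- nrow(m)
  if (mask_near_diagonal) {
    res <- attrs$residues
    same_chain <- outer(res$chain, res$chain, "==")
    near <- abs(outer(seq_len(n), seq_len(n), "-")) <= 1
    m[same_chain & near] <- NA
  }
  df <- tibble::tibble(i = rep(seq_len(n), times = n),
                       j = rep(seq_len(n), each = n),
                       occupancy = as.vector(m))
  bnd <- attrs$chain_boundaries
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                        fill = .data$occupancy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "residue", y = "residue",
                  fill = "occupancy") +
    ggplot2::theme_minimal()
  if (length(bnd) > 1) {
    cuts <- utils::head(as.numeric(bnd), -1) + 0.5
    p <- p + ggplot2::geom_hline(yintercept = cuts, linewidth = 0.3) +
      ggplot2::geom_vline(xintercept = cuts, linewidth = 0.3)
  }
  p
}

#' Plot per-residue RMSF profiles
#'
#' @param rmsf Tibble from [rmsf_per_residue()]; an optional `phase`
#'   column facets the plot.
#' @return A ggplot.
#' @export
plot_rmsf <- function(rmsf) {
  p <- ggplot2::ggplot(rmsf, ggplot2::aes(x = .data$resno, y = .data$rmsf,
                                          colour = .data$chain)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "RMSF [A]") +
    ggplot2::theme_minimal()
  if ("phase" %in% names(rmsf)) {
    p <- p + ggplot2::facet_wrap(~phase)
  }
  p
}

#' Plot per-metric compaction and recovery from a recovery report
#'
#' @param object A `recovery_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.recovery_report <- function(object, ...) {
  s <- tidyr::pivot_longer(object$summary,
                           c("compaction_pct", "recovery_pct"),
                           names_to = "quantity", values_to = "pct")
  ggplot2::ggplot(s, ggplot2::aes(x = .data$metric, y = .data$pct)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "%") +
    ggplot2::theme_minimal()
}
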