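# ggplot2 visualisations for the main result types.

#' Plot a free-energy landscape
#'
#' Heatmap of the landscape grid; empty bins (infinite free energy) are
#' shown at the maximum finite free energy plus one RT so the basin
#' structure stays readable.
#'
#' @param object A `fel`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fel <- function(object, ...) {
  g <- object$grid
  RT <- iondyn_constants$R_kj * object$temperature
  cap <- max(g$dG[is.finite(g$dG)]) + RT
  g$dG_plot <- pmin(g$dG, cap)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$dG_plot)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(Delta * G ~ "(kJ/mol)"),
                                  option = "turbo") +
    ggplot2::labs(x = "dPC1", y = "dPC2") +
    ggplot2::theme_minimal()
}

#' Plot a dynamic cross-correlation matrix
#'
#' @param object A `dccm`.
#' @param domain_breaks Optional residue positions at which to draw dashed
#'   domain demarcations.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dccm <- function(object, domain_breaks = NULL, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$i, y = .data$j,
                                       fill = .data$correlation)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "red", mid = "white", high = "blue",
                                  limits = c(-1, 1), name = "Pearson r") +
    ggplot2::labs(x = "residue index", y = "residue index") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
  if (!is.null(domain_breaks)) {
    p <- p + ggplot2::geom_vline(xintercept = domain_breaks, linetype = "dashed") +
      ggplot2::geom_hline(yintercept = domain_breaks, linetype = "dashed")
  }
  p
}

#' Plot a radial distribution function
#'
#' g(r) with the running coordination number on a secondary axis.
#'
#' @param object An `rdf_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rdf_profile <- function(object, ...) {
  p <- object$profile
  ggplot2::ggplot(p, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$g)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_count), linetype = "dotted") +
    ggplot2::labs(x = "r (nm)", y = "g(r)  /  cumulative count (dotted)") +
    ggplot2::theme_minimal()
}

#' Scree plot of a PC model
#'
#' @param object A `pc_model` or `cartesian_pc`.
#' @param n_components Components shown.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pc_model <- function(object, n_components = 10, ...) {
  d <- tidy(object)
  d <- d[seq_len(min(n_components, nrow(d))), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$var_fraction)) +
    ggplot2::geom_col() +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative)) +
    ggplot2::labs(x = "component", y = "variance fraction (bars), cumulative (line)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pc_model
#' @export
autoplot.cartesian_pc <- function(object, n_components = 10, ...) {
  d <- tidy(object)
  d <- d[seq_len(min(n_components, nrow(d))), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component,
                                  y = .data$var_fraction_internal)) +
    ggplot2::geom_col() +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative_internal)) +
    ggplot2::labs(x = "component",
                  y = "internal variance fraction (bars), cumulative (line)") +
    ggplot2::theme_minimal()
}

#' Per-residue RMSF profile plot
#'
#' @param rmsf Tibble from [rmsf_per_residue()] (or its `per_residue`
#'   attribute).
#' @return A ggplot.
#' @export
plot_rmsf <- function(rmsf) {
  d <- attr(rmsf, "per_residue") %||% rmsf
  ggplot2::ggplot(d, ggplot2::aes(x = .data$resid, y = .data$rmsf)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "RMSF (nm)") +
    ggplot2::theme_minimal()
}

#' Time-series plot for geometry observables
#'
#' @param series A tibble with a `time` column and one value column (as
#'   returned by [radius_of_gyration()], [rmsd_series()], [com_distance()]).
#' @return A ggplot.
#' @export
plot_series <- function(series) {
  val <- setdiff(names(series), "time")[1]
  ggplot2::ggplot(series, ggplot2::aes(x = .data$time, y = .data[[val]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ns)", y = sprintf("%s (nm)", val)) +
    ggplot2::theme_minimal()
}
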