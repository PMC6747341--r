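# broom-style tidy()/glance() methods for the fitted-object classes.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a principal component model
#'
#' @param x A `pc_model`.
#' @param ... Unused.
#' @return Tibble `component`, `eigenvalue`, `var_fraction`, `cumulative`.
#' @export
tidy.pc_model <- function(x, ...) {
  tibble::tibble(component = seq_along(x$values), eigenvalue = x$values,
                 var_fraction = x$var_fraction,
                 cumulative = cumsum(x$var_fraction))
}

#' @rdname tidy.pc_model
#' @export
glance.pc_model <- function(x, ...) {
  tibble::tibble(n_frames = nrow(x$projections), n_dims = length(x$values),
                 total_variance = sum(x$values))
}

#' Tidy a Cartesian PC model
#'
#' @param x A `cartesian_pc`.
#' @param ... Unused.
#' @return Tibble `component`, `eigenvalue`, `var_fraction`,
#'   `var_fraction_internal`, cumulative columns.
#' @export
tidy.cartesian_pc <- function(x, ...) {
  tibble::tibble(component = seq_along(x$values), eigenvalue = x$values,
                 var_fraction = x$var_fraction,
                 var_fraction_internal = x$var_fraction_internal,
                 cumulative_internal = cumsum(x$var_fraction_internal))
}

#' Tidy a cluster model
#'
#' @param x A `cluster_model`.
#' @param ... Unused.
#' @return One row per cluster: `cluster`, `size`, centroid coordinates.
#' @export
tidy.cluster_model <- function(x, ...) {
  cen <- tibble::as_tibble(as.data.frame(x$centroids))
  names(cen) <- paste0("centroid_", seq_len(ncol(cen)))
  dplyr::bind_cols(tibble::tibble(cluster = seq_len(x$k), size = x$sizes), cen)
}

#' @rdname tidy.cluster_model
#' @export
glance.cluster_model <- function(x, ...) {
  tibble::tibble(k = x$k, sse = x$sse, s_avg = x$s_avg, seed = x$seed)
}

#' Tidy a free-energy landscape
#'
#' @param x A `fel`.
#' @param ... Unused.
#' @return The grid tibble (`x`, `y`, `count`, `prob`, `dG`).
#' @export
tidy.fel <- function(x, ...) x$grid

#' Tidy a dynamic cross-correlation matrix
#'
#' @param x A `dccm`.
#' @param ... Unused.
#' @return Long tibble `i`, `j`, `resid_i`, `resid_j`, `correlation`.
#' @export
tidy.dccm <- function(x, ...) {
  n <- nrow(x$matrix)
  tibble::tibble(
    i = rep(seq_len(n), times = n), j = rep(seq_len(n), each = n),
    resid_i = rep(x$resid, times = n), resid_j = rep(x$resid, each = n),
    correlation = as.numeric(x$matrix)
  )
}

#' Tidy an RDF profile
#'
#' @param x An `rdf_profile`.
#' @param ... Unused.
#' @return The profile tibble (`r`, `g`, `occupancy`, `mean_count`).
#' @export
tidy.rdf_profile <- function(x, ...) x$profile

#' Tidy an energy series
#'
#' @param x An `energy_series`.
#' @param ... Unused.
#' @return The per-frame tibble (`time`, `lj`, `coulomb`, `total`).
#' @export
tidy.energy_series <- function(x, ...) x$series

#' @rdname tidy.energy_series
#' @export
glance.energy_series <- function(x, ...) {
  s <- x$series
  tibble::tibble(n_frames = nrow(s), mean_total = mean(s$total),
                 sd_total = stats::sd(s$total), mean_lj = mean(s$lj),
                 mean_coulomb = mean(s$coulomb))
}

#' Tidy a binding report into long form
#'
#' @param x A `binding_report`.
#' @param ... Unused.
#' @return Tibble `ion`, `term`, `estimate`, `se`.
#' @export
tidy.binding_report <- function(x, ...) {
  terms <- c("e_vdw", "e_elec", "g_polar", "g_nonpolar", "minus_TdS",
             "e_binding", "g_binding")
  dplyr::bind_rows(lapply(seq_len(nrow(x)), function(i) {
    tibble::tibble(ion = x$ion[i], term = terms,
                   estimate = as.numeric(x[i, terms]),
                   se = as.numeric(x[i, paste0(terms, "_se")]))
  }))
}
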