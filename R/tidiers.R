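#' Tidy a treatment plan into a leaf-position table
#'
#' One row per (beam, aperture, MLC row) with the validity span, the open
#' leaf interval (half-open columns) and the aperture intensity.
#'
#' @param x A `dao_plan`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.dao_plan <- function(x, ...) {
  purrr::imap(x$beams, function(b, c_idx) {
    purrr::imap(b$shapes, function(s, k) {
      tibble::tibble(beam = c_idx, angle = x$bac$angles[c_idx], aperture = k,
                     row = seq_len(s$n_row),
                     span_lo = s$span_lo, span_hi = s$span_hi,
                     open_lo = s$open_lo, open_hi = s$open_hi,
                     intensity = b$intensities[k])
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' One-row plan summary
#'
#' @param x A `dao_plan`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.dao_plan <- function(x, ...) {
  dplyr::mutate(beam_on_time(x), n_beams = x$bac$n_beams, .before = 1)
}

#' Tidy a search result into its iteration trace
#' @param x A `dao_search`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.dao_search <- function(x, ...) x$trace

#' One-row search summary
#' @param x A `dao_search`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.dao_search <- function(x, ...) {
  bt <- beam_on_time(x$plan)
  tibble::tibble(variant = x$variant, z = x$z, iterations = nrow(x$trace),
                 termination = x$termination,
                 n_apertures = bt$n_apertures, n_active = bt$n_active,
                 beam_on_time = bt$beam_on_time)
}

#' @exportS3Method generics::tidy
tidy.dao_awo <- function(x, ...) {
  tibble::tibble(aperture = seq_along(x$intensities),
                 intensity = x$intensities)
}

#' @exportS3Method generics::glance
glance.dao_awo <- function(x, ...) {
  tibble::tibble(objective = x$objective, status = x$status,
                 kkt_residual = x$kkt_residual)
}

#' @exportS3Method generics::tidy
tidy.dao_comparison <- function(x, ...) x$pairwise

#' @exportS3Method generics::glance
glance.dao_comparison <- function(x, ...) x$means

#' Plot a DVH curve
#' @param object A `dao_dvh` tibble from [dvh()].
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.dao_dvh <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$threshold,
                                       y = 100 * .data$fraction)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume (%)") +
    ggplot2::theme_minimal()
}

#' Plot a search trace (objective per iteration)
#' @param object A `dao_search`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.dao_search <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$z_after)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$accepted), size = 1.5) +
    ggplot2::labs(x = "Iteration", y = "Objective z",
                  title = paste0("Search trace (", object$variant, ")")) +
    ggplot2::theme_minimal()
}

#' Fluence-map heat map for one or all beams of a plan
#'
#' @param plan A `dao_plan`.
#' @param beam Beam index, or `NULL` for all beams facetted.
#' @export
plot_fluence <- function(plan, beam = NULL) {
  beams <- if (is.null(beam)) seq_along(plan$beams) else beam
  df <- purrr::map(beams, function(c_idx) {
    A <- aggregate_fluence(plan$beams[[c_idx]])
    tibble::tibble(beam = paste0("beam ", c_idx, " (",
                                 plan$bac$angles[c_idx], "°)"),
                   row = rep(seq_len(nrow(A)), times = ncol(A)),
                   col = rep(seq_len(ncol(A)), each = nrow(A)),
                   fluence = as.vector(A))
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$fluence)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::facet_wrap(~beam) +
    ggplot2::labs(x = "Beamlet column", y = "MLC row", fill = "MU") +
    ggplot2::theme_minimal()
}
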