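#' Percentage reduction of a quantity
#'
#' `100 * (reference - new) / reference`, rounded half-up to `digits`
#' decimals for reporting (pass `digits = NULL` for full precision).
#'
#' @param reference Baseline value (non-zero).
#' @param new New value.
#' @param digits Decimals for half-up rounding; `NULL` disables rounding.
#' @export
percent_reduction <- function(reference, new, digits = 2) {
  if (any(reference == 0)) abort("reference must be non-zero")
  pct <- 100 * (reference - new) / reference
  if (is.null(digits)) return(pct)
  round_half_up(pct, digits)
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Cross-algorithm comparison report
#'
#' Column means over beam-angle configurations per algorithm, then pairwise
#' percentage improvements `100 * (ref - new) / ref` on those means for every
#' ordered algorithm pair.
#'
#' @param results Tibble with columns `algorithm`, `bac`, and one or more of
#'   `z`, `n_apertures`, `beam_on_time`.
#' @return A `dao_comparison`: `$means` (per-algorithm column means) and
#'   `$pairwise` (tibble `reference`, `algorithm`, `metric`,
#'   `reduction_pct`), empty with a single algorithm.
#' @export
build_comparison <- function(results) {
  stopifnot(all(c("algorithm", "bac") %in% names(results)))
  metrics <- intersect(c("z", "n_apertures", "beam_on_time"), names(results))
  if (length(metrics) == 0) abort("no metric columns found")
  bac_sets <- tapply(results$bac, results$algorithm,
                     function(b) paste(sort(unique(b)), collapse = ","))
  if (length(unique(bac_sets)) > 1) {
    abort("all algorithms must be evaluated on the same BAC set")
  }
  means <- results |>
    dplyr::group_by(.data$algorithm) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(metrics),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
  algos <- means$algorithm
  pairs <- expand.grid(reference = algos, algorithm = algos,
                       stringsAsFactors = FALSE) |>
    dplyr::filter(.data$reference != .data$algorithm)
  pairwise <- purrr::pmap(pairs, function(reference, algorithm) {
    ref_row <- means[means$algorithm == reference, ]
    new_row <- means[means$algorithm == algorithm, ]
    tibble::tibble(
      reference = reference, algorithm = algorithm, metric = metrics,
      reference_mean = as.numeric(ref_row[1, metrics]),
      new_mean = as.numeric(new_row[1, metrics]),
      reduction_pct = purrr::map2_dbl(
        as.numeric(ref_row[1, metrics]), as.numeric(new_row[1, metrics]),
        function(a, b) if (is.na(a) || a == 0 || is.na(b)) NA_real_
                       else percent_reduction(a, b, digits = NULL))
    )
  }) |> dplyr::bind_rows()
  structure(list(means = means, pairwise = pairwise),
            class = "dao_comparison")
}

#' @export
print.dao_comparison <- function(x, ...) {
  cat("<dao_comparison>\nper-algorithm means:\n")
  print(x$means)
  if (nrow(x$pairwise) > 0) {
    cat("pairwise reductions (%):\n")
    shown <- dplyr::mutate(x$pairwise,
                           reduction_pct = round_half_up(.data$reduction_pct, 2))
    print(shown)
  }
  invisible(x)
}

#' Published benchmark averages for the CERR prostate case
#'
#' Summary rows (mean objective, aperture count and beam-on time over the 14
#' equidistant five-beam configurations) reported in the literature for this
#' benchmark: the two VND variants, rVNS, a hybrid local search (LS), and the
#' sequential baseline at its optimum and at roundings to multiples 1, 2
#' and 4. Useful for reproducing the standard comparison arithmetic without
#' access to the clinical case.
#'
#' @return A tibble with columns `algorithm`, `z`, `n_apertures`,
#'   `beam_on_time`.
#' @export
cerr_benchmark <- function() {
  path <- system.file("extdata", "cerr_benchmark_averages.csv",
                      package = "daovns", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path))
}
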