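#' Cumulative dose-volume histogram
#'
#' For each threshold `t`, the fraction of the region's voxels receiving at
#' least `t` Gy — a right-continuous, non-increasing step function.
#'
#' @param dose Non-negative dose vector of one region.
#' @param thresholds Evaluation thresholds; defaults to 200 points spanning
#'   `[0, max(dose)]`.
#' @return A tibble (`threshold`, `fraction`) of class `dao_dvh`.
#' @export
dvh <- function(dose, thresholds = NULL) {
  if (length(dose) == 0) abort("empty region: cannot compute a DVH")
  stopifnot(all(dose >= 0))
  if (is.null(thresholds)) {
    thresholds <- seq(0, max(dose, 1e-12), length.out = 200)
  }
  frac <- vapply(thresholds, function(t) mean(dose >= t), numeric(1))
  structure(tibble::tibble(threshold = thresholds, fraction = frac),
            class = c("dao_dvh", "tbl_df", "tbl", "data.frame"))
}

#' Dose percentile D_x
#'
#' The minimum dose received by the hottest `x`% of the region: the largest
#' dose `d` such that at least `x`% of voxels receive `>= d`, read off the
#' empirical (non-interpolated) dose distribution.
#'
#' @param dose Dose vector.
#' @param x Percentage in `(0, 100]`.
#' @export
dose_percentile <- function(dose, x) {
  stopifnot(length(dose) > 0, x > 0, x <= 100)
  sorted <- sort(dose, decreasing = TRUE)
  sorted[ceiling(x / 100 * length(dose))]
}

#' Fractional volume V_t receiving at least `t` Gy
#'
#' @param dose Dose vector.
#' @param t Threshold in Gy (>= 0).
#' @export
volume_at_least <- function(dose, t) {
  stopifnot(length(dose) > 0, t >= 0)
  mean(dose >= t)
}

#' Homogeneity index
#'
#' `HI = 100 * (D_5 - D_95) / reference`; zero for a perfectly uniform dose.
#'
#' @param dose Dose vector.
#' @param reference Reference (prescribed) dose in Gy.
#' @export
homogeneity_index <- function(dose, reference) {
  stopifnot(reference > 0)
  100 * (dose_percentile(dose, 5) - dose_percentile(dose, 95)) / reference
}

#' Clinical indicator summary for one region
#'
#' Mean, standard deviation, min/max, requested `D_x` percentiles and `V_t`
#' fractional volumes, and the homogeneity index.
#'
#' @param dose Dose vector.
#' @param d_at Percentages for `D_x` columns.
#' @param v_at Gy thresholds for `V_t` columns.
#' @param reference Reference dose for the homogeneity index.
#' @return A one-row tibble.
#' @export
region_indicators <- function(dose, d_at = c(5, 50, 95, 98),
                              v_at = numeric(), reference = 76) {
  out <- tibble::tibble(mean = mean(dose), sd = stats::sd(dose),
                        min = min(dose), max = max(dose))
  for (x in d_at) out[[paste0("D", x)]] <- dose_percentile(dose, x)
  for (t in v_at) out[[paste0("V", t)]] <- volume_at_least(dose, t)
  out$HI <- homogeneity_index(dose, reference)
  out
}

#' Indicator table for a plan
#'
#' Doses the plan on its case and summarises every region.
#' @param plan A `dao_plan`.
#' @param dose A `dao_dose_set`.
#' @inheritParams region_indicators
#' @export
plan_indicators <- function(plan, dose, d_at = c(5, 50, 95, 98),
                            v_at = c(50, 55), reference = 76) {
  doses <- compute_dose(flatten_to_intensity_vector(plan, dose), dose)
  purrr::imap(doses, function(d, nm) {
    dplyr::mutate(region_indicators(d, d_at, v_at, reference),
                  region = nm, .before = 1)
  }) |> dplyr::bind_rows()
}
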