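#' Objective parameters
#'
#' Prescription and penalty table for the mean-squared voxel-dose objective:
#' each region `r` contributes
#' `(1/m_r) * sum_v [ under_r * (Y_r - d_v)_+^2 + over_r * (d_v - Y_r)_+^2 ]`.
#'
#' @param region Region names.
#' @param prescribed Prescribed dose `Y_r` per region (Gy, > 0).
#' @param under,over Non-negative under-dose / over-dose penalty weights.
#' @return A tibble with one row per region.
#' @export
objective_params <- function(region, prescribed, under, over) {
  stopifnot(all(prescribed > 0), all(under >= 0), all(over >= 0))
  tibble::tibble(region = region, prescribed = as.numeric(prescribed),
                 under = as.numeric(under), over = as.numeric(over))
}

#' Standard prostate prescription
#'
#' 76 Gy to the PTV penalised both ways at weight 5; 65 Gy upper target for
#' rectum and bladder penalised only for over-dose at weight 1.
#' @export
objective_params_prostate <- function() {
  objective_params(region = c("PTV", "rectum", "bladder"),
                   prescribed = c(76, 65, 65),
                   under = c(5, 0, 0),
                   over = c(5, 1, 1))
}

#' Intensity bounds
#'
#' Allowed radiation weight range per aperture, `0 <= gamma_min <= gamma_max`.
#' @param gamma_min,gamma_max Bounds in MU.
#' @export
intensity_bounds <- function(gamma_min = 0, gamma_max = 20) {
  stopifnot(gamma_min >= 0, gamma_min <= gamma_max)
  structure(list(gamma_min = gamma_min, gamma_max = gamma_max),
            class = "dao_bounds")
}

#' Treatment plan
#'
#' A solution to the direct aperture optimisation problem: per beam, an
#' ordered list of C1 aperture shapes with matching intensities.
#'
#' @param bac A `dao_bac`.
#' @param beams List (length = number of beams) of records
#'   `list(shapes = <list of dao_aperture>, intensities = <numeric>)`.
#' @return A `dao_plan`.
#' @export
dao_plan <- function(bac, beams) {
  stopifnot(inherits(bac, "dao_bac"), length(beams) == bac$n_beams)
  for (c_idx in seq_along(beams)) {
    b <- beams[[c_idx]]
    stopifnot(length(b$shapes) == length(b$intensities),
              all(b$intensities >= 0))
    for (s in b$shapes) {
      if (!validate_c1(s)) abort("plan contains a non-C1 aperture")
      if (!same_mask(s, b$shapes[[1]])) {
        abort("apertures within a beam must share their validity mask")
      }
    }
  }
  structure(list(bac = bac, beams = beams), class = "dao_plan")
}

#' @export
print.dao_plan <- function(x, ...) {
  bt <- beam_on_time(x)
  cat("<dao_plan> ", x$bac$n_beams, " beams, ", bt$n_apertures,
      " apertures (", bt$n_active, " active), BoT = ",
      format(bt$beam_on_time, digits = 5), " MU\n", sep = "")
  invisible(x)
}

# enumeration of (beam, aperture) pairs in solver order (beam-major)
plan_aperture_index <- function(plan) {
  purrr::imap(plan$beams, function(b, c_idx) {
    if (length(b$shapes) == 0) return(NULL)
    tibble::tibble(beam = c_idx, aperture = seq_along(b$shapes))
  }) |> dplyr::bind_rows()
}

plan_intensities <- function(plan) {
  unlist(lapply(plan$beams, function(b) b$intensities), use.names = FALSE)
}

set_plan_intensities <- function(plan, intensities) {
  k <- 0L
  for (c_idx in seq_along(plan$beams)) {
    nk <- length(plan$beams[[c_idx]]$intensities)
    plan$beams[[c_idx]]$intensities <- intensities[k + seq_len(nk)]
    k <- k + nk
  }
  plan
}

#' Flatten a plan to the global beamlet intensity vector
#'
#' Aggregates each beam's apertures and maps every valid fluence cell to its
#' fixed global beamlet position (row-major within the beam, beams in BAC
#' order); invalid cells map to nothing.
#'
#' @param plan A `dao_plan`.
#' @param dose A `dao_dose_set` providing the cell-to-beamlet index maps.
#' @return Numeric vector of length `dose$n`.
#' @export
flatten_to_intensity_vector <- function(plan, dose) {
  stopifnot(inherits(plan, "dao_plan"), inherits(dose, "dao_dose_set"))
  if (length(plan$beams) != length(dose$beams)) {
    abort("plan and dose set disagree on the number of beams")
  }
  x <- numeric(dose$n)
  for (c_idx in seq_along(plan$beams)) {
    beam <- dose$beams[[c_idx]]
    ref <- plan$beams[[c_idx]]$shapes[[1]]
    if (ref$n_row != beam$n_row || ref$n_col != beam$n_col ||
        !all(ref$span_lo == beam$span_lo) || !all(ref$span_hi == beam$span_hi)) {
      abort("plan aperture mask does not match the dose set beam layout")
    }
    A <- aggregate_fluence(plan$beams[[c_idx]])
    valid <- !is.na(beam$index)
    x[beam$index[valid]] <- A[valid]
  }
  x
}

#' Dose delivered by an intensity vector
#'
#' `d_v^r = sum_b D_vb^r x_b` for every region and voxel.
#'
#' @param x Length-`n` non-negative beamlet intensity vector.
#' @param dose A `dao_dose_set`.
#' @return Named list of per-region dose vectors (Gy).
#' @export
compute_dose <- function(x, dose) {
  stopifnot(inherits(dose, "dao_dose_set"))
  if (length(x) != dose$n) abort("intensity vector length must equal n")
  lapply(dose$D, function(M) as.numeric(M %*% x))
}

#' Evaluate the penalty objective
#'
#' One-sided quadratic voxel penalties, averaged within each region and summed
#' over regions; always non-negative and convex in the dose (hence in the
#' intensities).
#'
#' @param doses Named list of per-region dose vectors.
#' @param params Objective parameter table from [objective_params()].
#' @return The scalar objective value `z >= 0`.
#' @export
evaluate_objective <- function(doses, params) {
  z <- 0
  for (i in seq_len(nrow(params))) {
    nm <- params$region[i]
    d <- doses[[nm]]
    if (is.null(d)) abort(paste0("no dose vector for region ", nm))
    under <- pmax(params$prescribed[i] - d, 0)
    over <- pmax(d - params$prescribed[i], 0)
    z <- z + (params$under[i] * sum(under^2) +
              params$over[i] * sum(over^2)) / length(d)
  }
  z
}

#' Objective value of a plan
#'
#' Flatten, compute dose, evaluate. Also available via the dose-vector route
#' for consistency checks.
#' @inheritParams flatten_to_intensity_vector
#' @param params Objective parameter table.
#' @export
plan_objective <- function(plan, dose, params) {
  evaluate_objective(compute_dose(flatten_to_intensity_vector(plan, dose), dose),
                     params)
}

#' Beam-on time and aperture counts of a plan
#'
#' Beam-on time is the sum of all aperture intensities (MU); `n_apertures`
#' counts every stored shape, `n_active` only shapes that actually deliver
#' radiation (positive intensity and at least one open cell) — the count
#' clinically reported as "#ap".
#'
#' @param plan A `dao_plan`.
#' @return A one-row tibble with `beam_on_time`, `n_apertures`, `n_active`.
#' @export
beam_on_time <- function(plan) {
  stopifnot(inherits(plan, "dao_plan"))
  ints <- plan_intensities(plan)
  act <- unlist(lapply(plan$beams, function(b) {
    vapply(seq_along(b$shapes), function(k) {
      b$intensities[k] > 1e-9 && open_width(b$shapes[[k]]) > 0L
    }, logical(1))
  }), use.names = FALSE)
  tibble::tibble(beam_on_time = sum(ints),
                 n_apertures = length(ints),
                 n_active = sum(act))
}

#' Write / read a treatment plan as JSON
#'
#' Human-diffable serialisation: gantry angles and, per beam, the row spans,
#' leaf positions and intensities.
#' @param plan A `dao_plan`.
#' @param path File path.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "dao_plan"))
  obj <- list(
    angles = plan$bac$angles,
    beams = lapply(plan$beams, function(b) list(
      n_row = b$shapes[[1]]$n_row,
      n_col = b$shapes[[1]]$n_col,
      span_lo = b$shapes[[1]]$span_lo,
      span_hi = b$shapes[[1]]$span_hi,
      intensities = b$intensities,
      apertures = lapply(b$shapes, function(s)
        list(open_lo = s$open_lo, open_hi = s$open_hi))
    ))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  beams <- lapply(obj$beams, function(b) {
    shapes <- lapply(b$apertures, function(a) {
      aperture_shape(b$span_lo, b$span_hi, a$open_lo, a$open_hi,
                     n_col = b$n_col)
    })
    list(shapes = shapes, intensities = as.numeric(b$intensities))
  })
  dao_plan(bac_spec(obj$angles), beams)
}

#' Export a beam's fluence matrix as CSV
#' @param plan A `dao_plan`.
#' @param beam Beam index.
#' @param path File path.
#' @export
write_fluence_csv <- function(plan, beam, path) {
  A <- aggregate_fluence(plan$beams[[beam]])
  utils::write.table(A, path, sep = ",", row.names = FALSE, col.names = FALSE,
                     na = "")
  invisible(path)
}
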