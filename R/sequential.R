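#' Fluence map optimisation (FMO)
#'
#' Box-constrained minimisation of the penalty objective over beamlet
#' intensities `x` in `[0, x_max]^n`, ignoring deliverability. With
#' `x_max = gamma_max * max_apertures` this is a true relaxation of the
#' aperture-limited plan space, so its optimum lower-bounds every deliverable
#' plan's objective.
#'
#' @param dose A `dao_dose_set`.
#' @param params Objective parameter table.
#' @param x_max Per-beamlet upper bound (MU).
#' @param tol Stationarity target (projected-gradient residual).
#' @param max_iter Iteration cap.
#' @return List with `x`, `objective`, `status`, `kkt_residual`.
#' @export
solve_fmo <- function(dose, params, x_max = 100, tol = 1e-6, max_iter = 2000) {
  stopifnot(inherits(dose, "dao_dose_set"), x_max > 0)
  pr <- params[match(names(dose$D), params$region), ]
  n <- dose$n
  f <- function(x) {
    z <- 0
    for (i in seq_along(dose$D)) {
      d <- as.numeric(dose$D[[i]] %*% x)
      z <- z + (pr$under[i] * sum(pmax(pr$prescribed[i] - d, 0)^2) +
                pr$over[i] * sum(pmax(d - pr$prescribed[i], 0)^2)) /
        nrow(dose$D[[i]])
    }
    z
  }
  g <- function(x) {
    grad <- numeric(n)
    for (i in seq_along(dose$D)) {
      d <- as.numeric(dose$D[[i]] %*% x)
      w <- 2 * (pr$over[i] * pmax(d - pr$prescribed[i], 0) -
                pr$under[i] * pmax(pr$prescribed[i] - d, 0)) / nrow(dose$D[[i]])
      grad <- grad + as.numeric(Matrix::crossprod(dose$D[[i]], w))
    }
    grad
  }
  # a beamlet that doses no penalised voxel is objective-irrelevant: pin to 0
  pen <- which(pr$under > 0 | pr$over > 0)
  touched <- Reduce(`+`, lapply(pen, function(i) Matrix::colSums(dose$D[[i]]^2)))
  if (is.null(touched)) touched <- numeric(n)
  flat <- touched == 0

  x <- numeric(n)
  opt <- stats::optim(x, f, g, method = "L-BFGS-B", lower = 0, upper = x_max,
                      control = list(maxit = max_iter, factr = 1e4,
                                     pgtol = tol / 10))
  x <- opt$par
  x[flat] <- 0
  gv <- g(x); gv[flat] <- 0
  res <- max(abs(x - pmin(pmax(x - gv, 0), x_max)))
  status <- if (res <= tol) "converged" else "iteration-limited"
  list(x = x, objective = f(x), status = status, kkt_residual = res)
}

#' Round a fluence vector to a multiple
#'
#' Each entry becomes `multiple * round(entry / multiple)` with half-way
#' cases rounded up (so 3 rounds to 4 at multiple 2). The rounding error is
#' bounded by `multiple / 2` per entry.
#'
#' @param x Non-negative intensity vector.
#' @param multiple Positive rounding unit.
#' @export
round_fluence <- function(x, multiple) {
  stopifnot(multiple > 0)
  multiple * floor(x / multiple + 0.5 + 1e-12)
}

#' Unidirectional sweep sequencing of an integer fluence matrix
#'
#' Decomposes a per-beam fluence matrix (entries non-negative integer
#' multiples of `unit`; `NA` cells treated as closed) into C1 segments with
#' positive integer-multiple intensities whose weighted sum reconstructs the
#' input exactly. Leaves sweep left to right: the t-th intensity layer of a
#' row opens where the cumulative positive increments reach `t` and closes
#' where the cumulative decrements do, so the beam-on time equals the maximum
#' over rows of the summed positive increments (the classical sweep bound).
#'
#' @param fluence Numeric matrix, one row per MLC row.
#' @param unit Positive intensity quantum.
#' @return A `dao_segments` record: `segments` (list of
#'   `list(shape, intensity)`), `n_segments`, `beam_on_time`,
#'   `source_fluence`.
#' @export
sequence_sweep <- function(fluence, unit = 1) {
  stopifnot(is.matrix(fluence), unit > 0)
  F0 <- fluence
  F0[is.na(F0)] <- 0
  if (any(F0 < 0)) abort("fluence must be non-negative")
  Fu <- F0 / unit
  if (max(abs(Fu - round(Fu))) > 1e-6) {
    abort("fluence entries must be integer multiples of `unit`")
  }
  Fu <- round(Fu)
  nr <- nrow(Fu); nc <- ncol(Fu)

  inc <- cbind(Fu, 0) - cbind(0, Fu)          # nr x (nc + 1) first differences
  pos <- pmax(inc, 0); neg <- pmax(-inc, 0)
  t_row <- rowSums(pos)
  T_total <- max(t_row, 0)
  if (T_total == 0) {
    return(structure(list(segments = list(), n_segments = 0L,
                          beam_on_time = 0, source_fluence = fluence),
                     class = "dao_segments"))
  }
  A <- t(apply(pos, 1, cumsum))               # opening thresholds per column
  B <- t(apply(neg, 1, cumsum))
  if (nr == 1) { A <- matrix(A, 1); B <- matrix(B, 1) }

  L <- matrix(1L, nr, T_total); R <- matrix(1L, nr, T_total)
  for (i in seq_len(nr)) {
    if (t_row[i] == 0) next
    for (t in seq_len(t_row[i])) {
      L[i, t] <- which(A[i, ] >= t)[1]        # layer opens at this column
      R[i, t] <- which(B[i, ] >= t)[1]        # and is closed from this column on
    }
    if (t_row[i] < T_total) {
      L[i, (t_row[i] + 1L):T_total] <- 1L
      R[i, (t_row[i] + 1L):T_total] <- 1L
    }
  }

  # group identical consecutive layers into segments
  keys <- vapply(seq_len(T_total), function(t)
    paste(c(L[, t], R[, t]), collapse = ","), character(1))
  runs <- rle(keys)
  starts <- cumsum(c(1L, head(runs$lengths, -1L)))
  segments <- lapply(seq_along(runs$lengths), function(s) {
    t <- starts[s]
    shape <- aperture_shape(rep(1L, nr), rep(nc + 1L, nr),
                            open_lo = L[, t], open_hi = R[, t], n_col = nc)
    list(shape = shape, intensity = runs$lengths[s] * unit)
  })
  # drop all-closed layers (rows where l == r carry no fluence)
  open_any <- vapply(segments, function(s) open_width(s$shape) > 0L, logical(1))
  segments <- segments[open_any]

  structure(list(segments = segments, n_segments = length(segments),
                 beam_on_time = T_total * unit, source_fluence = fluence),
            class = "dao_segments")
}

#' @export
print.dao_segments <- function(x, ...) {
  cat("<dao_segments> ", x$n_segments, " segments, BoT = ", x$beam_on_time,
      "\n", sep = "")
  invisible(x)
}

#' Reconstruct the fluence of a segment decomposition
#'
#' @param decomp A `dao_segments`.
#' @return The cellwise sum `sum_k S_k * i_k` (`NA` cells of the source kept
#'   at 0).
#' @export
reconstruct_segments <- function(decomp) {
  src <- decomp$source_fluence
  out <- matrix(0, nrow(src), ncol(src))
  for (s in decomp$segments) {
    M <- as.matrix(s$shape)
    out <- out + (M == 1) * s$intensity
  }
  out
}

# reshape a beamlet vector into the per-beam fluence matrices
beam_fluence_matrices <- function(x, dose) {
  lapply(dose$beams, function(beam) {
    F_ <- matrix(NA_real_, beam$n_row, beam$n_col)
    valid <- !is.na(beam$index)
    F_[valid] <- x[beam$index[valid]]
    F_
  })
}

#' Sequential planning baseline: FMO, rounding, sweep sequencing
#'
#' Computes the fluence-map optimum, rounds it to each requested multiple,
#' re-evaluates the objective of the rounded map, and sequences each beam's
#' rounded fluence into C1 segments; aperture counts and beam-on times are
#' summed over beams.
#'
#' @inheritParams solve_fmo
#' @param multiples Rounding units to report (the classical 1, 2, 4).
#' @return A tibble with one row per multiple (`multiple`, `z`,
#'   `n_apertures`, `beam_on_time`) carrying the unrounded optimum as
#'   attributes `z_fmo` and `x_fmo`.
#' @export
sequential_pipeline <- function(dose, params, x_max = 100,
                                multiples = c(1, 2, 4)) {
  fmo <- solve_fmo(dose, params, x_max = x_max)
  rows <- purrr::map(multiples, function(m) {
    xr <- round_fluence(fmo$x, m)
    z <- evaluate_objective(compute_dose(xr, dose), params)
    decomps <- purrr::map(beam_fluence_matrices(xr, dose), sequence_sweep,
                          unit = m)
    tibble::tibble(multiple = m, z = z,
                   n_apertures = sum(purrr::map_int(decomps, "n_segments")),
                   beam_on_time = sum(purrr::map_dbl(decomps, "beam_on_time")))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "z_fmo") <- fmo$objective
  attr(out, "x_fmo") <- fmo$x
  class(out) <- c("dao_sequential", class(out))
  out
}
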