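#' @title Aperture weight optimisation (AWO)
#' @description With the aperture shapes held fixed, the objective is a smooth
#'   convex piecewise-quadratic function of the intensities (the one-sided
#'   squared penalties are continuously differentiable), minimised over the
#'   box `[gamma_min, gamma_max]^K`. The solver is L-BFGS-B followed by a
#'   projected-gradient polish; directions with no dose effect on any
#'   penalised region are resolved to `gamma_min`, which keeps beam-on time
#'   minimal at no objective cost.
#' @name awo
NULL

# per-region m x K matrices of dose per unit intensity of each aperture
aperture_dose_columns <- function(plan, dose) {
  idx <- plan_aperture_index(plan)
  K <- nrow(idx)
  trip_i <- integer(); trip_j <- integer()
  for (k in seq_len(K)) {
    c_idx <- idx$beam[k]
    s <- plan$beams[[c_idx]]$shapes[[idx$aperture[k]]]
    beam <- dose$beams[[c_idx]]
    cols <- integer()
    for (i in seq_len(s$n_row)) {
      if (s$open_hi[i] > s$open_lo[i]) {
        cols <- c(cols, beam$index[i, s$open_lo[i]:(s$open_hi[i] - 1L)])
      }
    }
    cols <- cols[!is.na(cols)]
    trip_i <- c(trip_i, cols)
    trip_j <- c(trip_j, rep(k, length(cols)))
  }
  Uind <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = 1,
                               dims = c(dose$n, K))
  lapply(dose$D, function(M) as.matrix(M %*% Uind))
}

awo_objective_fns <- function(Phi, params) {
  pr <- params[match(names(Phi), params$region), ]
  f <- function(I) {
    z <- 0
    for (i in seq_along(Phi)) {
      d <- as.numeric(Phi[[i]] %*% I)
      z <- z + (pr$under[i] * sum(pmax(pr$prescribed[i] - d, 0)^2) +
                pr$over[i] * sum(pmax(d - pr$prescribed[i], 0)^2)) / nrow(Phi[[i]])
    }
    z
  }
  g <- function(I) {
    grad <- numeric(length(I))
    for (i in seq_along(Phi)) {
      d <- as.numeric(Phi[[i]] %*% I)
      w <- 2 * (pr$over[i] * pmax(d - pr$prescribed[i], 0) -
                pr$under[i] * pmax(pr$prescribed[i] - d, 0)) / nrow(Phi[[i]])
      grad <- grad + as.numeric(crossprod(Phi[[i]], w))
    }
    grad
  }
  list(f = f, g = g, pr = pr)
}

project_box <- function(I, bounds) pmin(pmax(I, bounds$gamma_min), bounds$gamma_max)

kkt_residual_box <- function(I, g, bounds) {
  max(abs(I - project_box(I - g, bounds)))
}

#' Optimise aperture intensities for fixed shapes
#'
#' @param plan A `dao_plan` (all shapes fixed; intensities are the start
#'   point).
#' @param dose A `dao_dose_set`.
#' @param params Objective parameter table, see [objective_params()].
#' @param bounds An [intensity_bounds()] box.
#' @param tol Target on the projected-gradient stationarity residual.
#' @param max_iter Iteration cap for the polish phase.
#' @return A `dao_awo` result: `intensities`, `objective`, `status`
#'   (`"converged"` or `"iteration-limited"`), `kkt_residual`. The returned
#'   objective is never worse than the incoming one.
#' @export
optimise_weights <- function(plan, dose, params, bounds = intensity_bounds(),
                             tol = 1e-6, max_iter = 500) {
  Phi <- aperture_dose_columns(plan, dose)
  fns <- awo_objective_fns(Phi, params)
  I0 <- project_box(plan_intensities(plan), bounds)
  K <- length(I0)

  penalised <- fns$pr$under > 0 | fns$pr$over > 0
  colnorm <- Reduce(`+`, lapply(which(penalised),
                                function(i) colSums(Phi[[i]]^2)),
                    accumulate = FALSE)
  if (is.null(colnorm)) colnorm <- numeric(K)
  flat <- colnorm == 0
  z0 <- fns$f(I0)
  if (!is.finite(z0)) abort("non-finite objective: corrupt dose-deposition data")

  I <- I0
  status <- "converged"
  if (any(!flat)) {
    free <- which(!flat)
    f_free <- function(v) { I[free] <- v; fns$f(I) }
    g_free <- function(v) { I[free] <- v; fns$g(I)[free] }
    opt <- stats::optim(I[free], f_free, g_free, method = "L-BFGS-B",
                        lower = bounds$gamma_min, upper = bounds$gamma_max,
                        control = list(maxit = max_iter, factr = 1e4,
                                       pgtol = tol / 10))
    I[free] <- opt$par
    # projected-gradient polish; Lipschitz bound from the quadratic majoriser
    L <- 0
    for (i in seq_along(Phi)) {
      L <- L + 2 * max(fns$pr$under[i], fns$pr$over[i]) *
        sum(Phi[[i]]^2) / nrow(Phi[[i]])
    }
    if (L > 0) {
      it <- 0
      repeat {
        gv <- fns$g(I); gv[flat] <- 0
        if (kkt_residual_box(I, gv, bounds) <= tol || it >= max_iter) break
        I_new <- project_box(I - gv / L, bounds)
        I_new[flat] <- I[flat]
        if (fns$f(I_new) > fns$f(I) + 1e-15) break
        I <- I_new
        it <- it + 1
      }
      if (it >= max_iter) status <- "iteration-limited"
    }
  }
  I[flat] <- bounds$gamma_min

  z <- fns$f(I)
  if (z > z0) {        # monotone-improvement guarantee
    I <- I0
    I[flat] <- bounds$gamma_min
    z <- min(z0, fns$f(I))
    if (fns$f(I) > z0) I <- I0
  }
  gv <- fns$g(I); gv[flat] <- 0
  res <- kkt_residual_box(I, gv, bounds)
  if (res > tol && status == "converged") status <- "iteration-limited"
  structure(list(intensities = I, objective = fns$f(I), status = status,
                 kkt_residual = res), class = "dao_awo")
}

#' @export
print.dao_awo <- function(x, ...) {
  cat("<dao_awo> z = ", format(x$objective, digits = 8), " (", x$status,
      ", kkt ", format(x$kkt_residual, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Re-optimise a plan's intensities in place
#'
#' Convenience wrapper around [optimise_weights()] returning the plan with
#' updated intensities.
#' @inheritParams optimise_weights
#' @export
reweight_plan <- function(plan, dose, params, bounds = intensity_bounds(),
                          tol = 1e-6, max_iter = 500) {
  res <- optimise_weights(plan, dose, params, bounds, tol, max_iter)
  set_plan_intensities(plan, res$intensities)
}

#' Exhaustive grid-search oracle for aperture weights
#'
#' Enumerates the full Cartesian intensity grid at resolution `grid_step` and
#' returns the best grid point. Intended as an independent correctness oracle
#' on tiny instances; refuses more than four apertures or grids beyond 2e7
#' points because the grid is exponential in the aperture count.
#'
#' @inheritParams optimise_weights
#' @param grid_step Grid resolution (MU).
#' @return A `dao_awo` with `status = "oracle"`.
#' @export
brute_force_weights <- function(plan, dose, params, bounds = intensity_bounds(),
                                grid_step = 0.01) {
  idx <- plan_aperture_index(plan)
  K <- nrow(idx)
  if (K > 4) abort("brute_force_weights refuses more than 4 apertures")
  grid <- seq(bounds$gamma_min, bounds$gamma_max, by = grid_step)
  n_combo <- length(grid)^K
  if (n_combo > 2e7) abort("grid too large; shrink the bounds or the step")

  # unit-intensity dose vectors through the public flatten/dose pipeline,
  # independent of the solver path
  unit_dose <- vector("list", K)
  for (k in seq_len(K)) {
    e <- numeric(K); e[k] <- 1
    pk <- set_plan_intensities(plan, e)
    unit_dose[[k]] <- compute_dose(flatten_to_intensity_vector(pk, dose), dose)
  }
  Phi <- lapply(names(dose$D), function(nm) {
    do.call(cbind, lapply(unit_dose, function(u) u[[nm]]))
  })
  names(Phi) <- names(dose$D)
  pr <- params[match(names(Phi), params$region), ]

  G <- as.matrix(expand.grid(rep(list(grid), K)))
  best_z <- Inf; best_I <- NULL
  chunk <- 20000L
  for (s in seq(1L, nrow(G), by = chunk)) {
    rows <- s:min(s + chunk - 1L, nrow(G))
    Gc <- G[rows, , drop = FALSE]
    z <- numeric(length(rows))
    for (i in seq_along(Phi)) {
      Dm <- Phi[[i]] %*% t(Gc)
      z <- z + (pr$under[i] * colSums(pmax(pr$prescribed[i] - Dm, 0)^2) +
                pr$over[i] * colSums(pmax(Dm - pr$prescribed[i], 0)^2)) /
        nrow(Phi[[i]])
    }
    j <- which.min(z)
    if (z[j] < best_z) { best_z <- z[j]; best_I <- Gc[j, ] }
  }
  structure(list(intensities = as.numeric(best_I), objective = best_z,
                 status = "oracle", kkt_residual = NA_real_),
            class = "dao_awo")
}
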