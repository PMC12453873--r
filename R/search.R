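#' Search configuration
#'
#' @param variant `"rvns"`, `"vnd12"` (N1 then N2) or `"vnd21"` (N2 then N1).
#' @param epsilon Strict-improvement tolerance: a candidate is accepted only
#'   when its objective is below the incumbent's by more than `epsilon`
#'   (a literal "less or equal" acceptance can loop on ties).
#' @param seed Seed for the neighbourhood draws (`NULL` = ambient stream).
#' @param max_iterations Safety cap; the algorithms normally terminate when
#'   jointly locally optimal.
#' @param max_apertures_per_beam Structural cap on apertures per beam.
#' @export
search_config <- function(variant = c("rvns", "vnd12", "vnd21"),
                          epsilon = 1e-9, seed = NULL,
                          max_iterations = 10000,
                          max_apertures_per_beam = 5) {
  variant <- match.arg(variant)
  stopifnot(epsilon > 0, max_iterations >= 1, max_apertures_per_beam >= 1)
  structure(list(variant = variant, k_max = 2L, epsilon = epsilon, seed = seed,
                 max_iterations = max_iterations,
                 max_apertures_per_beam = max_apertures_per_beam),
            class = "dao_search_config")
}

#' Best neighbour of a candidate set
#'
#' Minimum objective; ties broken by earliest generation order.
#' @param N Non-empty list of neighbour records.
#' @export
best_neighbour <- function(N) {
  if (length(N) == 0) abort("empty neighbourhood: no feasible moves")
  N[[which.min(vapply(N, `[[`, numeric(1), "objective"))]]
}

check_plan_caps <- function(plan, cfg) {
  n_per_beam <- vapply(plan$beams, function(b) length(b$shapes), integer(1))
  if (any(n_per_beam > cfg$max_apertures_per_beam)) {
    abort("plan exceeds the per-beam aperture cap")
  }
}

new_trace_row <- function(iteration, k, kind, z_current, z_candidate,
                          accepted, awo_called, z_after) {
  tibble::tibble(iteration = iteration, k = k, move = kind,
                 z_current = z_current, z_candidate = z_candidate,
                 accepted = accepted, awo_called = awo_called,
                 z_after = z_after)
}

finish_search <- function(plan, z, rows, reason, variant) {
  trace <- dplyr::bind_rows(rows)
  structure(list(plan = plan, z = z, trace = trace,
                 termination = reason, variant = variant),
            class = "dao_search")
}

#' @export
print.dao_search <- function(x, ...) {
  cat("<dao_search> ", x$variant, ": z = ", format(x$z, digits = 8), " after ",
      nrow(x$trace), " iterations (", x$termination, ")\n", sep = "")
  invisible(x)
}

#' Variable neighbourhood descent (VND)
#'
#' Deterministic-transition variant: explore neighbourhood `k` (ordering set
#' by the variant), accept the best neighbour when it strictly improves and
#' return to the first neighbourhood; otherwise re-optimise that best
#' neighbour's intensities and accept on improvement; otherwise advance `k`.
#' Terminates when both neighbourhoods fail, so the returned plan admits no
#' improving neighbour in either neighbourhood even after weight
#' re-optimisation of the best candidate.
#'
#' @param initial Feasible starting `dao_plan` (see
#'   [adhoc_initial_solution()]).
#' @param cfg A [search_config()] with variant `"vnd12"` or `"vnd21"`.
#' @param dose A `dao_dose_set`.
#' @param params Objective parameter table.
#' @param bounds An [intensity_bounds()] box.
#' @return A `dao_search` record: final `plan`, final `z`, iteration `trace`
#'   tibble and the `termination` reason.
#' @export
run_vnd <- function(initial, cfg = search_config("vnd12"), dose, params,
                    bounds = intensity_bounds()) {
  stopifnot(cfg$variant %in% c("vnd12", "vnd21"))
  order <- if (cfg$variant == "vnd12") c(1L, 2L) else c(2L, 1L)
  check_plan_caps(initial, cfg)
  run_seeded(cfg$seed, {
    H <- initial
    ctx <- neighbour_context(H, dose, params)
    k <- 0L
    rows <- list()
    iter <- 0L
    reason <- "local_optimum"
    while (TRUE) {
      if (iter >= cfg$max_iterations) { reason <- "iteration_cap"; break }
      iter <- iter + 1L
      kind <- order[k + 1L]
      z_before <- ctx$z
      N <- neighbourhood_movement(H, kind, dose, params, ctx)
      if (length(N) == 0) { k <- k + 1L; if (k >= cfg$k_max) break else next }
      star <- best_neighbour(N)
      accepted <- FALSE; awo <- FALSE
      z_after <- ctx$z
      if (star$objective < ctx$z - cfg$epsilon) {
        H <- star$plan
        ctx <- neighbour_context(H, dose, params)
        k <- 0L; accepted <- TRUE; z_after <- ctx$z
      } else {
        awo <- TRUE
        Hp <- reweight_plan(star$plan, dose, params, bounds)
        ctx_p <- neighbour_context(Hp, dose, params)
        if (ctx_p$z < ctx$z - cfg$epsilon) {
          H <- Hp; ctx <- ctx_p
          accepted <- TRUE; z_after <- ctx$z
        } else {
          k <- k + 1L
        }
      }
      rows[[iter]] <- new_trace_row(iter, k, paste0("n", kind),
                                    z_before, star$objective, accepted, awo,
                                    z_after)
      if (k >= cfg$k_max) break
    }
    out <- finish_search(H, ctx$z, rows, reason, cfg$variant)
    check_plan_caps(out$plan, cfg)
    out
  })
}

#' Reduced variable neighbourhood search (rVNS)
#'
#' No transition rule: every iteration pools the candidates of both
#' neighbourhood movements, takes the best, accepts on strict improvement,
#' otherwise re-optimises the best candidate's intensities and accepts on
#' improvement, otherwise stops.
#'
#' @inheritParams run_vnd
#' @export
run_rvns <- function(initial, cfg = search_config("rvns"), dose, params,
                     bounds = intensity_bounds()) {
  stopifnot(cfg$variant == "rvns")
  check_plan_caps(initial, cfg)
  run_seeded(cfg$seed, {
    H <- initial
    ctx <- neighbour_context(H, dose, params)
    rows <- list()
    iter <- 0L
    reason <- "local_optimum"
    while (TRUE) {
      if (iter >= cfg$max_iterations) { reason <- "iteration_cap"; break }
      iter <- iter + 1L
      z_before <- ctx$z
      N <- c(neighbourhood_movement(H, 1L, dose, params, ctx),
             neighbourhood_movement(H, 2L, dose, params, ctx))
      if (length(N) == 0) break
      star <- best_neighbour(N)
      accepted <- FALSE; awo <- FALSE
      z_after <- ctx$z
      stop_now <- FALSE
      if (star$objective < ctx$z - cfg$epsilon) {
        H <- star$plan
        ctx <- neighbour_context(H, dose, params)
        accepted <- TRUE; z_after <- ctx$z
      } else {
        awo <- TRUE
        Hp <- reweight_plan(star$plan, dose, params, bounds)
        ctx_p <- neighbour_context(Hp, dose, params)
        if (ctx_p$z < ctx$z - cfg$epsilon) {
          H <- Hp; ctx <- ctx_p
          accepted <- TRUE; z_after <- ctx$z
        } else {
          stop_now <- TRUE
        }
      }
      rows[[iter]] <- new_trace_row(iter, NA_integer_, "n1+n2",
                                    z_before, star$objective, accepted, awo,
                                    z_after)
      if (stop_now) break
    }
    out <- finish_search(H, ctx$z, rows, reason, "rvns")
    check_plan_caps(out$plan, cfg)
    out
  })
}

#' One-call direct aperture optimisation
#'
#' Builds the ad-hoc initial solution on a case and runs the requested
#' variant.
#'
#' @param case A `dao_case` from [build_case()], or a `dao_dose_set` (then
#'   `params` must be given).
#' @param variant `"rvns"`, `"vnd12"` or `"vnd21"`.
#' @param seed Seed for the neighbourhood draws.
#' @param bounds An [intensity_bounds()] box.
#' @param params Objective parameters (defaults to the case's).
#' @param ... Further arguments to [search_config()].
#' @export
dao_optimise <- function(case, variant = c("rvns", "vnd12", "vnd21"),
                         seed = NULL, bounds = intensity_bounds(),
                         params = NULL, ...) {
  variant <- match.arg(variant)
  if (inherits(case, "dao_case")) {
    dose <- case$dose
    if (is.null(params)) params <- case$params
  } else {
    dose <- case
    if (is.null(params)) abort("params required when passing a dose set")
  }
  cfg <- search_config(variant, seed = seed, ...)
  initial <- adhoc_initial_solution(dose, params, bounds,
                                    max_apertures = cfg$max_apertures_per_beam)
  if (variant == "rvns") {
    run_rvns(initial, cfg, dose, params, bounds)
  } else {
    run_vnd(initial, cfg, dose, params, bounds)
  }
}
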