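#' @title Neighbourhood movements
#' @description Local-search moves over leaf positions. `N1` draws one
#'   aperture at random and generates, for every MLC row, up to one open-by-one
#'   and one close-by-one move per leaf (at most four neighbours per row; two
#'   for fully closed or fully open rows). `N2` builds the same per-row moves
#'   but draws the aperture holding each row's moves independently, so the
#'   modified leaves belong to different aperture shapes. Improving neighbours
#'   are pushed further in the same direction while the objective keeps
#'   strictly improving (intensification), and all improving moves are
#'   combined into one extra candidate (merge) that competes with the rest.
#'   Neighbour objectives are evaluated at the parent's current intensities.
#' @name neighbourhoods
NULL

# state needed to evaluate neighbours incrementally
neighbour_context <- function(plan, dose, params) {
  x <- flatten_to_intensity_vector(plan, dose)
  doses <- compute_dose(x, dose)
  list(doses = doses, z = evaluate_objective(doses, params))
}

doses_with_delta <- function(doses, dose, cols, deltas) {
  if (length(cols) == 0) return(doses)
  lapply(stats::setNames(names(doses), names(doses)), function(nm) {
    doses[[nm]] + as.numeric(dose$D[[nm]][, cols, drop = FALSE] %*% deltas)
  })
}

# one unit leaf move on one row; returns NULL when infeasible
apply_unit_move <- function(shape, row, side, direction) {
  a <- shape$span_lo[row]; b <- shape$span_hi[row]
  l <- shape$open_lo[row]; r <- shape$open_hi[row]
  if (b <= a) return(NULL)            # row outside the usable field
  if (side == "left") {
    if (direction == "open") {
      if (l - 1L < a) return(NULL)
      shape$open_lo[row] <- l - 1L
      return(list(shape = shape, col = l - 1L, sign = +1))
    }
    if (r <= l) return(NULL)          # closing needs an open row
    shape$open_lo[row] <- l + 1L
    return(list(shape = shape, col = l, sign = -1))
  }
  if (direction == "open") {
    if (r + 1L > b) return(NULL)
    shape$open_hi[row] <- r + 1L
    return(list(shape = shape, col = r, sign = +1))
  }
  if (r <= l) return(NULL)
  shape$open_hi[row] <- r - 1L
  return(list(shape = shape, col = r - 1L, sign = -1))
}

unit_moves <- expand.grid(side = c("left", "right"),
                          direction = c("open", "close"),
                          stringsAsFactors = FALSE)

make_row_neighbours <- function(plan, dose, params, ctx, c_idx, k_idx, row,
                                kind) {
  shape <- plan$beams[[c_idx]]$shapes[[k_idx]]
  inten <- plan$beams[[c_idx]]$intensities[k_idx]
  beam <- dose$beams[[c_idx]]
  out <- list()
  for (mv in seq_len(nrow(unit_moves))) {
    side <- unit_moves$side[mv]; direction <- unit_moves$direction[mv]
    res <- apply_unit_move(shape, row, side, direction)
    if (is.null(res)) next
    col_g <- beam$index[row, res$col]
    delta <- res$sign * inten
    nd <- doses_with_delta(ctx$doses, dose, col_g, delta)
    new_plan <- plan
    new_plan$beams[[c_idx]]$shapes[[k_idx]] <- res$shape
    out[[length(out) + 1L]] <- structure(list(
      move = list(beam = c_idx, aperture = k_idx, row = row, side = side,
                  direction = direction, magnitude = 1L,
                  cols = col_g, deltas = delta),
      plan = new_plan,
      objective = evaluate_objective(nd, params),
      kind = kind
    ), class = "dao_neighbour")
  }
  out
}

#' Generate the single-aperture neighbourhood (N1)
#'
#' Draws one aperture uniformly at random from the whole plan, then emits
#' every feasible unit leaf move for each of its rows, evaluated at the
#' parent's intensities. Draws come from R's ambient RNG stream; seed it (see
#' [search_config()]) for reproducibility.
#'
#' @param plan A `dao_plan`.
#' @param dose A `dao_dose_set`.
#' @param params Objective parameter table.
#' @param ctx Optional cached parent context (internal).
#' @param aperture Optional `(beam, aperture)` override used by tests.
#' @return List of neighbour records (`move`, `plan`, `objective`).
#' @export
generate_n1 <- function(plan, dose, params, ctx = NULL, aperture = NULL) {
  if (is.null(ctx)) ctx <- neighbour_context(plan, dose, params)
  idx <- plan_aperture_index(plan)
  if (is.null(aperture)) {
    pick <- idx[sample.int(nrow(idx), 1L), ]
  } else {
    pick <- tibble::tibble(beam = aperture[1], aperture = aperture[2])
  }
  shape <- plan$beams[[pick$beam]]$shapes[[pick$aperture]]
  unlist(lapply(seq_len(shape$n_row), function(row) {
    make_row_neighbours(plan, dose, params, ctx, pick$beam, pick$aperture,
                        row, "n1")
  }), recursive = FALSE)
}

#' Generate the cross-aperture neighbourhood (N2)
#'
#' Per-row move creation as in [generate_n1()], but the aperture holding each
#' row's moves is drawn independently and uniformly over all apertures of all
#' beams.
#' @inheritParams generate_n1
#' @param apertures Optional integer matrix (`mlc_rows x 2`) of
#'   `(beam, aperture)` picks per row, used by tests.
#' @export
generate_n2 <- function(plan, dose, params, ctx = NULL, apertures = NULL) {
  if (is.null(ctx)) ctx <- neighbour_context(plan, dose, params)
  idx <- plan_aperture_index(plan)
  n_row <- plan$beams[[1]]$shapes[[1]]$n_row
  unlist(lapply(seq_len(n_row), function(row) {
    if (is.null(apertures)) {
      pick <- idx[sample.int(nrow(idx), 1L), ]
    } else {
      pick <- tibble::tibble(beam = apertures[row, 1], aperture = apertures[row, 2])
    }
    make_row_neighbours(plan, dose, params, ctx, pick$beam, pick$aperture,
                        row, "n2")
  }), recursive = FALSE)
}

#' Intensification operator
#'
#' Keeps moving the neighbour's leaf in the same direction, one column per
#' step, while each step strictly improves the objective at fixed
#' intensities; returns the last improving state.
#'
#' @param neighbour An improving neighbour record.
#' @param dose A `dao_dose_set`.
#' @param params Objective parameter table.
#' @param ctx Parent context (doses at the parent plan).
#' @export
intensify <- function(neighbour, dose, params, ctx) {
  mv <- neighbour$move
  plan <- neighbour$plan
  inten <- plan$beams[[mv$beam]]$intensities[mv$aperture]
  d_cur <- doses_with_delta(ctx$doses, dose, mv$cols, mv$deltas)
  z_cur <- neighbour$objective
  beam <- dose$beams[[mv$beam]]
  repeat {
    shape <- plan$beams[[mv$beam]]$shapes[[mv$aperture]]
    res <- apply_unit_move(shape, mv$row, mv$side, mv$direction)
    if (is.null(res)) break
    col_g <- beam$index[mv$row, res$col]
    delta <- res$sign * inten
    nd <- doses_with_delta(d_cur, dose, col_g, delta)
    z_new <- evaluate_objective(nd, params)
    if (!(z_new < z_cur)) break
    plan$beams[[mv$beam]]$shapes[[mv$aperture]] <- res$shape
    d_cur <- nd; z_cur <- z_new
    mv$magnitude <- mv$magnitude + 1L
    mv$cols <- c(mv$cols, col_g)
    mv$deltas <- c(mv$deltas, delta)
  }
  neighbour$move <- mv
  neighbour$plan <- plan
  neighbour$objective <- z_cur
  neighbour
}

#' Merge operator
#'
#' Combines every improving neighbour (post-intensification leaf positions)
#' of one movement application into a single candidate plan. When two
#' neighbours move the same leaf, the better-improving one wins; when the
#' combined leaves of a row would cross, the worse-improving move is dropped
#' until the row is C1-valid again. Returns `NULL` with fewer than two
#' improving neighbours. The merged candidate competes in best-neighbour
#' selection; it is not auto-accepted.
#'
#' @param improving List of improving neighbour records derived from `parent`
#'   within the same movement application.
#' @param parent The parent `dao_plan`.
#' @param dose A `dao_dose_set`.
#' @param params Objective parameter table.
#' @param parent_z Parent objective at its current intensities.
#' @export
merge_neighbours <- function(improving, parent, dose, params, parent_z) {
  if (length(improving) < 2) return(NULL)
  moves <- purrr::map(improving, function(nb) {
    mv <- nb$move
    s <- nb$plan$beams[[mv$beam]]$shapes[[mv$aperture]]
    list(beam = mv$beam, aperture = mv$aperture, row = mv$row, side = mv$side,
         direction = mv$direction, magnitude = mv$magnitude,
         value = if (mv$side == "left") s$open_lo[mv$row] else s$open_hi[mv$row],
         improvement = parent_z - nb$objective)
  })
  # same-leaf conflicts: keep the single best-improving move
  key <- vapply(moves, function(m)
    paste(m$beam, m$aperture, m$row, m$side, sep = "/"), character(1))
  keep <- tapply(seq_along(moves), key, function(ix) {
    ix[which.max(vapply(moves[ix], `[[`, numeric(1), "improvement"))]
  })
  moves <- moves[sort(unlist(keep))]

  # crossing leaves on a row: drop moves in order of worst improvement
  repeat {
    plan <- parent
    for (m in moves) {
      s <- plan$beams[[m$beam]]$shapes[[m$aperture]]
      if (m$side == "left") s$open_lo[m$row] <- m$value else s$open_hi[m$row] <- m$value
      plan$beams[[m$beam]]$shapes[[m$aperture]] <- s
    }
    bad <- NULL
    for (j in seq_along(moves)) {
      m <- moves[[j]]
      s <- plan$beams[[m$beam]]$shapes[[m$aperture]]
      if (s$open_lo[m$row] > s$open_hi[m$row]) bad <- c(bad, j)
    }
    if (is.null(bad)) break
    worst <- bad[which.min(vapply(moves[bad], `[[`, numeric(1), "improvement"))]
    moves <- moves[-worst]
    if (length(moves) == 0) return(NULL)
  }

  z <- plan_objective(plan, dose, params)
  structure(list(move = moves, plan = plan, objective = z, kind = "merge"),
            class = "dao_neighbour")
}

#' One full neighbourhood movement
#'
#' Raw move generation, intensification of the improving neighbours, and the
#' merged candidate, pooled into one candidate set.
#'
#' @param plan Parent plan.
#' @param kind `1` for N1, `2` for N2.
#' @inheritParams generate_n1
#' @export
neighbourhood_movement <- function(plan, kind, dose, params, ctx = NULL) {
  if (is.null(ctx)) ctx <- neighbour_context(plan, dose, params)
  raw <- if (kind == 1) generate_n1(plan, dose, params, ctx)
         else generate_n2(plan, dose, params, ctx)
  if (length(raw) == 0) return(list())
  improving_ix <- which(vapply(raw, `[[`, numeric(1), "objective") < ctx$z)
  candidates <- raw
  if (length(improving_ix) > 0) {
    intensified <- lapply(raw[improving_ix], intensify, dose = dose,
                          params = params, ctx = ctx)
    candidates[improving_ix] <- intensified
    merged <- merge_neighbours(intensified, plan, dose, params, ctx$z)
    if (!is.null(merged)) candidates[[length(candidates) + 1L]] <- merged
  }
  candidates
}

#' Ad-hoc initial solution
#'
#' Five predetermined apertures per beam — half-open bottom, half-open top,
#' half-open right, half-open left, and fully open — with intensities then
#' set by [optimise_weights()].
#'
#' @param dose A `dao_dose_set` (carries the BAC beams and validity spans).
#' @param params Objective parameter table.
#' @param bounds An [intensity_bounds()] box.
#' @param max_apertures Cap on apertures per beam (must be >= 5).
#' @return A `dao_plan` with optimised intensities.
#' @export
adhoc_initial_solution <- function(dose, params, bounds = intensity_bounds(),
                                   max_apertures = 5) {
  stopifnot(inherits(dose, "dao_dose_set"), max_apertures >= 5)
  angles <- vapply(dose$beams, `[[`, numeric(1), "angle")
  beams <- lapply(dose$beams, function(beam) {
    shapes <- unname(adhoc_shapes_for_beam(beam))
    list(shapes = shapes, intensities = rep(bounds$gamma_min, length(shapes)))
  })
  plan <- dao_plan(bac_spec(angles), beams)
  reweight_plan(plan, dose, params, bounds)
}
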