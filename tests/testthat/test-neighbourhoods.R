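test_that("the five ad-hoc apertures have their definitional shapes", {
  case <- small_case(seed = 1)
  init <- adhoc_initial_solution(case$dose, case$params)
  expect_equal(vapply(init$beams, function(b) length(b$shapes), integer(1)),
               rep(5L, 5))
  for (c_idx in seq_along(init$beams)) {
    beam <- case$dose$beams[[c_idx]]
    sh <- init$beams[[c_idx]]$shapes
    nr <- beam$n_row
    # fifth aperture covers every valid cell
    expect_equal(sh[[5]]$open_lo, beam$span_lo)
    expect_equal(sh[[5]]$open_hi, beam$span_hi)
    # half-open bottom opens exactly 0-based rows ceil(R/2)..R-1
    bottom <- which(seq_len(nr) - 1 >= ceiling(nr / 2))
    open_rows <- which(sh[[1]]$open_hi > sh[[1]]$open_lo)
    expect_equal(open_rows, bottom)
    for (i in bottom) {
      expect_equal(sh[[1]]$open_lo[i], beam$span_lo[i])
      expect_equal(sh[[1]]$open_hi[i], beam$span_hi[i])
    }
    # top is the complement
    expect_equal(which(sh[[2]]$open_hi > sh[[2]]$open_lo), setdiff(seq_len(nr), bottom))
    # left/right half-columns stay within the span and touch its edges
    expect_equal(sh[[4]]$open_lo, beam$span_lo)
    expect_equal(sh[[3]]$open_hi, beam$span_hi)
  }
  # intensities were optimised: no worse than any scalar rescaling
  z <- plan_objective(init, case$dose, case$params)
  for (s in c(0.8, 1.2)) {
    scaled <- init
    for (c_idx in seq_along(scaled$beams)) {
      scaled$beams[[c_idx]]$intensities <-
        pmin(scaled$beams[[c_idx]]$intensities * s, 20)
    }
    expect_lte(z, plan_objective(scaled, case$dose, case$params) + 1e-9)
  }
})

test_that("per-row neighbour counts match the brute-force move enumerator", {
  # every leaf state of a width-6 row, including closed rows at any meeting
  # column, on a one-aperture single-row plan
  dose <- cell_dose_set(1, 6, list(PTV = cbind(1, 1:6)))
  params <- objective_params("PTV", 10, 5, 5)
  for (st in all_row_states(1L, 7L)) {
    plan <- leaf_plan(dose, st[1], st[2], intensity = 3)
    nbs <- generate_n1(plan, dose, params, aperture = c(1, 1))
    expected <- brute_force_unit_moves(1L, 7L, st[1], st[2])
    expect_length(nbs, length(expected))
    got <- lapply(nbs, function(nb) {
      s <- nb$plan$beams[[1]]$shapes[[1]]
      c(s$open_lo[1], s$open_hi[1])
    })
    expect_setequal(vapply(got, paste, character(1), collapse = ","),
                    vapply(expected, paste, character(1), collapse = ","))
    # all emitted neighbours are C1-valid
    for (nb in nbs) expect_true(validate_c1(nb$plan$beams[[1]]$shapes[[1]]))
  }
  # headline cases: interior 4, fully closed 2, fully open 2
  counts <- function(l, r) length(generate_n1(leaf_plan(dose, l, r, 1),
                                              dose, params, aperture = c(1, 1)))
  expect_equal(counts(3, 5), 4L)
  expect_equal(counts(4, 4), 2L)
  expect_equal(counts(1, 7), 2L)
  expect_equal(counts(1, 1), 1L)   # closed against the span edge
})

test_that("N2 equals N1 for single-aperture plans and stays feasible", {
  dose <- cell_dose_set(2, 4, list(PTV = rbind(c(1, 2), c(2, 3))))
  params <- objective_params("PTV", 10, 5, 5)
  plan <- open_plan(dose, intensity = 4)
  for (seed in c(1, 99)) {
    set.seed(seed)
    n1 <- generate_n1(plan, dose, params)
    set.seed(seed)
    n2 <- generate_n2(plan, dose, params)
    key <- function(nbs) sort(vapply(nbs, function(nb) {
      paste(nb$move$row, nb$move$side, nb$move$direction, nb$objective)
    }, character(1)))
    expect_equal(key(n2), key(n1))
  }

  case <- small_case(seed = 3)
  plan5 <- adhoc_initial_solution(case$dose, case$params)
  set.seed(5)
  nbs <- generate_n2(plan5, case$dose, case$params)
  for (nb in nbs) {
    s <- nb$plan$beams[[nb$move$beam]]$shapes[[nb$move$aperture]]
    expect_true(validate_c1(s))
  }
})

test_that("neighbour objectives are evaluated at the parent's intensities", {
  dose <- cell_dose_set(1, 3, list(PTV = cbind(1, 1:3)))
  params <- objective_params("PTV", 10, 5, 5)
  plan <- leaf_plan(dose, 1, 4, intensity = 6)
  nbs <- generate_n1(plan, dose, params, aperture = c(1, 1))
  for (nb in nbs) {
    expect_equal(nb$objective, plan_objective(nb$plan, dose, params),
                 tolerance = 1e-10)
  }
})

test_that("intensification closes a purely harmful row completely", {
  # 1 target voxel without dose + an organ dosed by all four cells: closing
  # always helps, so intensify must sweep the leaf to a fully closed row
  D <- list(PTV = Matrix::sparseMatrix(i = integer(), j = integer(),
                                       x = numeric(), dims = c(1, 4)),
            OAR = Matrix::Diagonal(4))
  beam <- list(angle = 0, n_row = 1, n_col = 4, span_lo = 1L, span_hi = 5L,
               index = matrix(1:4, 1))
  dose <- new_dose_set(D, 4, 1L, list(beam),
                       region_m = c(PTV = 1, OAR = 4), target = "PTV")
  params <- objective_params(c("PTV", "OAR"), c(1, 0.5), c(0, 0), c(0, 1))
  plan <- leaf_plan(dose, 1, 5, intensity = 2)
  ctx <- list(doses = compute_dose(flatten_to_intensity_vector(plan, dose), dose))
  ctx$z <- evaluate_objective(ctx$doses, params)
  nbs <- generate_n1(plan, dose, params, ctx = ctx, aperture = c(1, 1))
  closing <- nbs[vapply(nbs, function(nb) nb$move$direction == "close" &&
                          nb$move$side == "left", logical(1))]
  expect_length(closing, 1)
  out <- intensify(closing[[1]], dose, params, ctx)
  s <- out$plan$beams[[1]]$shapes[[1]]
  expect_equal(s$open_hi[1] - s$open_lo[1], 0L)      # fully closed
  expect_equal(out$objective, 0)
  expect_equal(out$move$magnitude, 4L)
  expect_true(validate_c1(s))

  # when no further step improves, the neighbour is returned unchanged
  dose2 <- cell_dose_set(1, 3, list(PTV = cbind(1, 1:3)))
  params2 <- objective_params("PTV", 10, 5, 5)
  plan2 <- leaf_plan(dose2, 1, 4, intensity = 10)
  ctx2 <- list(doses = compute_dose(flatten_to_intensity_vector(plan2, dose2), dose2))
  ctx2$z <- evaluate_objective(ctx2$doses, params2)
  nb2 <- generate_n1(plan2, dose2, params2, ctx = ctx2, aperture = c(1, 1))[[1]]
  out2 <- intensify(nb2, dose2, params2, ctx2)
  expect_equal(out2$objective, nb2$objective)
  expect_equal(out2$move$magnitude, 1L)
})

test_that("merge combines improving moves and resolves crossings", {
  # three rows, each with one harmful leftmost cell: three disjoint improving
  # closures merge into one plan differing from the parent on those rows only
  ptv <- rbind(c(1, 3), c(2, 3), c(3, 3))
  oar <- rbind(c(1, 1), c(2, 1), c(3, 1))
  dose <- cell_dose_set(3, 3, list(PTV = ptv, OAR = oar))
  params <- objective_params(c("PTV", "OAR"), c(5, 1), c(5, 0), c(5, 1))
  plan <- open_plan(dose, intensity = 5)
  ctx <- list(doses = compute_dose(flatten_to_intensity_vector(plan, dose), dose))
  ctx$z <- evaluate_objective(ctx$doses, params)
  nbs <- generate_n1(plan, dose, params, ctx = ctx, aperture = c(1, 1))
  improving <- nbs[vapply(nbs, function(nb) nb$objective < ctx$z, logical(1))]
  expect_gte(length(improving), 3)
  improving <- lapply(improving, intensify, dose = dose, params = params,
                      ctx = ctx)
  merged <- merge_neighbours(improving, plan, dose, params, ctx$z)
  expect_false(is.null(merged))
  s <- merged$plan$beams[[1]]$shapes[[1]]
  expect_true(validate_c1(s))
  # left leaf closed past the harmful cell on every row, right leaf untouched
  expect_true(all(s$open_lo >= 2))
  expect_equal(s$open_hi, plan$beams[[1]]$shapes[[1]]$open_hi)
  expect_lt(merged$objective, ctx$z)

  # fewer than two improving neighbours: no merge
  expect_null(merge_neighbours(improving[1], plan, dose, params, ctx$z))
  expect_null(merge_neighbours(list(), plan, dose, params, ctx$z))

  # crossing construction: both leaves of a width-2 row sweep to fully closed
  dose2 <- cell_dose_set(1, 2, list(PTV = rbind(c(1, 1)), OAR = rbind(c(1, 1), c(1, 2))))
  params2 <- objective_params(c("PTV", "OAR"), c(1, 0.5), c(0, 0), c(0, 1))
  plan2 <- leaf_plan(dose2, 1, 3, intensity = 2)
  ctx2 <- list(doses = compute_dose(flatten_to_intensity_vector(plan2, dose2), dose2))
  ctx2$z <- evaluate_objective(ctx2$doses, params2)
  nbs2 <- generate_n1(plan2, dose2, params2, ctx = ctx2, aperture = c(1, 1))
  improving2 <- nbs2[vapply(nbs2, function(nb) nb$objective < ctx2$z, logical(1))]
  improving2 <- lapply(improving2, intensify, dose = dose2, params = params2,
                       ctx = ctx2)
  merged2 <- merge_neighbours(improving2, plan2, dose2, params2, ctx2$z)
  if (!is.null(merged2)) {
    expect_true(validate_c1(merged2$plan$beams[[1]]$shapes[[1]]))
  }
})

test_that("random movement applications only ever emit C1-valid shapes", {
  set.seed(77)
  case <- small_case(seed = 6)
  plan <- adhoc_initial_solution(case$dose, case$params)
  n_checked <- 0
  for (step in 1:40) {
    kind <- sample_one(1:2)
    N <- neighbourhood_movement(plan, kind, case$dose, case$params)
    for (nb in N) {
      for (b in nb$plan$beams) {
        for (s in b$shapes) {
          expect_true(validate_c1(s))
          n_checked <- n_checked + 1
        }
        expect_true(all(b$intensities >= 0 & b$intensities <= 20))
      }
    }
    if (length(N) > 0) plan <- N[[sample_one(seq_along(N))]]$plan
  }
  expect_gt(n_checked, 1000)
})

test_that("neighbourhood generation is reproducible under a fixed seed", {
  case <- small_case(seed = 2)
  plan <- adhoc_initial_solution(case$dose, case$params)
  key <- function(nbs) vapply(nbs, function(nb)
    paste(nb$move$beam, nb$move$aperture, nb$move$row, nb$move$side,
          nb$move$direction, signif(nb$objective, 12)), character(1))
  set.seed(123); a <- generate_n2(plan, case$dose, case$params)
  set.seed(123); b <- generate_n2(plan, case$dose, case$params)
  expect_identical(key(a), key(b))
})
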