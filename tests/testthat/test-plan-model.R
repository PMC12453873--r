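test_that("consecutive-ones validation agrees with a brute-force tester", {
  # all {-1,0,1} single-row patterns of width 3 against direct contiguity
  patterns <- expand.grid(rep(list(c(-1, 0, 1)), 3))
  brute <- function(row) {
    ones <- which(row == 1)
    valid <- which(row != -1)
    contiguous <- function(ix) length(ix) == 0 || all(diff(ix) == 1)
    contiguous(valid) && contiguous(ones) &&
      (length(ones) == 0 || all(ones %in% valid))
  }
  for (p in seq_len(nrow(patterns))) {
    row <- as.numeric(patterns[p, ])
    expect_identical(validate_c1(matrix(row, 1)), brute(row), label = paste(row, collapse = ","))
  }
  expect_true(validate_c1(matrix(c(1, 1, 0), 1)))
  expect_false(validate_c1(matrix(c(1, 0, 1), 1)))
  # fully closed row is valid
  expect_true(validate_c1(matrix(c(-1, 0, 0, -1), 1)))
})

test_that("interval apertures expand to C1 matrices and reject bad intervals", {
  sh <- aperture_shape(span_lo = c(1, 2), span_hi = c(5, 4),
                       open_lo = c(2, 3), open_hi = c(4, 3), n_col = 4)
  M <- as.matrix(sh)
  expect_identical(M[1, ], c(0, 1, 1, 0))
  expect_identical(M[2, ], c(-1, 0, 0, -1))   # closed row, leaves meet at 3
  expect_true(validate_c1(M))
  expect_error(aperture_shape(1, 5, 3, 2), "invalid aperture")
  expect_error(aperture_shape(2, 4, 1, 4), "invalid aperture")
})

test_that("fluence aggregation is the intensity-weighted sum of shapes", {
  one <- aperture_shape(1, 5, 1, 5)
  expect_equal(aggregate_fluence(list(one), 7), matrix(7, 1, 4))
  expect_equal(aggregate_fluence(list(one, one), c(0, 0)), matrix(0, 1, 4))

  a <- aperture_shape(1, 5, 1, 5)        # open [0,4) at 3 (0-based)
  b <- aperture_shape(1, 5, 2, 4)        # open [1,3) at 2
  expect_equal(aggregate_fluence(list(a, b), c(3, 2)),
               matrix(c(3, 5, 5, 3), 1))

  # invalid cells come back NA
  sp <- aperture_shape(span_lo = 2, span_hi = 4, open_lo = 2, open_hi = 4,
                       n_col = 4)
  A <- aggregate_fluence(list(sp), 1)
  expect_identical(is.na(A[1, ]), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("flattening concatenates beams row-major over valid cells", {
  dose <- cell_dose_set(1, 3, list(PTV = rbind(c(1, 1), c(1, 2), c(1, 3))))
  plan <- leaf_plan(dose, 1, 4, intensity = 2)
  expect_equal(flatten_to_intensity_vector(plan, dose), c(2, 2, 2))

  plan0 <- leaf_plan(dose, 1, 4, intensity = 0)
  expect_equal(flatten_to_intensity_vector(plan0, dose), c(0, 0, 0))

  # two beams: the vector is the concatenation of per-beam flattenings
  n_row <- 2; n_col <- 3; n <- 12
  mk_beam <- function(angle, offset) {
    list(angle = angle, n_row = n_row, n_col = n_col,
         span_lo = rep(1L, n_row), span_hi = rep(n_col + 1L, n_row),
         index = matrix(offset + seq_len(6), n_row, n_col, byrow = TRUE))
  }
  D <- list(PTV = Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(1, n)))
  dose2 <- new_dose_set(D, n, beam_offsets = c(1L, 7L),
                        beams = list(mk_beam(0, 0L), mk_beam(90, 6L)),
                        region_m = c(PTV = 1), target = "PTV")
  plan2 <- open_plan(dose2, intensity = 1)
  plan2$beams[[2]]$intensities <- 3
  x <- flatten_to_intensity_vector(plan2, dose2)
  expect_equal(x, c(rep(1, 6), rep(3, 6)))

  # mask mismatch errors
  bad <- leaf_plan(dose, 1, 4)
  bad$beams[[1]]$shapes[[1]]$span_hi <- 3L
  bad$beams[[1]]$shapes[[1]]$open_hi <- 3L
  expect_error(flatten_to_intensity_vector(bad, dose), "mask")
})

test_that("dose computation is the matrix-vector product per region", {
  D <- list(R = Matrix::Matrix(matrix(c(1, 0, 2, 4), 2, 2), sparse = TRUE))
  beam <- list(angle = 0, n_row = 1, n_col = 2, span_lo = 1L, span_hi = 3L,
               index = matrix(1:2, 1))
  dose <- new_dose_set(D, 2, 1L, list(beam), region_m = c(R = 2), target = "R")
  expect_equal(compute_dose(c(2, 3), dose)$R, c(8, 12))
  expect_equal(compute_dose(c(0, 0), dose)$R, c(0, 0))
  expect_error(compute_dose(c(1, 2, 3), dose), "length")

  ident <- new_dose_set(list(R = Matrix::Diagonal(2)), 2, 1L, list(beam),
                        region_m = c(R = 2), target = "R")
  expect_equal(compute_dose(c(1, 1), ident)$R, c(1, 1))
})

test_that("objective matches hand-evaluated one-sided quadratic penalties", {
  params <- objective_params(c("PTV", "OAR"), c(76, 65), c(5, 0), c(5, 1))
  expect_equal(evaluate_objective(list(PTV = 76, OAR = 60), params), 0)
  expect_equal(evaluate_objective(list(PTV = 70, OAR = 60), params), 5 * 36)
  expect_equal(evaluate_objective(list(PTV = 76, OAR = 70), params), 25)
  # under-dosed OAR voxel contributes nothing
  expect_equal(evaluate_objective(list(PTV = 76, OAR = 0), params), 0)
  # region means: two PTV voxels at 70 average the same as one
  expect_equal(evaluate_objective(list(PTV = c(70, 70), OAR = 60), params),
               180)
})

test_that("objective is convex and consistent across evaluation routes", {
  set.seed(42)
  case <- small_case(seed = 5)
  dose <- case$dose; params <- case$params
  for (rep in 1:20) {
    x1 <- runif(dose$n, 0, 50); x2 <- runif(dose$n, 0, 50)
    z1 <- evaluate_objective(compute_dose(x1, dose), params)
    z2 <- evaluate_objective(compute_dose(x2, dose), params)
    zm <- evaluate_objective(compute_dose((x1 + x2) / 2, dose), params)
    expect_lte(zm, (z1 + z2) / 2 + 1e-9)
  }

  # flatten-of-aggregate equals the sum of per-aperture unit flattenings
  for (rep in 1:5) {
    plan <- random_plan(dose, n_apertures = 3)
    x <- flatten_to_intensity_vector(plan, dose)
    K <- 0
    x2 <- numeric(dose$n)
    for (c_idx in seq_along(plan$beams)) {
      for (k in seq_along(plan$beams[[c_idx]]$shapes)) {
        unit <- plan
        for (cc in seq_along(unit$beams)) {
          unit$beams[[cc]]$intensities <- rep(0, length(unit$beams[[cc]]$intensities))
        }
        unit$beams[[c_idx]]$intensities[k] <- plan$beams[[c_idx]]$intensities[k]
        x2 <- x2 + flatten_to_intensity_vector(unit, dose)
      }
    }
    expect_equal(x, x2, tolerance = 1e-9)
    z_a <- evaluate_objective(compute_dose(x, dose), params)
    z_b <- evaluate_objective(compute_dose(x2, dose), params)
    expect_equal(z_a, z_b, tolerance = 1e-9)
  }
})

test_that("beam-on time sums intensities and counts apertures", {
  dose <- cell_dose_set(1, 3, list(PTV = rbind(c(1, 2))))
  plan <- open_plan(dose, intensity = 0)
  expect_equal(beam_on_time(plan)$beam_on_time, 0)

  case <- small_case(seed = 1)
  init <- adhoc_initial_solution(case$dose, case$params)
  bt <- beam_on_time(init)
  expect_equal(bt$n_apertures, 25L)             # 5 beams x 5 apertures
  expect_equal(bt$beam_on_time, sum(unlist(lapply(init$beams, `[[`, "intensities"))))
  expect_lte(bt$n_active, 25L)
})

test_that("plans round-trip through JSON", {
  case <- small_case(seed = 4)
  plan <- adhoc_initial_solution(case$dose, case$params)
  path <- withr::local_tempfile(fileext = ".json")
  write_plan(plan, path)
  back <- read_plan(path)
  expect_equal(tidy(back), tidy(plan))
  expect_equal(plan_objective(back, case$dose, case$params),
               plan_objective(plan, case$dose, case$params))
})
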