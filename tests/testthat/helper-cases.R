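# Hand-built cases on explicit beamlet grids: voxels correspond one-to-one to
# cells, with unit dose from "their" beamlet, which makes objectives exactly
# computable by hand.

# regions: named list of 2-column matrices (row, col); first entry is the
# target. One beam, all cells valid.
cell_dose_set <- function(n_row, n_col, regions, angle = 0) {
  n <- n_row * n_col
  index <- matrix(seq_len(n), n_row, n_col, byrow = TRUE)
  beam <- list(angle = angle, n_row = n_row, n_col = n_col,
               span_lo = rep(1L, n_row), span_hi = rep(n_col + 1L, n_row),
               index = index)
  D <- lapply(regions, function(cells) {
    cells <- matrix(cells, ncol = 2)
    b <- index[cells]
    Matrix::sparseMatrix(i = seq_len(nrow(cells)), j = b, x = 1,
                         dims = c(nrow(cells), n))
  })
  new_dose_set(D, n, beam_offsets = 1L, beams = list(beam),
               region_m = vapply(D, nrow, integer(1)),
               target = names(regions)[1])
}

# plan with a single fully open aperture per beam
open_plan <- function(dose, intensity = 0) {
  angles <- vapply(dose$beams, `[[`, numeric(1), "angle")
  beams <- lapply(dose$beams, function(b) {
    sh <- aperture_shape(b$span_lo, b$span_hi, n_col = b$n_col)
    list(shapes = list(sh), intensities = intensity)
  })
  dao_plan(bac_spec(angles), beams)
}

# replace the single aperture of a 1-beam plan by explicit leaf positions
leaf_plan <- function(dose, open_lo, open_hi, intensity = 0) {
  b <- dose$beams[[1]]
  sh <- aperture_shape(b$span_lo, b$span_hi, open_lo, open_hi, n_col = b$n_col)
  dao_plan(bac_spec(b$angle),
           list(list(shapes = list(sh), intensities = intensity)))
}

# 2-row width-4 toy whose optimum has a bound-active weight: a strongly
# under-prescribed target in the two middle columns, a weak over-dose-only
# ring at the edges. Enumerable exactly.
toy_bound_case <- function() {
  target <- rbind(c(1, 2), c(1, 3), c(2, 2), c(2, 3))
  ring <- rbind(c(1, 1), c(1, 4), c(2, 1), c(2, 4))
  dose <- cell_dose_set(2, 4, list(PTV = target, ring = ring))
  params <- objective_params(c("PTV", "ring"), prescribed = c(26, 1),
                             under = c(5, 0), over = c(5, 1))
  list(dose = dose, params = params, bounds = intensity_bounds(0, 10))
}

# all leaf states (l, r) of one row with validity span [a, b), half-open,
# closed rows at every meeting point
all_row_states <- function(a, b) {
  states <- list()
  for (l in a:b) for (r in l:b) states[[length(states) + 1L]] <- c(l, r)
  states
}

# independent enumerator of feasible unit leaf moves: any state reachable by
# moving one leaf one column while keeping a <= l' <= r' <= b
brute_force_unit_moves <- function(a, b, l, r) {
  cand <- list(c(l - 1L, r), c(l + 1L, r), c(l, r - 1L), c(l, r + 1L))
  Filter(function(s) s[1] >= a && s[2] <= b && s[1] <= s[2], cand)
}

# small phantom cases used by the search tests
small_case <- function(seed = 1, bac = make_equidistant_bacs()[[6]]) {
  geom <- build_phantom(grid_shape = c(21, 21), voxel_size = 0.8,
                        mlc_rows = 3, beamlet_width = 1.6, seed = seed)
  dose <- compute_dose_matrix(geom, bac)
  list(geom = geom, dose = dose, params = objective_params_prostate())
}

plan_intensities_test <- function(plan) {
  unlist(lapply(plan$beams, function(b) b$intensities), use.names = FALSE)
}

# random C1 aperture on a beam mask (sample_one avoids the sample(n, 1) trap)
sample_one <- function(v) v[sample.int(length(v), 1L)]

random_aperture <- function(beam) {
  lo <- integer(beam$n_row); hi <- integer(beam$n_row)
  for (i in seq_len(beam$n_row)) {
    a <- beam$span_lo[i]; b <- beam$span_hi[i]
    lo[i] <- sample_one(a:b)
    hi[i] <- sample_one(lo[i]:b)
  }
  aperture_shape(beam$span_lo, beam$span_hi, lo, hi, n_col = beam$n_col)
}

random_plan <- function(dose, n_apertures = 2, bounds = intensity_bounds()) {
  angles <- vapply(dose$beams, `[[`, numeric(1), "angle")
  beams <- lapply(dose$beams, function(b) {
    shapes <- replicate(n_apertures, random_aperture(b), simplify = FALSE)
    list(shapes = shapes,
         intensities = runif(n_apertures, bounds$gamma_min, bounds$gamma_max))
  })
  dao_plan(bac_spec(angles), beams)
}

# random tiny AWO instance: 1 beam, <= 4 apertures, <= 30 voxels split over a
# target and an organ at risk with random sparse non-negative dose columns
random_awo_instance <- function(K) {
  n_row <- sample(1:2, 1); n_col <- sample(2:3, 1)
  n <- n_row * n_col
  m_t <- sample(3:15, 1); m_o <- sample(3:15, 1)
  index <- matrix(seq_len(n), n_row, n_col, byrow = TRUE)
  beam <- list(angle = 0, n_row = n_row, n_col = n_col,
               span_lo = rep(1L, n_row), span_hi = rep(n_col + 1L, n_row),
               index = index)
  rand_D <- function(m) {
    M <- matrix(runif(m * n), m, n) * (matrix(runif(m * n), m, n) < 0.7)
    Matrix::Matrix(M, sparse = TRUE)
  }
  dose <- new_dose_set(list(PTV = rand_D(m_t), OAR = rand_D(m_o)), n,
                       beam_offsets = 1L, beams = list(beam),
                       region_m = c(PTV = m_t, OAR = m_o), target = "PTV")
  bounds <- if (K <= 2) intensity_bounds(0, 2) else intensity_bounds(0, 0.3)
  params <- objective_params(c("PTV", "OAR"),
                             prescribed = c(runif(1, 0.5, 2), runif(1, 0.1, 1)),
                             under = c(5, 0), over = c(5, 1))
  shapes <- replicate(K, random_aperture(beam), simplify = FALSE)
  plan <- dao_plan(bac_spec(0),
                   list(list(shapes = shapes,
                             intensities = runif(K, bounds$gamma_min,
                                                 bounds$gamma_max))))
  list(dose = dose, params = params, bounds = bounds, plan = plan)
}
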