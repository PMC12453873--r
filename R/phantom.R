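#' Equidistant beam-angle configurations
#'
#' Generates the standard grid of equidistant coplanar beam-angle
#' configurations (BACs): configuration `k` (1-based) uses gantry angles
#' `offset_step * (k - 1) + angle_spacing * (j - 1)` for `j = 1..beams_per_bac`.
#' With the defaults (14 BACs of 5 beams, 5 degree offset, 70 degree spacing)
#' this spans 70 distinct angles out of the usual 72-angle candidate set.
#'
#' @param num_bacs Number of configurations to generate.
#' @param beams_per_bac Beams per configuration.
#' @param offset_step Offset between consecutive configurations (degrees).
#' @param angle_spacing Spacing between beams within a configuration (degrees).
#' @return A list of `dao_bac` objects (each holds sorted gantry angles in
#'   `[0, 360)` degrees).
#' @examples
#' bacs <- make_equidistant_bacs()
#' bacs[[1]]$angles   # 0 70 140 210 280
#' @export
make_equidistant_bacs <- function(num_bacs = 14, beams_per_bac = 5,
                                  offset_step = 5, angle_spacing = 70) {
  stopifnot(num_bacs >= 1, beams_per_bac >= 1,
            offset_step >= 0, angle_spacing >= 0)
  lapply(seq_len(num_bacs), function(k) {
    angles <- offset_step * (k - 1) + angle_spacing * (seq_len(beams_per_bac) - 1)
    if (any(angles >= 360)) {
      abort("BAC generation produced angles >= 360 degrees; reduce the steps.")
    }
    bac_spec(angles)
  })
}

#' Beam-angle configuration
#'
#' @param angles Strictly increasing gantry angles in degrees, `[0, 360)`.
#' @return A `dao_bac` object.
#' @export
bac_spec <- function(angles) {
  angles <- as.numeric(angles)
  stopifnot(length(angles) >= 1, all(angles >= 0), all(angles < 360),
            !is.unsorted(angles, strictly = TRUE))
  structure(list(angles = angles, n_beams = length(angles)), class = "dao_bac")
}

#' @export
print.dao_bac <- function(x, ...) {
  cat("<dao_bac> ", x$n_beams, " beams: ",
      paste0(x$angles, "°", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Default prostate-like region layout
#'
#' One elliptical target (PTV) flanked by an anterior bladder and a posterior
#' rectum, all centred laterally. Centres and radii are in cm relative to the
#' lattice centre; `z_fraction` scales each region's out-of-plane half-extent
#' relative to the phantom half-thickness.
#'
#' @return A tibble with one row per region.
#' @export
phantom_regions <- function() {
  tibble::tibble(
    name       = c("PTV", "bladder", "rectum"),
    centre_x   = c(0, 0, 0),
    centre_y   = c(0, 4.8, -4.4),
    radius_x   = c(3.0, 4.2, 2.6),
    radius_y   = c(2.6, 3.0, 2.0),
    z_fraction = c(0.95, 1.0, 1.0),
    is_target  = c(TRUE, FALSE, FALSE)
  )
}

#' Build a synthetic prostate-like phantom
#'
#' Rasterises elliptical regions onto a 2-D in-plane voxel lattice replicated
#' over `mlc_rows` out-of-plane slabs (one slab per MLC leaf pair). A small
#' seeded boundary jitter roughens region edges so projections are not
#' perfectly smooth; generation is bit-reproducible for a fixed seed.
#'
#' @param grid_shape In-plane lattice dimensions `c(ny, nx)` (voxel counts).
#' @param voxel_size Edge length of a voxel, cm (also the slab thickness).
#' @param mlc_rows Number of MLC leaf pairs per beam (= out-of-plane slabs).
#' @param beamlet_width Lateral beamlet spacing, cm.
#' @param regions Region table as produced by [phantom_regions()].
#' @param boundary_jitter Standard deviation of the ellipsoid-membership
#'   perturbation (unitless, on the normalised radius scale).
#' @param allow_overlap If `FALSE` (default) organ-at-risk voxels that fall
#'   inside the target are removed from the organ.
#' @param seed Integer seed controlling the boundary jitter.
#' @return A `dao_geometry` object.
#' @export
build_phantom <- function(grid_shape = c(31, 31), voxel_size = 0.6,
                          mlc_rows = 5, beamlet_width = 1.2,
                          regions = phantom_regions(),
                          boundary_jitter = 0.04, allow_overlap = FALSE,
                          seed = 1) {
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 1), voxel_size > 0,
            mlc_rows >= 1, beamlet_width > 0, boundary_jitter >= 0)
  if (sum(regions$is_target) != 1) {
    abort("exactly one region must be flagged as the target")
  }
  ny <- grid_shape[1]; nx <- grid_shape[2]; nz <- mlc_rows
  slab <- voxel_size

  ix <- rep(rep(seq_len(nx), each = ny), times = nz)
  iy <- rep(rep(seq_len(ny), times = nx), times = nz)
  iz <- rep(seq_len(nz), each = ny * nx)
  coords <- cbind(
    x = (ix - (nx + 1) / 2) * voxel_size,
    y = ((ny + 1) / 2 - iy) * voxel_size,
    z = (iz - (nz + 1) / 2) * slab
  )
  half_thick <- nz * slab / 2

  run_seeded(seed, {
    voxel_sets <- lapply(seq_len(nrow(regions)), function(i) {
      r <- regions[i, ]
      rz <- max(r$z_fraction * half_thick, slab / 2)
      v <- ((coords[, "x"] - r$centre_x) / r$radius_x)^2 +
           ((coords[, "y"] - r$centre_y) / r$radius_y)^2 +
           (coords[, "z"] / rz)^2
      if (boundary_jitter > 0) v <- v + rnorm(length(v), sd = boundary_jitter)
      which(v <= 1)
    })
    names(voxel_sets) <- regions$name

    target <- voxel_sets[[which(regions$is_target)]]
    if (!allow_overlap) {
      voxel_sets <- imap(voxel_sets, function(ids, nm) {
        if (regions$is_target[match(nm, regions$name)]) ids else setdiff(ids, target)
      })
    }
    empty <- names(voxel_sets)[lengths(voxel_sets) == 0]
    if (length(empty) > 0) {
      abort(paste0("region(s) rasterised to zero voxels: ",
                   paste(empty, collapse = ", ")))
    }

    structure(list(
      grid_shape = c(ny, nx),
      voxel_size = voxel_size,
      slab_thickness = slab,
      mlc_rows = mlc_rows,
      beamlet_width = beamlet_width,
      coords = coords,
      slab_index = iz,
      regions = tibble::tibble(
        name = regions$name,
        is_target = regions$is_target,
        m = unname(lengths(voxel_sets)),
        voxel_ids = unname(voxel_sets)
      )
    ), class = "dao_geometry")
  })
}

#' @export
print.dao_geometry <- function(x, ...) {
  cat("<dao_geometry> ", x$grid_shape[1], "x", x$grid_shape[2], " lattice, ",
      x$mlc_rows, " slabs, voxel ", x$voxel_size, " cm\n", sep = "")
  print(dplyr::select(x$regions, "name", "is_target", "m"))
  invisible(x)
}

#' Pencil-beam dose kernel parameters
#'
#' Exponential depth attenuation with Gaussian lateral spread. `sigma = 0`
#' degenerates to a top-hat profile of one beamlet width (the delta-kernel
#' limit in which each ray only doses the voxels it crosses).
#'
#' @param mu Linear attenuation coefficient, 1/cm (>= 0).
#' @param sigma Lateral Gaussian spread, cm (>= 0; 0 = top-hat).
#' @param cutoff Relative dose below which matrix entries are dropped
#'   (sparsity threshold).
#' @param surface_dose Dose rate on the central ray at zero depth, Gy per MU.
#' @param valid_margin Lateral margin (cm) around the target projection used
#'   to flag beamlets as inside the field.
#' @export
dose_kernel <- function(mu = 0.05, sigma = 0.5, cutoff = 1e-3,
                        surface_dose = 1, valid_margin = 1.0) {
  stopifnot(mu >= 0, sigma >= 0, cutoff >= 0, surface_dose > 0, valid_margin >= 0)
  structure(list(mu = mu, sigma = sigma, cutoff = cutoff,
                 surface_dose = surface_dose, valid_margin = valid_margin),
            class = "dao_kernel")
}

lateral_profile <- function(dist, kernel, width) {
  if (kernel$sigma > 0) {
    exp(-dist^2 / (2 * kernel$sigma^2))
  } else {
    as.numeric(abs(dist) <= width / 2 + 1e-12)
  }
}

#' Dose-deposition matrices for a phantom and beam-angle configuration
#'
#' For every beam the field is discretised into `mlc_rows x n_col` beamlets;
#' parallel rays travel in-plane, each MLC row collimating one slab. A beamlet
#' is part of the usable field (not a "-1" cell) when its central ray passes
#' within `valid_margin` of the target's projection in its slab; valid cells
#' get global beamlet indices row-major within the beam, beams concatenated in
#' BAC order. Entries are `surface_dose * exp(-mu * depth) * lateral(dist)`,
#' truncated below `cutoff` for sparsity, so dose is non-negative and linear
#' in the intensity vector.
#'
#' @param geom A `dao_geometry` from [build_phantom()].
#' @param bac A `dao_bac`.
#' @param kernel A `dao_kernel`.
#' @return A `dao_dose_set`: per-region sparse matrices `D[[region]]`
#'   (`m_r x n`), the beamlet count `n`, 1-based `beam_offsets`, and per-beam
#'   layout (validity spans and the cell-to-beamlet index map).
#' @export
compute_dose_matrix <- function(geom, bac, kernel = dose_kernel()) {
  stopifnot(inherits(geom, "dao_geometry"), inherits(bac, "dao_bac"),
            inherits(kernel, "dao_kernel"))
  nz <- geom$mlc_rows
  bw <- geom$beamlet_width
  field_width <- max(geom$grid_shape) * geom$voxel_size
  n_col <- ceiling(field_width / bw)
  u_off <- (seq_len(n_col) - (n_col + 1) / 2) * bw

  target_ids <- geom$regions$voxel_ids[[which(geom$regions$is_target)]]
  xy <- geom$coords[, c("x", "y")]

  beams <- vector("list", bac$n_beams)
  trip <- lapply(geom$regions$name, function(nm) list(i = integer(), j = integer(), x = numeric()))
  names(trip) <- geom$regions$name

  offset <- 0L
  beam_offsets <- integer(bac$n_beams)
  for (c_idx in seq_len(bac$n_beams)) {
    th <- bac$angles[c_idx] * pi / 180
    e <- c(sin(th), -cos(th))   # ray direction
    u <- c(cos(th), sin(th))    # lateral axis
    proj_e <- as.numeric(xy %*% e)
    proj_u <- as.numeric(xy %*% u)
    depth <- proj_e - min(proj_e)

    # validity spans: columns whose ray passes near the target, per slab
    span_lo <- integer(nz); span_hi <- integer(nz)
    for (i in seq_len(nz)) {
      tv <- target_ids[geom$slab_index[target_ids] == i]
      if (length(tv) == 0) { span_lo[i] <- 1L; span_hi[i] <- 1L; next }
      lat_rng <- range(proj_u[tv])
      ok <- which(u_off >= lat_rng[1] - bw / 2 - kernel$valid_margin &
                  u_off <= lat_rng[2] + bw / 2 + kernel$valid_margin)
      if (length(ok) == 0) { span_lo[i] <- 1L; span_hi[i] <- 1L; next }
      span_lo[i] <- min(ok); span_hi[i] <- max(ok) + 1L
    }

    index <- matrix(NA_integer_, nz, n_col)
    nb <- 0L
    for (i in seq_len(nz)) {
      if (span_hi[i] > span_lo[i]) {
        cols <- span_lo[i]:(span_hi[i] - 1L)
        index[i, cols] <- offset + nb + seq_along(cols)
        nb <- nb + length(cols)
      }
    }
    beam_offsets[c_idx] <- offset + 1L

    for (rg in seq_len(nrow(geom$regions))) {
      nm <- geom$regions$name[rg]
      ids <- geom$regions$voxel_ids[[rg]]
      vslab <- geom$slab_index[ids]
      att <- kernel$surface_dose * exp(-kernel$mu * depth[ids])
      for (i in seq_len(nz)) {
        if (span_hi[i] <= span_lo[i]) next
        rows_r <- which(vslab == i)
        if (length(rows_r) == 0) next
        cols <- span_lo[i]:(span_hi[i] - 1L)
        lat <- outer(proj_u[ids[rows_r]], u_off[cols], "-")
        vals <- att[rows_r] * lateral_profile(lat, kernel, bw)
        keep <- which(vals >= kernel$cutoff * kernel$surface_dose)
        if (length(keep) == 0) next
        kr <- ((keep - 1L) %% length(rows_r)) + 1L
        kc <- ((keep - 1L) %/% length(rows_r)) + 1L
        trip[[nm]]$i <- c(trip[[nm]]$i, rows_r[kr])
        trip[[nm]]$j <- c(trip[[nm]]$j, index[i, cols[kc]])
        trip[[nm]]$x <- c(trip[[nm]]$x, vals[keep])
      }
    }

    beams[[c_idx]] <- list(angle = bac$angles[c_idx], n_row = nz, n_col = n_col,
                           span_lo = span_lo, span_hi = span_hi, index = index)
    offset <- offset + nb
  }

  n <- offset
  D <- lapply(seq_len(nrow(geom$regions)), function(rg) {
    nm <- geom$regions$name[rg]
    Matrix::sparseMatrix(i = trip[[nm]]$i, j = trip[[nm]]$j, x = trip[[nm]]$x,
                         dims = c(geom$regions$m[rg], n))
  })
  names(D) <- geom$regions$name

  new_dose_set(D = D, n = n, beam_offsets = beam_offsets, beams = beams,
               region_m = setNames(geom$regions$m, geom$regions$name),
               target = geom$regions$name[geom$regions$is_target])
}

#' Assemble a dose-deposition set from raw matrices
#'
#' Low-level constructor used by [compute_dose_matrix()] and by tests that
#' build hand-crafted cases. Validates non-negativity, matching column counts
#' and strictly increasing beam offsets.
#'
#' @param D Named list of (sparse) `m_r x n` matrices, one per region.
#' @param n Total beamlet count.
#' @param beam_offsets 1-based start index of each beam's beamlet block.
#' @param beams Per-beam layout: `angle`, `n_row`, `n_col`, half-open validity
#'   spans `span_lo`/`span_hi`, and the `n_row x n_col` global index map.
#' @param region_m Named voxel counts per region.
#' @param target Name of the target region.
#' @export
new_dose_set <- function(D, n, beam_offsets, beams, region_m, target) {
  stopifnot(length(D) >= 1, !is.null(names(D)), target %in% names(D))
  D <- lapply(D, function(M) as(as(M, "generalMatrix"), "CsparseMatrix"))
  for (nm in names(D)) {
    if (ncol(D[[nm]]) != n) abort("all D matrices must have n columns")
    if (length(D[[nm]]@x) && min(D[[nm]]@x) < 0) abort("dose deposition must be >= 0")
  }
  stopifnot(!is.unsorted(beam_offsets, strictly = TRUE))
  structure(list(D = D, n = n, beam_offsets = as.integer(beam_offsets),
                 beams = beams, region_m = region_m, target = target),
            class = "dao_dose_set")
}

#' @export
print.dao_dose_set <- function(x, ...) {
  cat("<dao_dose_set> ", length(x$beams), " beams, n = ", x$n, " beamlets\n",
      sep = "")
  for (nm in names(x$D)) {
    cat("  ", nm, ": ", nrow(x$D[[nm]]), " voxels, ",
        format(length(x$D[[nm]]@x), big.mark = ","), " nonzeros\n", sep = "")
  }
  invisible(x)
}

#' Bundle geometry, BAC, dose matrices and objective parameters
#'
#' Convenience container used by the search drivers and the CLI.
#'
#' @param geometry A `dao_geometry`.
#' @param bac A `dao_bac`.
#' @param kernel A `dao_kernel`.
#' @param params Objective parameters, see [objective_params()].
#' @export
build_case <- function(geometry = build_phantom(),
                       bac = make_equidistant_bacs()[[6]],
                       kernel = dose_kernel(),
                       params = objective_params_prostate()) {
  dose <- compute_dose_matrix(geometry, bac, kernel)
  structure(list(geometry = geometry, bac = bac, dose = dose, params = params),
            class = "dao_case")
}

#' @export
print.dao_case <- function(x, ...) {
  cat("<dao_case>\n")
  print(x$bac)
  print(x$dose)
  invisible(x)
}

#' Serialise / restore a case
#'
#' The case (geometry, BAC, sparse dose matrices, parameters) is stored as a
#' single RDS array container; this is a runtime artifact, regenerable from
#' [build_case()].
#' @param case A `dao_case`.
#' @param path File path.
#' @export
write_case <- function(case, path) {
  stopifnot(inherits(case, "dao_case"))
  saveRDS(case, path)
  invisible(path)
}

#' @rdname write_case
#' @export
read_case <- function(path) {
  case <- readRDS(path)
  stopifnot(inherits(case, "dao_case"))
  case
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
run_seeded <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
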