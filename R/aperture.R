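#' Multi-leaf collimator aperture shape
#'
#' One leaf pair per row. Intervals are half-open on 1-based columns: row `i`
#' of the field is usable on columns `span_lo[i] .. span_hi[i] - 1` (cells
#' outside are the "-1" cells that cover no target voxel) and open on columns
#' `open_lo[i] .. open_hi[i] - 1`. `open_lo == open_hi` encodes a fully closed
#' row whose leaves meet at that column, so re-opening stays well defined.
#' Storing one interval per row enforces the consecutive-ones (C1) property by
#' construction: both leaves of a physical MLC row close from opposite sides,
#' so open cells are always contiguous.
#'
#' @param span_lo,span_hi Integer vectors, half-open validity span per row.
#' @param open_lo,open_hi Integer vectors, half-open open interval per row;
#'   default fully open.
#' @param n_col Number of field columns (defaults to the largest span bound).
#' @return A `dao_aperture`.
#' @export
aperture_shape <- function(span_lo, span_hi, open_lo = span_lo,
                           open_hi = span_hi, n_col = max(span_hi) - 1L) {
  span_lo <- as.integer(span_lo); span_hi <- as.integer(span_hi)
  open_lo <- as.integer(open_lo); open_hi <- as.integer(open_hi)
  n <- length(span_lo)
  stopifnot(length(span_hi) == n, length(open_lo) == n, length(open_hi) == n,
            n >= 1)
  shape <- structure(list(n_row = n, n_col = as.integer(n_col),
                          span_lo = span_lo, span_hi = span_hi,
                          open_lo = open_lo, open_hi = open_hi),
                     class = "dao_aperture")
  if (!validate_c1(shape)) {
    abort("invalid aperture: need span_lo <= open_lo <= open_hi <= span_hi per row")
  }
  shape
}

#' Check the consecutive-ones property of an aperture
#'
#' For interval-encoded apertures this verifies the leaf-interval ordering
#' `a <= l <= r <= b` per row; for a `{-1, 0, 1}` matrix it checks that every
#' row's open (1) cells form one contiguous run inside the row's valid
#' (non -1) cells, which must themselves be contiguous. A fully closed row is
#' valid.
#'
#' @param shape A `dao_aperture` or a matrix with entries in `{-1, 0, 1}`.
#' @return `TRUE` or `FALSE`.
#' @export
validate_c1 <- function(shape) UseMethod("validate_c1")

#' @export
validate_c1.dao_aperture <- function(shape) {
  all(shape$span_lo <= shape$open_lo) &&
    all(shape$open_lo <= shape$open_hi) &&
    all(shape$open_hi <= shape$span_hi) &&
    all(shape$span_lo >= 1L) &&
    all(shape$span_hi <= shape$n_col + 1L)
}

#' @export
validate_c1.matrix <- function(shape) {
  if (!all(shape %in% c(-1, 0, 1))) return(FALSE)
  for (i in seq_len(nrow(shape))) {
    row <- shape[i, ]
    valid <- which(row != -1)
    if (length(valid) > 0 && any(diff(valid) != 1L)) return(FALSE)
    ones <- which(row == 1)
    if (length(ones) == 0) next
    if (any(diff(ones) != 1L)) return(FALSE)
    if (length(valid) == 0 || min(ones) < min(valid) || max(ones) > max(valid)) {
      return(FALSE)
    }
  }
  TRUE
}

#' @export
as.matrix.dao_aperture <- function(x, ...) {
  M <- matrix(-1, x$n_row, x$n_col)
  for (i in seq_len(x$n_row)) {
    if (x$span_hi[i] > x$span_lo[i]) {
      M[i, x$span_lo[i]:(x$span_hi[i] - 1L)] <- 0
    }
    if (x$open_hi[i] > x$open_lo[i]) {
      M[i, x$open_lo[i]:(x$open_hi[i] - 1L)] <- 1
    }
  }
  M
}

#' @export
print.dao_aperture <- function(x, ...) {
  M <- as.matrix(x)
  cat("<dao_aperture> ", x$n_row, "x", x$n_col, "\n", sep = "")
  sym <- c(`-1` = ".", `0` = "-", `1` = "#")
  for (i in seq_len(nrow(M))) {
    cat(" ", paste(sym[as.character(M[i, ])], collapse = ""), "\n", sep = "")
  }
  invisible(x)
}

open_width <- function(shape) sum(pmax(shape$open_hi - shape$open_lo, 0L))

same_mask <- function(a, b) {
  a$n_row == b$n_row && a$n_col == b$n_col &&
    all(a$span_lo == b$span_lo) && all(a$span_hi == b$span_hi)
}

#' Aggregate a beam's apertures into a fluence matrix
#'
#' The per-beam fluence is the intensity-weighted sum of the aperture shape
#' matrices: `A_c = sum_i S_i^c * I_i^c`. Cells outside the validity span are
#' returned as `NA` (they are outside the usable field and never carry
#' fluence).
#'
#' @param shapes Either a list of `dao_aperture` sharing one validity mask, or
#'   a beam record `list(shapes =, intensities =)`.
#' @param intensities Numeric intensities (MU), one per shape; omit when
#'   `shapes` is a beam record.
#' @return A numeric `n_row x n_col` matrix with `NA` at invalid cells.
#' @examples
#' sh <- aperture_shape(1, 5, 1, 5)               # one fully open 1x4 row
#' aggregate_fluence(list(sh), 7)                  # every cell 7
#' @export
aggregate_fluence <- function(shapes, intensities = NULL) {
  if (!is.null(shapes$shapes)) {
    intensities <- shapes$intensities
    shapes <- shapes$shapes
  }
  stopifnot(length(shapes) == length(intensities), length(shapes) >= 1,
            all(intensities >= 0))
  ref <- shapes[[1]]
  A <- matrix(0, ref$n_row, ref$n_col)
  for (k in seq_along(shapes)) {
    s <- shapes[[k]]
    if (!same_mask(s, ref)) abort("apertures of one beam must share their validity mask")
    for (i in seq_len(s$n_row)) {
      if (s$open_hi[i] > s$open_lo[i]) {
        cols <- s$open_lo[i]:(s$open_hi[i] - 1L)
        A[i, cols] <- A[i, cols] + intensities[k]
      }
    }
  }
  for (i in seq_len(ref$n_row)) {
    invalid <- setdiff(seq_len(ref$n_col),
                       if (ref$span_hi[i] > ref$span_lo[i])
                         ref$span_lo[i]:(ref$span_hi[i] - 1L) else integer())
    A[i, invalid] <- NA_real_
  }
  A
}

# the five predetermined shapes for one beam's validity mask
adhoc_shapes_for_beam <- function(beam) {
  nr <- beam$n_row
  a <- beam$span_lo; b <- beam$span_hi
  mid <- pmin(pmax(a + (b - a) %/% 2L, a), b)
  full <- function() aperture_shape(a, b, a, b, n_col = beam$n_col)
  rows_open <- function(open_rows) {
    lo <- ifelse(seq_len(nr) %in% open_rows, a, mid)
    hi <- ifelse(seq_len(nr) %in% open_rows, b, mid)
    aperture_shape(a, b, lo, hi, n_col = beam$n_col)
  }
  half_cols <- function(side) {
    w <- b - a
    cut <- a + ceiling(w / 2)
    if (side == "left") {
      aperture_shape(a, b, a, pmax(cut, a), n_col = beam$n_col)
    } else {
      aperture_shape(a, b, pmin(cut, b), b, n_col = beam$n_col)
    }
  }
  bottom_rows <- which(seq_len(nr) - 1L >= ceiling(nr / 2))  # 0-based ceil(R/2)..R-1
  top_rows <- setdiff(seq_len(nr), bottom_rows)
  list(bottom = rows_open(bottom_rows),
       top = rows_open(top_rows),
       right = half_cols("right"),
       left = half_cols("left"),
       open = full())
}
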