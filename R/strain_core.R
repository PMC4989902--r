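# Lagrangian strain from displacement fields.
#
# With reference coordinates (X, Y) and deformed coordinates
# (x, y) = (X + u, Y + v), the deformation gradient is
#   F = [[dx/dX, dx/dY], [dy/dX, dy/dY]],
# estimated by central differences of the displacement components over a
# four-point stencil (X +/- h, Y) and (X, Y +/- h).  The Lagrangian strain
# is E = (F'F - I)/2; its eigenvalues follow from the invariants
# I1 = E11 + E22 and I2 = E11 E22 - E12^2 as
#   lambda_+/- = (I1 +/- sqrt(I1^2 - 4 I2)) / 2,
# with I1^2 - 4 I2 = (E11 - E22)^2 + 4 E12^2 >= 0, so both are real.  The
# major eigenvector is proportional to (E12, lambda_+ - E11) and is
# oriented so a component points toward the lumen.  A constant added to
# the displacement cancels in the central differences, so rigid
# translation leaves every strain unchanged (to the rounding of the
# shifted values).

#' Deformation gradient at a point by central differences
#'
#' Uses the four displacement samples around the point of interest,
#' `(X +/- h, Y)` and `(X, Y +/- h)`, exact for displacement fields linear
#' in position.
#'
#' @param field a [displacement_field].
#' @param point `c(x, y)` 0-based pixel coordinates; must be at least `h`
#'   px from every frame edge.
#' @param h stencil half-width in px (integer).
#' @return 2x2 matrix `F` (rows: x, y of the deformed position; columns:
#'   d/dX, d/dY).
#' @export
deformation_gradient_at <- function(field, point, h) {
  nr <- nrow(field$u); nc <- ncol(field$u)
  x <- point[1]; y <- point[2]
  if (x - h < 0 || x + h > nc - 1 || y - h < 0 || y + h > nr - 1)
    stopf("stencil of half-width %g at (%g, %g) exits the %d x %d frame",
          h, x, y, nc, nr)
  ix <- x + 1; iy <- y + 1  # 1-based matrix indices
  dudX <- (field$u[iy, ix + h] - field$u[iy, ix - h]) / (2 * h)
  dudY <- (field$u[iy + h, ix] - field$u[iy - h, ix]) / (2 * h)
  dvdX <- (field$v[iy, ix + h] - field$v[iy, ix - h]) / (2 * h)
  dvdY <- (field$v[iy + h, ix] - field$v[iy - h, ix]) / (2 * h)
  F <- matrix(c(1 + dudX, dvdX, dudY, 1 + dvdY), 2, 2)
  if (det(F) <= 0)
    attr(F, "degenerate") <- TRUE   # flow noise can fold the map; flagged
  F
}

#' Lagrangian strain tensor from a deformation gradient
#'
#' `E = (F'F - I) / 2`, the Green-Lagrange strain: zero for any rigid
#' motion, positive principal values for stretch, negative for
#' compression.
#'
#' @param F 2x2 deformation gradient matrix.
#' @return list of class `strain_tensor` with `E11`, `E12`, `E22` and the
#'   invariants `I1`, `I2`.
#' @export
lagrangian_strain <- function(F) {
  C <- crossprod(F)                 # F'F, right Cauchy-Green tensor
  E11 <- (C[1, 1] - 1) / 2
  E22 <- (C[2, 2] - 1) / 2
  E12 <- C[1, 2] / 2
  structure(list(E11 = E11, E12 = E12, E22 = E22,
                 I1 = E11 + E22, I2 = E11 * E22 - E12^2),
            class = "strain_tensor")
}

#' Principal strains and major eigenvector of a 2x2 strain tensor
#'
#' Solves the characteristic polynomial via the invariants:
#' `lambda_+/- = (I1 +/- sqrt((E11-E22)^2 + 4 E12^2)) / 2`.  The unit major
#' eigenvector is proportional to `(E12, lambda_+ - E11)`; when the
#' eigenvalue is repeated (E11 = E22, E12 = 0) every direction is an
#' eigenvector and the result is flagged `degenerate` so the caller can
#' substitute the radial direction.
#'
#' @param E a `strain_tensor` from [lagrangian_strain()], or a list with
#'   `E11`, `E12`, `E22`.
#' @return list of class `principal_strain`: `lambda_major`,
#'   `lambda_minor`, `major_eigenvector` (unit 2-vector), `degenerate`.
#' @export
principal_strains <- function(E) {
  disc <- sqrt((E$E11 - E$E22)^2 + 4 * E$E12^2)
  I1 <- E$E11 + E$E22
  lp <- (I1 + disc) / 2
  lm <- (I1 - disc) / 2
  wx <- E$E12; wy <- lp - E$E11
  n <- sqrt(wx^2 + wy^2)
  scale <- max(abs(E$E11), abs(E$E22), abs(E$E12), 1)
  degenerate <- FALSE
  if (n <= 1e-14 * scale) {
    if (abs(E$E11 - E$E22) <= 1e-14 * scale) {
      # truly repeated eigenvalue: any direction is an eigenvector
      degenerate <- TRUE
      vec <- c(1, 0)                # placeholder; see strain_field()
    } else {
      # diagonal tensor with E11 > E22: the formula's row degenerates but
      # the major eigenvector is the x axis
      vec <- c(1, 0)
    }
  } else {
    vec <- c(wx, wy) / n
  }
  structure(list(lambda_major = lp, lambda_minor = lm,
                 major_eigenvector = vec, degenerate = degenerate),
            class = "principal_strain")
}

#' Orient an eigenvector toward the airway lumen
#'
#' The eigenvector of the major principal strain is defined up to sign;
#' by convention it is flipped, if necessary, so that it has a component
#' pointing toward (not away from) the lumen centre.  An exactly
#' tangential vector (zero dot product) keeps its input sign, and a point
#' coinciding with the centre is returned unchanged with a warning.
#'
#' @param vec unit 2-vector `c(x, y)`.
#' @param point evaluation position `c(x, y)` (reference coordinates, px).
#' @param lumen_center lumen centre `c(x, y)` (px).
#' @return unit 2-vector, `vec` or `-vec`.
#' @export
orient_major_eigenvector <- function(vec, point, lumen_center) {
  to_lumen <- c(lumen_center[1] - point[1], lumen_center[2] - point[2])
  if (all(to_lumen == 0)) {
    warnf("evaluation point coincides with the lumen centre; orientation unchanged")
    return(vec)
  }
  d <- sum(vec * to_lumen)
  if (d < 0) -vec else vec
}

#' Principal-strain field on a regular evaluation grid
#'
#' Evaluates the Lagrangian strain tensor at equally spaced grid points
#' across the frame (excluding a boundary margin of the stencil
#' half-width), eigen-decomposes it, orients major eigenvectors toward the
#' lumen, and zeroes strains where there is no tissue.
#'
#' @param field a [displacement_field].
#' @param grid_spacing grid step in px (default 7).
#' @param h central-difference stencil half-width in px (default =
#'   `grid_spacing`).
#' @param mask optional logical tissue mask (frame-sized); strains at grid
#'   points off tissue are set to zero.
#' @param lumen_center lumen centre `c(x, y)` in px for eigenvector
#'   orientation (and for the radial convention at degenerate points).
#' @return object of class `strain_field`: matrices `lambda_major`,
#'   `lambda_minor`, `evec_x`, `evec_y`, `on_tissue` over the grid, plus
#'   `grid_x`, `grid_y` (0-based px), `spacing`, `h`, `pixel_size`,
#'   `lumen_center`.
#' @export
strain_field <- function(field, grid_spacing = 7, h = grid_spacing,
                         mask = NULL, lumen_center) {
  nr <- nrow(field$u); nc <- ncol(field$u)
  h <- as.integer(h); grid_spacing <- as.integer(grid_spacing)
  gx <- seq(h, nc - 1 - h, by = grid_spacing)       # 0-based
  gy <- seq(h, nr - 1 - h, by = grid_spacing)
  if (length(gx) == 0 || length(gy) == 0)
    stopf("frame too small for stencil half-width %d", h)
  cx <- gx + 1; cy <- gy + 1                        # 1-based
  u <- field$u; v <- field$v
  dudX <- (u[cy, cx + h, drop = FALSE] - u[cy, cx - h, drop = FALSE]) / (2 * h)
  dudY <- (u[cy + h, cx, drop = FALSE] - u[cy - h, cx, drop = FALSE]) / (2 * h)
  dvdX <- (v[cy, cx + h, drop = FALSE] - v[cy, cx - h, drop = FALSE]) / (2 * h)
  dvdY <- (v[cy + h, cx, drop = FALSE] - v[cy - h, cx, drop = FALSE]) / (2 * h)
  F11 <- 1 + dudX; F12 <- dudY; F21 <- dvdX; F22 <- 1 + dvdY
  E11 <- (F11^2 + F21^2 - 1) / 2
  E22 <- (F12^2 + F22^2 - 1) / 2
  E12 <- (F11 * F12 + F21 * F22) / 2
  disc <- sqrt((E11 - E22)^2 + 4 * E12^2)
  I1 <- E11 + E22
  lp <- (I1 + disc) / 2
  lm <- (I1 - disc) / 2
  wx <- E12; wy <- lp - E11
  n <- sqrt(wx^2 + wy^2)
  # grid point coordinate matrices (rows = gy, cols = gx)
  px <- matrix(rep(gx, each = length(gy)), length(gy), length(gx))
  py <- matrix(rep(gy, times = length(gx)), length(gy), length(gx))
  rx <- lumen_center[1] - px
  ry <- lumen_center[2] - py
  rn <- sqrt(rx^2 + ry^2)
  scl <- pmax(abs(E11), abs(E22), abs(E12), 1)
  zero_n <- n <= 1e-14 * scl
  # diagonal tensor with E11 > E22: major eigenvector is the x axis
  axis_x <- zero_n & abs(E11 - E22) > 1e-14 * scl
  wx[axis_x] <- 1; wy[axis_x] <- 0; n[axis_x] <- 1
  # truly repeated eigenvalue: use the unit radial direction to the lumen
  deg <- zero_n & !axis_x
  wx[deg] <- ifelse(rn[deg] > 0, rx[deg] / rn[deg], 1)
  wy[deg] <- ifelse(rn[deg] > 0, ry[deg] / rn[deg], 0)
  n[deg] <- 1
  evx <- wx / n; evy <- wy / n
  flip <- (evx * rx + evy * ry) < 0
  evx[flip] <- -evx[flip]; evy[flip] <- -evy[flip]
  on_tissue <- matrix(TRUE, length(gy), length(gx))
  if (!is.null(mask)) {
    on_tissue <- matrix(mask[cbind(as.vector(py) + 1, as.vector(px) + 1)],
                        length(gy), length(gx))
    if (!any(on_tissue))
      warnf("tissue mask is empty on the evaluation grid; all strains zero")
    lp[!on_tissue] <- 0
    lm[!on_tissue] <- 0
  }
  structure(list(lambda_major = lp, lambda_minor = lm,
                 evec_x = evx, evec_y = evy, on_tissue = on_tissue,
                 E11 = E11, E12 = E12, E22 = E22,
                 grid_x = gx, grid_y = gy,
                 spacing = grid_spacing, h = h,
                 pixel_size = field$pixel_size,
                 lumen_center = lumen_center,
                 reference_index = field$reference_index,
                 target_index = field$target_index),
            class = "strain_field")
}

#' @export
print.strain_field <- function(x, ...) {
  cat(sprintf(paste0("<strain_field> %d x %d grid (spacing %d px, h = %d px), ",
                     "lambda_major in [%.3g, %.3g]\n"),
              length(x$grid_x), length(x$grid_y), x$spacing, x$h,
              min(x$lambda_major), max(x$lambda_major)))
  invisible(x)
}

#' Flatten a strain field to a data frame
#'
#' One row per evaluation grid point with positions in px and um, the
#' principal strains and the oriented major eigenvector.
#'
#' @param x a [strain_field()].
#' @param ... unused.
#' @return data.frame with columns `X_px`, `Y_px`, `X_um`, `Y_um`,
#'   `lambda_major`, `lambda_minor`, `evec_x`, `evec_y`, `on_tissue`.
#' @export
as.data.frame.strain_field <- function(x, ...) {
  ny <- length(x$grid_y); nx <- length(x$grid_x)
  px <- rep(x$grid_x, each = ny)
  py <- rep(x$grid_y, times = nx)
  data.frame(X_px = px, Y_px = py,
             X_um = px * x$pixel_size, Y_um = py * x$pixel_size,
             lambda_major = as.vector(x$lambda_major),
             lambda_minor = as.vector(x$lambda_minor),
             evec_x = as.vector(x$evec_x),
             evec_y = as.vector(x$evec_y),
             on_tissue = as.vector(x$on_tissue))
}
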