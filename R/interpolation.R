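# Bilinear interpolation used throughout: image warping, incremental flow
# composition and spokes sampling all share this kernel.

#' Bilinear sampling of images and displacement fields
#'
#' Standard bilinear weighting of the four pixels surrounding a continuous
#' query position (0-based pixel coordinates, pixel centres at integers).
#' Exact at integer coordinates and exact for fields that are linear in
#' (x, y).
#'
#' @param x a numeric matrix, or a [displacement_field].
#' @param ... passed to methods.
#' @return For a matrix: sampled values with the shape of the query
#'   coordinates.  For a displacement field: a list with vectors `u` and
#'   `v` (px).
#' @export
bilinear_sample <- function(x, ...) UseMethod("bilinear_sample")

#' @rdname bilinear_sample
#' @param xq,yq query coordinates (0-based px; any common shape).
#' @param fill value returned for queries outside the frame interior; use
#'   `NA` to detect them, or a constant for warping.  If `fill = "error"`
#'   an out-of-domain query raises an error.
#' @export
bilinear_sample.matrix <- function(x, xq, yq, fill = NA_real_, ...) {
  nr <- nrow(x); nc <- ncol(x)
  shp <- dim(xq)
  xqv <- as.vector(xq); yqv <- as.vector(yq)
  bad <- xqv < 0 | xqv > nc - 1 | yqv < 0 | yqv > nr - 1 |
    !is.finite(xqv) | !is.finite(yqv)
  if (identical(fill, "error")) {
    if (any(bad)) stopf("%d sample point(s) outside the frame domain",
                        sum(bad))
    fill <- NA_real_
  }
  x0 <- floor(pmin(pmax(xqv, 0), nc - 1)); y0 <- floor(pmin(pmax(yqv, 0), nr - 1))
  x0 <- pmin(x0, nc - 2); y0 <- pmin(y0, nr - 2)
  fx <- pmin(pmax(xqv - x0, 0), 1); fy <- pmin(pmax(yqv - y0, 0), 1)
  i00 <- (x0) * nr + y0 + 1            # column-major linear index
  v <- (1 - fx) * ((1 - fy) * x[i00] + fy * x[i00 + 1]) +
    fx * ((1 - fy) * x[i00 + nr] + fy * x[i00 + nr + 1])
  v[bad] <- fill
  if (!is.null(shp)) dim(v) <- shp
  v
}

# Catmull-Rom bicubic sampling, used for image warping inside the flow
# solver: bilinear warping attenuates the speckle carrier unevenly with
# subpixel phase, which shows up as spurious strain; the cubic kernel
# suppresses that interpolation bias.  Queries need a 2 px border.
#' @noRd
.bicubic_sample <- function(img, xq, yq, fill = NA_real_) {
  nr <- nrow(img); nc <- ncol(img)
  xv <- as.vector(xq); yv <- as.vector(yq)
  bad <- xv < 1 | xv > nc - 2 | yv < 1 | yv > nr - 2 |
    !is.finite(xv) | !is.finite(yv)
  xv2 <- pmin(pmax(xv, 1), nc - 2); yv2 <- pmin(pmax(yv, 1), nr - 2)
  x0 <- floor(xv2); y0 <- floor(yv2)
  fx <- xv2 - x0; fy <- yv2 - y0
  wcr <- function(t) list(
    ((-0.5 * t + 1) * t - 0.5) * t,
    (1.5 * t - 2.5) * t * t + 1,
    ((-1.5 * t + 2) * t + 0.5) * t,
    (0.5 * t - 0.5) * t * t)
  wx <- wcr(fx); wy <- wcr(fy)
  acc <- numeric(length(xv))
  for (j in 0:3) {
    base <- (x0 - 1 + j) * nr + y0        # linear index of (y0-1, col) + 1
    rowv <- wy[[1]] * img[base] + wy[[2]] * img[base + 1] +
      wy[[3]] * img[base + 2] + wy[[4]] * img[base + 3]
    acc <- acc + wx[[j + 1]] * rowv
  }
  acc[bad] <- fill
  if (!is.null(dim(xq))) dim(acc) <- dim(xq)
  acc
}

#' @rdname bilinear_sample
#' @param point query position(s): `c(x, y)` or a 2-column matrix of
#'   (x, y) rows (0-based px).
#' @export
bilinear_sample.displacement_field <- function(x, point, fill = "error",
                                               ...) {
  if (is.null(dim(point))) point <- matrix(point, ncol = 2, byrow = FALSE)
  if (is.data.frame(point)) point <- as.matrix(point)
  list(u = bilinear_sample(x$u, point[, 1], point[, 2], fill = fill),
       v = bilinear_sample(x$v, point[, 1], point[, 2], fill = fill))
}
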