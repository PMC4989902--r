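# Lumen segmentation, ellipse fitting and the airway caliber time series.

#' Segment the airway lumen
#'
#' Runs two candidate segmentations and keeps the better one: (1) global
#' Otsu thresholding of the smoothed frame, keeping the bright connected
#' component at the seed; (2) tolerance-based region growing (flood fill)
#' from the seed.  The winner is the candidate whose boundary has the
#' higher mean gradient magnitude (the sharper edge); ties go to the
#' larger region.  A valid lumen must be a smooth (untextured) region of
#' at least `min_area` px — a frame of pure speckle with no lumen is a
#' segmentation error.
#'
#' @param frame intensity matrix in `[0, 1]`.
#' @param seed_hint interior point `c(x, y)` (0-based px); default frame
#'   centre.
#' @param smooth_sigma Gaussian presmoothing (px) before both methods.
#' @param grow_tol intensity tolerance of the region-growing method.
#' @param min_area minimum candidate area (px).
#' @return logical matrix, `TRUE` on the lumen (single connected
#'   component, holes filled).
#' @export
segment_lumen <- function(frame, seed_hint = NULL, smooth_sigma = 3,
                          grow_tol = 0.1, min_area = 500) {
  nr <- nrow(frame); nc <- ncol(frame)
  if (is.null(seed_hint)) seed_hint <- c((nc - 1) / 2, (nr - 1) / 2)
  seed_rc <- c(round(seed_hint[2]) + 1, round(seed_hint[1]) + 1)
  seed_rc <- pmin(pmax(seed_rc, 1), c(nr, nc))
  sm <- .gsmooth(frame, smooth_sigma)

  candidates <- list(
    threshold = .lumen_by_threshold(sm, seed_rc),
    region_growing = .lumen_by_growing(sm, seed_rc, grow_tol))
  candidates <- Filter(function(m) !is.null(m) && sum(m) >= min_area,
                       candidates)
  # the lumen is featureless: reject textured candidates (e.g. a bright
  # speckle patch) by comparing interior texture to the frame's split
  candidates <- Filter(function(m) .is_smooth_region(frame, m), candidates)
  if (length(candidates) == 0L)
    stopf(paste0("lumen segmentation failed: no smooth bright region of ",
                 ">= %d px found around seed (%g, %g)"),
          min_area, seed_hint[1], seed_hint[2])
  scores <- vapply(candidates, function(m) .boundary_sharpness(sm, m),
                   numeric(1))
  areas <- vapply(candidates, sum, numeric(1))
  best <- order(-scores, -areas)[1]
  candidates[[best]]
}

.lumen_by_threshold <- function(sm, seed_rc) {
  th <- EBImage::otsu(sm, range = range(sm))
  bright <- sm > th
  if (!any(bright)) return(NULL)
  lab <- EBImage::bwlabel(bright * 1)
  id <- lab[seed_rc[1], seed_rc[2]]
  if (id == 0) {
    # seed not on a bright region: take the nearest bright component
    idx <- which(bright)
    rows <- (idx - 1) %% nrow(sm) + 1
    cols <- (idx - 1) %/% nrow(sm) + 1
    j <- which.min((rows - seed_rc[1])^2 + (cols - seed_rc[2])^2)
    id <- lab[rows[j], cols[j]]
  }
  m <- lab == id
  EBImage::fillHull(m * 1) > 0
}

.lumen_by_growing <- function(sm, seed_rc, tol) {
  filled <- EBImage::floodFill(sm, pt = seed_rc, col = 2, tolerance = tol)
  m <- filled == 2
  if (!any(m)) return(NULL)
  EBImage::fillHull(m * 1) > 0
}

.boundary_pixels <- function(mask) {
  er <- EBImage::erode(mask * 1, EBImage::makeBrush(3, "box")) > 0
  mask & !er
}

.boundary_sharpness <- function(sm, mask) {
  gb <- .boundary_pixels(mask)
  if (!any(gb)) return(-Inf)
  gx <- .grad_x(sm); gy <- .grad_y(sm)
  mean(sqrt(gx[gb]^2 + gy[gb]^2))
}

.is_smooth_region <- function(frame, mask) {
  mu <- .gsmooth(frame, 2); mu2 <- .gsmooth(frame^2, 2)
  lsd <- sqrt(pmax(mu2 - mu^2, 0))
  core <- EBImage::erode(mask * 1, EBImage::makeBrush(7, "disc")) > 0
  if (!any(core)) core <- mask
  if (all(mask)) return(TRUE)
  # the lumen is featureless but its wall is textured tissue: compare the
  # candidate's interior to the shell immediately surrounding it (the
  # far field may legitimately be smooth agarose/background)
  shell <- (EBImage::dilate(mask * 1, EBImage::makeBrush(31, "disc")) > 0) &
    !(EBImage::dilate(mask * 1, EBImage::makeBrush(7, "disc")) > 0)
  if (!any(shell)) return(TRUE)
  wall <- median(lsd[shell])
  if (wall <= .Machine$double.eps) return(TRUE)
  median(lsd[core]) < 0.5 * wall
}

#' Least-squares ellipse fit to a lumen mask
#'
#' Direct least-squares fitting of an ellipse (conic with the ellipse
#' constraint) to the boundary pixels of the mask.
#'
#' @param mask logical matrix, non-empty connected region with at least 5
#'   boundary pixels.
#' @return list of class `lumen_ellipse`: `center` (`c(x, y)`, 0-based
#'   px), `a`, `b` (semi-axes, px, `a >= b`), `angle` (radians, major-axis
#'   direction in `[0, pi)`).
#' @export
fit_ellipse <- function(mask) {
  if (!any(mask)) stopf("cannot fit an ellipse to an empty mask")
  gb <- .boundary_pixels(mask)
  idx <- which(gb)
  if (length(idx) < 5L)
    stopf("ellipse fit needs >= 5 boundary pixels, got %d", length(idx))
  y <- (idx - 1) %% nrow(mask)         # 0-based
  x <- (idx - 1) %/% nrow(mask)
  mx <- mean(x); my <- mean(y)
  xs <- x - mx; ys <- y - my
  # direct least-squares conic fit with the 4AC - B^2 = 1 constraint
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M2 <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M2)
  cond <- 4 * Re(ev$vectors[1, ]) * Re(ev$vectors[3, ]) -
    Re(ev$vectors[2, ])^2
  k <- which(cond > 0)
  if (length(k) == 0L) stopf("ellipse fit degenerate (no elliptic solution)")
  a1 <- Re(ev$vectors[, k[1]])
  coefs <- c(a1, Tm %*% a1)            # A B C D E F (centred coords)
  .conic_to_ellipse(coefs, mx, my)
}

.conic_to_ellipse <- function(co, mx, my) {
  A <- co[1]; B <- co[2]; C <- co[3]; D <- co[4]; E <- co[5]; Ff <- co[6]
  den <- B^2 - 4 * A * C
  xc <- (2 * C * D - B * E) / den
  yc <- (2 * A * E - B * D) / den
  Fc <- A * xc^2 + B * xc * yc + C * yc^2 + D * xc + E * yc + Ff
  Mq <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eg <- eigen(Mq, symmetric = TRUE)
  ax <- sqrt(-Fc / eg$values)          # both positive for a real ellipse
  if (any(!is.finite(ax)))
    stopf("ellipse fit degenerate (non-elliptic conic)")
  ord <- order(-ax)                    # major first
  major_vec <- eg$vectors[, ord[1]]
  ang <- atan2(major_vec[2], major_vec[1]) %% pi
  structure(list(center = c(xc + mx, yc + my),
                 a = ax[ord[1]], b = ax[ord[2]], angle = ang),
            class = "lumen_ellipse")
}

#' @export
print.lumen_ellipse <- function(x, ...) {
  cat(sprintf(
    "<lumen_ellipse> centre (%.1f, %.1f) px, semi-axes %.1f x %.1f px, angle %.1f deg\n",
    x$center[1], x$center[2], x$a, x$b, x$angle * 180 / pi))
  invisible(x)
}

#' Render a filled ellipse as a binary mask (for round-trip checks)
#' @param ellipse a `lumen_ellipse`
#' @param shape output `c(rows, cols)`
#' @return logical matrix
#' @export
ellipse_mask <- function(ellipse, shape) {
  xg <- matrix(rep(0:(shape[2] - 1), each = shape[1]), shape[1], shape[2])
  yg <- matrix(rep(0:(shape[1] - 1), times = shape[2]), shape[1], shape[2])
  dx <- xg - ellipse$center[1]; dy <- yg - ellipse$center[2]
  ca <- cos(ellipse$angle); sa <- sin(ellipse$angle)
  xr <- ca * dx + sa * dy; yr <- -sa * dx + ca * dy
  (xr / ellipse$a)^2 + (yr / ellipse$b)^2 <= 1
}

#' Airway caliber (lumen area) time series
#'
#' Segments the lumen in every frame (seeding each frame with the previous
#' frame's lumen centroid for temporal coherence), fits an ellipse, and
#' converts pixel counts to um^2.  Frames whose segmentation fails are
#' interpolated from their neighbours with a warning; if more than 20% of
#' frames fail the series is considered unreliable and an error is
#' raised.
#'
#' @param sequence a [frame_sequence].
#' @param seed_hint optional initial seed `c(x, y)` px for the first
#'   frame.
#' @param ... passed to [segment_lumen()].
#' @return data.frame of class `lumen_series`: `time_s`, `area_um2`,
#'   `center_x_px`, `center_y_px`, `a_px`, `b_px`, `angle_rad`,
#'   `segmented` (FALSE where interpolated).  The first frame's mask and
#'   ellipse are attached as attributes `reference_mask` and
#'   `reference_ellipse`.
#' @export
lumen_area_series <- function(sequence, seed_hint = NULL, ...) {
  n <- length(sequence$frames)
  px2 <- sequence$pixel_size^2
  out <- data.frame(time_s = sequence$times, area_um2 = NA_real_,
                    center_x_px = NA_real_, center_y_px = NA_real_,
                    a_px = NA_real_, b_px = NA_real_, angle_rad = NA_real_,
                    segmented = FALSE)
  seed <- seed_hint
  ref_mask <- NULL; ref_ellipse <- NULL
  for (i in seq_len(n)) {
    res <- tryCatch({
      m <- segment_lumen(sequence$frames[[i]], seed_hint = seed, ...)
      e <- fit_ellipse(m)
      list(m = m, e = e)
    }, error = function(err) NULL)
    if (!is.null(res)) {
      out$area_um2[i] <- sum(res$m) * px2
      out$center_x_px[i] <- res$e$center[1]
      out$center_y_px[i] <- res$e$center[2]
      out$a_px[i] <- res$e$a; out$b_px[i] <- res$e$b
      out$angle_rad[i] <- res$e$angle
      out$segmented[i] <- TRUE
      seed <- res$e$center
      if (i == sequence$reference_index) {
        ref_mask <- res$m; ref_ellipse <- res$e
      }
    }
  }
  n_fail <- sum(!out$segmented)
  if (n_fail > 0.2 * n)
    stopf("lumen segmentation failed on %d of %d frames (> 20%%)", n_fail, n)
  if (n_fail > 0) {
    warnf("lumen segmentation failed on %d frame(s); areas interpolated",
          n_fail)
    ok <- out$segmented
    for (col in c("area_um2", "center_x_px", "center_y_px", "a_px", "b_px",
                  "angle_rad"))
      out[[col]] <- approx(out$time_s[ok], out[[col]][ok],
                           xout = out$time_s, rule = 2)$y
  }
  attr(out, "reference_mask") <- ref_mask
  attr(out, "reference_ellipse") <- ref_ellipse
  class(out) <- c("lumen_series", "data.frame")
  out
}
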