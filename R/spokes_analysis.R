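# Spokes analysis: displacement and strain sampled along rays normal to
# the lumen ellipse, averaged within angular sections.  Where the
# whole-field strain map shows the global picture, the spokes reveal
# directional heterogeneity — a neighbouring vessel or airway in one
# section changes that section's profile while the others agree.

#' Build spokes normal to the lumen ellipse
#'
#' The area around the airway is divided into `n_sections` equal angular
#' sections (section 1 starts at polar angle 0, the +x direction, angles
#' increasing toward +y).  Within each section `n_spokes` rays start on
#' the ellipse boundary at angularly equispaced positions and extend
#' outward along the local ellipse normal with a fixed radial step.
#' Sample points outside the frame (minus a 2 px interpolation border)
#' are truncated.
#'
#' @param ellipse a [fit_ellipse()] result (or any list with `center`,
#'   `a`, `b`, `angle`).
#' @param frame_shape `c(rows, cols)` of the underlying frames.
#' @param pixel_size um/px.
#' @param n_sections number of angular sections (default 8).
#' @param n_spokes rays per section (default 7).
#' @param radial_step_um distance between samples along a ray (um);
#'   default `7 * pixel_size` (one strain-grid cell).
#' @param max_length_um maximum ray length (um), default 400.
#' @return data.frame of class `spoke_set`: `section`, `spoke`, `step`,
#'   `distance_um`, `x`, `y` (0-based px), `nx`, `ny` (outward unit
#'   normal), with the construction parameters as attributes.
#' @export
build_spokes <- function(ellipse, frame_shape, pixel_size,
                         n_sections = 8L, n_spokes = 7L,
                         radial_step_um = 7 * pixel_size,
                         max_length_um = 400) {
  if (n_sections < 1 || n_spokes < 1 || radial_step_um <= 0 ||
      max_length_um <= 0)
    stopf("spoke parameters must be positive")
  nr <- frame_shape[1]; nc <- frame_shape[2]
  if (ellipse$center[1] < 0 || ellipse$center[1] > nc - 1 ||
      ellipse$center[2] < 0 || ellipse$center[2] > nr - 1)
    stopf("lumen ellipse centre lies outside the frame")
  span <- 2 * pi / n_sections
  step_px <- radial_step_um / pixel_size
  n_steps <- floor(max_length_um / radial_step_um)
  rows <- list()
  for (s in seq_len(n_sections)) {
    for (k in seq_len(n_spokes)) {
      theta <- (s - 1) * span + (k - 0.5) * span / n_spokes
      bp <- .ellipse_boundary_point(ellipse, theta)
      steps <- 0:n_steps
      x <- bp$x + steps * step_px * bp$nx
      y <- bp$y + steps * step_px * bp$ny
      keep <- x >= 2 & x <= nc - 3 & y >= 2 & y <= nr - 3
      if (!any(keep)) next
      rows[[length(rows) + 1L]] <- data.frame(
        section = s, spoke = k, step = steps[keep],
        distance_um = steps[keep] * radial_step_um,
        x = x[keep], y = y[keep], nx = bp$nx, ny = bp$ny)
    }
  }
  if (length(rows) == 0L)
    stopf("no spoke sample points fall inside the frame")
  out <- do.call(rbind, rows)
  class(out) <- c("spoke_set", "data.frame")
  attr(out, "params") <- list(n_sections = n_sections, n_spokes = n_spokes,
                              radial_step_um = radial_step_um,
                              max_length_um = max_length_um,
                              pixel_size = pixel_size)
  attr(out, "ellipse") <- ellipse
  out
}

# boundary point of the ellipse in polar direction theta from its centre,
# with the outward unit normal there
.ellipse_boundary_point <- function(ellipse, theta) {
  ca <- cos(ellipse$angle); sa <- sin(ellipse$angle)
  dx <- cos(theta); dy <- sin(theta)
  # direction in the ellipse frame
  ex <- ca * dx + sa * dy; ey <- -sa * dx + ca * dy
  r <- 1 / sqrt((ex / ellipse$a)^2 + (ey / ellipse$b)^2)
  px <- ellipse$center[1] + r * dx
  py <- ellipse$center[2] + r * dy
  # gradient of the implicit form in the ellipse frame, rotated back
  gx_e <- r * ex / ellipse$a^2; gy_e <- r * ey / ellipse$b^2
  gx <- ca * gx_e - sa * gy_e; gy <- sa * gx_e + ca * gy_e
  gn <- sqrt(gx^2 + gy^2)
  list(x = px, y = py, nx = gx / gn, ny = gy / gn)
}

#' Section-averaged inward radial displacement along spokes
#'
#' Samples the displacement field bilinearly at every spoke point,
#' projects it onto the inward ray direction, and averages over the rays
#' of each section at each radial position, reporting the spread so the
#' within-section variability is visible.
#'
#' @param field a [displacement_field].
#' @param spokes a [build_spokes()] set.
#' @return data.frame: `section`, `distance_um`,
#'   `mean_displacement_um` (positive = toward the lumen),
#'   `sd_displacement_um`, `n`.
#' @export
spoke_displacement_profile <- function(field, spokes) {
  px <- attr(spokes, "params")$pixel_size
  s <- bilinear_sample(field, cbind(spokes$x, spokes$y), fill = "error")
  inward <- -(s$u * spokes$nx + s$v * spokes$ny) * px
  agg <- .aggregate_by(spokes$section, spokes$distance_um, inward)
  names(agg)[names(agg) == "mean"] <- "mean_displacement_um"
  names(agg)[names(agg) == "sd"] <- "sd_displacement_um"
  agg
}

#' Section-averaged principal strains along spokes
#'
#' At every spoke sample point, displacements at the four surrounding
#' stencil positions (x +/- h, y) and (x, y +/- h) are obtained by
#' bilinear interpolation, the deformation gradient by central
#' differences, and the Lagrangian strain tensor eigen-decomposed; the
#' major (radial) and minor (circumferential) eigenvalues are then
#' averaged over each section's rays at each radial position.  Sample
#' points whose stencil leaves the frame are dropped.
#'
#' @param field a [displacement_field].
#' @param spokes a [build_spokes()] set.
#' @param h stencil half-width in px (default 7).
#' @return data.frame: `section`, `distance_um`, `mean_major`,
#'   `mean_minor`, `sd_major`, `sd_minor`, `n`.
#' @export
spoke_strain_profile <- function(field, spokes, h = 7) {
  nr <- nrow(field$u); nc <- ncol(field$u)
  ok <- spokes$x - h >= 0 & spokes$x + h <= nc - 1 &
    spokes$y - h >= 0 & spokes$y + h <= nr - 1
  sp <- spokes[ok, ]
  ue <- function(xx, yy) bilinear_sample(field$u, xx, yy, fill = 0)
  ve <- function(xx, yy) bilinear_sample(field$v, xx, yy, fill = 0)
  F11 <- 1 + (ue(sp$x + h, sp$y) - ue(sp$x - h, sp$y)) / (2 * h)
  F12 <- (ue(sp$x, sp$y + h) - ue(sp$x, sp$y - h)) / (2 * h)
  F21 <- (ve(sp$x + h, sp$y) - ve(sp$x - h, sp$y)) / (2 * h)
  F22 <- 1 + (ve(sp$x, sp$y + h) - ve(sp$x, sp$y - h)) / (2 * h)
  E11 <- (F11^2 + F21^2 - 1) / 2
  E22 <- (F12^2 + F22^2 - 1) / 2
  E12 <- (F11 * F12 + F21 * F22) / 2
  disc <- sqrt((E11 - E22)^2 + 4 * E12^2)
  lp <- (E11 + E22 + disc) / 2
  lm <- (E11 + E22 - disc) / 2
  a_maj <- .aggregate_by(sp$section, sp$distance_um, lp)
  a_min <- .aggregate_by(sp$section, sp$distance_um, lm)
  data.frame(section = a_maj$section, distance_um = a_maj$distance_um,
             mean_major = a_maj$mean, mean_minor = a_min$mean,
             sd_major = a_maj$sd, sd_minor = a_min$sd, n = a_maj$n)
}

.aggregate_by <- function(section, distance, value) {
  key <- interaction(section, distance, drop = TRUE)
  mean_v <- tapply(value, key, mean)
  sd_v <- tapply(value, key, function(z) if (length(z) > 1) sd(z) else 0)
  n_v <- tapply(value, key, length)
  sec <- tapply(section, key, `[`, 1)
  dst <- tapply(distance, key, `[`, 1)
  out <- data.frame(section = as.integer(sec), distance_um = as.numeric(dst),
                    mean = as.numeric(mean_v), sd = as.numeric(sd_v),
                    n = as.integer(n_v))
  out[order(out$section, out$distance_um), , drop = FALSE]
}

#' Spokes strain kymographs over a movie
#'
#' Applies [spoke_strain_profile()] to a displacement field per frame and
#' stacks the per-section profiles over time.
#'
#' @param fields list of [displacement_field]s (one per analysed frame).
#' @param times acquisition times (s) of those frames.
#' @param spokes a [build_spokes()] set.
#' @param h stencil half-width (px).
#' @return long data.frame: `section`, `time_s`, `distance_um`,
#'   `mean_major`, `mean_minor`, `sd_major`, `sd_minor`, `n`.
#' @export
spoke_strain_kymograph <- function(fields, times, spokes, h = 7) {
  if (length(fields) != length(times))
    stopf("fields and times lengths differ")
  do.call(rbind, lapply(seq_along(fields), function(j) {
    p <- spoke_strain_profile(fields[[j]], spokes, h = h)
    cbind(section = p$section, time_s = times[j],
          p[, setdiff(names(p), "section"), drop = FALSE])
  }))
}

#' Export spoke geometry as JSON (for figure annotation)
#' @param spokes a [build_spokes()] set; @param path output path.
#' @return `path`, invisibly.
#' @export
write_spokes_json <- function(spokes, path) {
  par <- attr(spokes, "params")
  ell <- attr(spokes, "ellipse")
  obj <- list(params = par,
              ellipse = list(center = ell$center, a = ell$a, b = ell$b,
                             angle = ell$angle),
              rays = unclass(spokes[spokes$step == 0,
                                    c("section", "spoke", "x", "y",
                                      "nx", "ny")]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
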