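# Synthetic PCLS-like movies with exact analytic displacement and strain
# ground truth.  These stand in for microscope recordings: a speckle-
# textured annular "tissue" around a bright, smooth lumen, deformed by a
# prescribed contraction with closed-form Lagrangian strains.

#' Reproducible multi-scale speckle texture
#'
#' A sum of band-limited Gaussian noise octaves with the finest
#' correlation length of roughly `feature_scale` pixels and weaker
#' components at 4x and 16x that scale, percentile-stretched to `[0, 1]`.
#' Bright-field tissue images carry structure at many scales (fine
#' speckle, alveolar walls, vessels); the coarse octaves matter for
#' optical flow because they are what survives pyramid downsampling and
#' anchors large motions.
#'
#' @param shape `c(rows, cols)` in pixels.
#' @param feature_scale finest (dominant) autocorrelation length in px.
#' @param seed integer seed; the same seed always yields the same texture.
#' @param octave_weights relative amplitudes of the octaves at
#'   `feature_scale * c(1, 4, 16)`.
#' @return matrix in `[0, 1]`.
#' @export
make_speckle_texture <- function(shape, feature_scale = 4, seed = 1L,
                                 octave_weights = c(1, 0.5, 0.3)) {
  if (any(shape <= 0)) stopf("shape must be positive")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  s <- 0
  for (k in seq_along(octave_weights)) {
    w <- matrix(rnorm(prod(shape)), shape[1], shape[2])
    sig <- max(feature_scale * 4^(k - 1) / 2, 0.5)
    if (2 * ceiling(3 * sig) + 1 > min(shape)) next  # octave exceeds frame
    band <- .gsmooth(w, sig)
    # normalise each octave to unit variance before weighting
    s <- s + octave_weights[k] * band / sd(band)
  }
  stretch_contrast(s, 0.5, 99.5)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Prescribed annular contraction with analytic strain
#'
#' Defines the deformation of tissue around a circular airway lumen of
#' reference (relaxed) radius `R0_um` whose contracted radius follows the
#' trajectory `r0_t_um` over time.  Two kinematic modes:
#' \describe{
#'   \item{`"area-preserving"`}{`r(R) = sqrt(R^2 - R0^2 + r0^2)` for
#'     `R >= R0`: in-plane incompressible tissue, the default because lung
#'     parenchyma is nearly incompressible at these scales and the
#'     Lagrangian strains have closed forms
#'     `E_rr = ((dr/dR)^2 - 1)/2` with `dr/dR = R/r`, and
#'     `E_tt = ((r/R)^2 - 1)/2`.}
#'   \item{`"exponential-decay"`}{`r(R) = R + (r0 - R0) exp(-(R - R0)/L)`:
#'     wall displacement decaying into the parenchyma with length `L`,
#'     emulating the observed drop of strain away from the lumen.}
#' }
#' Inside the lumen (`R < R0`) the map is extended linearly
#' (`r = R r0/R0`) so it is continuous on the whole plane; tissue never
#' lives there.
#'
#' @param R0_um reference lumen radius (um).
#' @param r0_t_um numeric vector of contracted lumen radii (um), one per
#'   frame; the first entry should equal `R0_um` so the first deformation
#'   map is the identity.  All entries must satisfy `0 < r0 <= R0`.
#' @param mode `"area-preserving"` or `"exponential-decay"`.
#' @param decay_length_um decay length `L` (um) for the exponential mode.
#' @param inclusion optional stiff circular inclusion which does not deform
#'   (emulates e.g. a neighbouring vessel): a list with `center_um`
#'   (c(x, y), um, relative to the airway centre), `radius_um` and
#'   `blend_um` (smooth transition width).
#' @return object of class `synthetic_truth` with closed-form accessors
#'   `forward_radius(R, i)`, `inverse_radius(r, i)`, `E_rr(R, i)`,
#'   `E_tt(R, i)` (all um, frame index `i`), and `displacement(x, y, i,
#'   center_px, pixel_size)` giving per-pixel (u, v).
#' @export
annulus_contraction <- function(R0_um, r0_t_um,
                                mode = c("area-preserving",
                                         "exponential-decay"),
                                decay_length_um = 60,
                                inclusion = NULL) {
  mode <- match.arg(mode)
  if (any(r0_t_um > R0_um + 1e-9) || any(r0_t_um <= 0))
    stopf("need 0 < r0(t) <= R0 for every frame")
  truth <- list(R0_um = R0_um, r0_t_um = as.numeric(r0_t_um), mode = mode,
                decay_length_um = decay_length_um, inclusion = inclusion)
  class(truth) <- "synthetic_truth"
  truth
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %s annulus, R0 = %g um, r0 in [%g, %g] um, %d frames%s\n",
              x$mode, x$R0_um, min(x$r0_t_um), max(x$r0_t_um),
              length(x$r0_t_um),
              if (is.null(x$inclusion)) "" else ", with stiff inclusion"))
  invisible(x)
}

# deformed radius r as a function of reference radius R (um), both modes,
# linear extension inside the lumen
.fwd_radius <- function(truth, R, i) {
  r0 <- truth$r0_t_um[i]; R0 <- truth$R0_um
  out <- numeric(length(R))
  inside <- R < R0
  out[inside] <- R[inside] * r0 / R0
  Ro <- R[!inside]
  out[!inside] <- switch(truth$mode,
    "area-preserving" = sqrt(Ro^2 - R0^2 + r0^2),
    "exponential-decay" = Ro + (r0 - R0) *
      exp(-(Ro - R0) / truth$decay_length_um))
  out
}

# reference radius R from deformed radius r; exponential mode is inverted
# by Newton iteration (the map is monotone for (R0 - r0)/L < 1)
.inv_radius <- function(truth, r, i) {
  r0 <- truth$r0_t_um[i]; R0 <- truth$R0_um
  out <- numeric(length(r))
  inside <- r < r0
  out[inside] <- r[inside] * R0 / r0
  ro <- r[!inside]
  if (truth$mode == "area-preserving") {
    out[!inside] <- sqrt(ro^2 - r0^2 + R0^2)
  } else {
    L <- truth$decay_length_um
    R <- ro - (r0 - R0)            # initial guess: undo full displacement
    for (k in 1:50) {
      f <- R + (r0 - R0) * exp(-(R - R0) / L) - ro
      fp <- 1 - (r0 - R0) / L * exp(-(R - R0) / L)
      step <- f / fp
      R <- R - step
      if (max(abs(step)) < 1e-10) break
    }
    out[!inside] <- R
  }
  out
}

#' @rdname annulus_contraction
#' @param truth a `synthetic_truth`
#' @param R_um reference radius (um)
#' @param i frame index
#' @export
truth_E_rr <- function(truth, R_um, i) {
  r <- .fwd_radius(truth, R_um, i)
  drdR <- switch(truth$mode,
    "area-preserving" = ifelse(R_um < truth$R0_um,
                               truth$r0_t_um[i] / truth$R0_um, R_um / r),
    "exponential-decay" = ifelse(R_um < truth$R0_um,
      truth$r0_t_um[i] / truth$R0_um,
      1 - (truth$r0_t_um[i] - truth$R0_um) / truth$decay_length_um *
        exp(-(R_um - truth$R0_um) / truth$decay_length_um)))
  (drdR^2 - 1) / 2
}

#' @rdname annulus_contraction
#' @export
truth_E_tt <- function(truth, R_um, i) {
  r <- .fwd_radius(truth, R_um, i)
  ratio <- ifelse(R_um > 0, r / R_um, truth$r0_t_um[i] / truth$R0_um)
  (ratio^2 - 1) / 2
}

#' Analytic displacement of the annulus truth at reference pixel positions
#'
#' @param truth a `synthetic_truth`
#' @param x,y 0-based reference pixel coordinates (any shape)
#' @param i frame index
#' @param center_px airway centre `c(x, y)` in px
#' @param pixel_size um/px
#' @return list with components `u`, `v` in px (same shape as `x`)
#' @export
truth_displacement <- function(truth, x, y, i, center_px, pixel_size) {
  dx <- (x - center_px[1]) * pixel_size
  dy <- (y - center_px[2]) * pixel_size
  R <- sqrt(dx^2 + dy^2)
  r <- .fwd_radius(truth, R, i)
  scale <- ifelse(R > 0, r / R, 1)
  u_um <- dx * (scale - 1)
  v_um <- dy * (scale - 1)
  if (!is.null(truth$inclusion)) {
    w <- .inclusion_weight(truth$inclusion,
                           dx - truth$inclusion$center_um[1],
                           dy - truth$inclusion$center_um[2])
    u_um <- (1 - w) * u_um
    v_um <- (1 - w) * v_um
  }
  list(u = u_um / pixel_size, v = v_um / pixel_size)
}

# blending weight: 1 inside the inclusion, cosine falloff to 0 over blend
.inclusion_weight <- function(inc, dx_um, dy_um) {
  d <- sqrt(dx_um^2 + dy_um^2)
  w <- numeric(length(d))
  w[d <= inc$radius_um] <- 1
  band <- d > inc$radius_um & d < inc$radius_um + inc$blend_um
  w[band] <- 0.5 * (1 + cos(pi * (d[band] - inc$radius_um) / inc$blend_um))
  array(w, dim(dx_um) %||% length(dx_um))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a synthetic contraction movie
#'
#' Produces a [frame_sequence] by backward-warping a reference speckle
#' texture through the inverse deformation map of `truth` at each frame.
#' The lumen is rendered bright and smooth, the region beyond the tissue
#' outer radius as smooth agarose-like background, and optional Gaussian
#' noise is added.  The returned sequence carries a `truth_bundle`
#' attribute with the truth object, geometry and the reference tissue
#' footprint.
#'
#' @param texture reference texture matrix in `[0, 1]` (tissue speckle).
#' @param truth a [annulus_contraction()] truth whose `r0_t_um` has one
#'   entry per requested frame.
#' @param times acquisition times (s), same length as `truth$r0_t_um`.
#' @param pixel_size um/px (default 1.15, the acquisition calibration).
#' @param center_px airway centre in px (default frame centre).
#' @param tissue_outer_um outer radius of the textured tissue annulus (um).
#' @param noise_sd additive Gaussian noise standard deviation (intensity
#'   units; default 0.01).
#' @param lumen_intensity,background_intensity intensities of the smooth
#'   lumen interior and the out-of-tissue background.
#' @param texture_low,texture_high intensity range the tissue texture is
#'   mapped into (darker than lumen/background, as in bright-field PCLS).
#' @param seed seed for the rendering noise.
#' @return a [frame_sequence] with attribute `truth_bundle`.
#' @export
render_sequence <- function(texture, truth, times, pixel_size = 1.15,
                            center_px = NULL, tissue_outer_um = 240,
                            noise_sd = 0.01, lumen_intensity = 0.95,
                            background_intensity = 0.85,
                            texture_low = 0.05, texture_high = 0.80,
                            seed = 1L) {
  nt <- length(truth$r0_t_um)
  if (length(times) != nt)
    stopf("times length (%d) != truth frames (%d)", length(times), nt)
  shp <- dim(texture)
  if (is.null(center_px)) center_px <- c((shp[2] - 1) / 2, (shp[1] - 1) / 2)
  tex <- texture_low + texture * (texture_high - texture_low)

  xg <- matrix(rep(0:(shp[2] - 1), each = shp[1]), shp[1], shp[2])
  yg <- matrix(rep(0:(shp[1] - 1), times = shp[2]), shp[1], shp[2])
  dx <- (xg - center_px[1]) * pixel_size
  dy <- (yg - center_px[2]) * pixel_size
  r_um <- sqrt(dx^2 + dy^2)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  frames <- vector("list", nt)
  for (i in seq_len(nt)) {
    R_um <- .inv_radius(truth, r_um, i)
    if (!is.null(truth$inclusion)) {
      # the inclusion does not move: blend the inverse map toward identity
      w <- .inclusion_weight(truth$inclusion,
                             dx - truth$inclusion$center_um[1],
                             dy - truth$inclusion$center_um[2])
      R_um <- w * r_um + (1 - w) * R_um
    }
    scale <- ifelse(r_um > 0, R_um / r_um, 1)
    Xs <- center_px[1] + dx * scale / pixel_size
    Ys <- center_px[2] + dy * scale / pixel_size
    f <- bilinear_sample(tex, Xs, Ys, fill = background_intensity)
    lum <- r_um < truth$r0_t_um[i]
    bg <- R_um > tissue_outer_um
    f[bg] <- background_intensity
    f[lum] <- lumen_intensity
    if (noise_sd > 0)
      f <- f + matrix(rnorm(length(f), sd = noise_sd), shp[1], shp[2])
    frames[[i]] <- pmin(pmax(f, 0), 1)
  }
  seqn <- frame_sequence(frames, pixel_size = pixel_size, times = times,
                         reference_index = 1L)
  footprint <- r_um >= truth$R0_um & r_um <= tissue_outer_um
  if (!is.null(truth$inclusion)) {
    # inclusion interior is also tissue (it is rendered with texture)
    inc_r <- sqrt((dx - truth$inclusion$center_um[1])^2 +
                  (dy - truth$inclusion$center_um[2])^2)
    footprint <- footprint | (inc_r <= truth$inclusion$radius_um &
                              r_um >= truth$R0_um)
  }
  attr(seqn, "truth_bundle") <- list(
    truth = truth, center_px = center_px, pixel_size = pixel_size,
    tissue_outer_um = tissue_outer_um, footprint = footprint)
  seqn
}

# extend a texture by mirror reflection so that warped frames can sample
# genuine content beyond the field of view (tissue does not end at the
# image border in a real recording)
.mirror_pad <- function(m, pad) {
  nr <- nrow(m); nc <- ncol(m)
  ridx <- c(rev(seq_len(min(pad, nr))), seq_len(nr),
            nr - seq_len(min(pad, nr)) + 1)
  cidx <- c(rev(seq_len(min(pad, nc))), seq_len(nc),
            nc - seq_len(min(pad, nc)) + 1)
  m[ridx, cidx]
}

#' Rigid-motion movie with zero true strain
#'
#' Translates and rotates a texture rigidly; the true displacement field is
#' nonzero but the true Lagrangian strain is identically zero, exercising
#' the property that whole-slice motion affects displacements but not
#' strains.  Motion is ramped linearly from zero (frame 1) to the full
#' `(dx, dy, theta)` (last frame), about the frame centre.
#'
#' @param texture reference texture matrix.
#' @param dx_px,dy_px final translation (px).
#' @param theta_deg final rotation (degrees, counterclockwise in the
#'   x-right / y-down pixel frame).
#' @param n_frames number of frames (>= 2).
#' @param pixel_size um/px; `frame_interval` s.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed rendering noise seed.
#' @inheritParams render_sequence
#' @return [frame_sequence] with a `truth_bundle` attribute providing
#'   `displacement(x, y, i)` in px.
#' @export
rigid_motion_sequence <- function(texture, dx_px = 0, dy_px = 0,
                                  theta_deg = 0, n_frames = 2L,
                                  pixel_size = 1.15, frame_interval = 2,
                                  noise_sd = 0.01, seed = 1L) {
  shp <- dim(texture)
  center <- c((shp[2] - 1) / 2, (shp[1] - 1) / 2)
  # content moving into the field of view comes from the mirror-padded
  # texture, as tissue outside the frame would in a real recording
  pad <- ceiling(abs(dx_px) + abs(dy_px) +
                   sin(abs(theta_deg) * pi / 180) * max(shp)) + 4L
  texp <- .mirror_pad(texture, pad)
  xg <- matrix(rep(0:(shp[2] - 1), each = shp[1]), shp[1], shp[2])
  yg <- matrix(rep(0:(shp[1] - 1), times = shp[2]), shp[1], shp[2])
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  frames <- vector("list", n_frames)
  fracs <- seq(0, 1, length.out = n_frames)
  for (i in seq_len(n_frames)) {
    th <- fracs[i] * theta_deg * pi / 180
    tx <- fracs[i] * dx_px; ty <- fracs[i] * dy_px
    # inverse map: undo translation then rotation
    xr <- xg - center[1] - tx; yr <- yg - center[2] - ty
    Xs <- center[1] + cos(th) * xr + sin(th) * yr
    Ys <- center[2] - sin(th) * xr + cos(th) * yr
    f <- bilinear_sample(texp, Xs + pad, Ys + pad, fill = 0.5)
    if (noise_sd > 0)
      f <- f + matrix(rnorm(length(f), sd = noise_sd), shp[1], shp[2])
    frames[[i]] <- pmin(pmax(f, 0), 1)
  }
  seqn <- frame_sequence(frames, pixel_size = pixel_size,
                         frame_interval = frame_interval,
                         reference_index = 1L)
  disp <- function(x, y, i) {
    th <- fracs[i] * theta_deg * pi / 180
    tx <- fracs[i] * dx_px; ty <- fracs[i] * dy_px
    xr <- x - center[1]; yr <- y - center[2]
    list(u = center[1] + cos(th) * xr - sin(th) * yr + tx - x,
         v = center[2] + sin(th) * xr + cos(th) * yr + ty - y)
  }
  attr(seqn, "truth_bundle") <- list(kind = "rigid", center_px = center,
                                     pixel_size = pixel_size,
                                     displacement = disp)
  seqn
}

#' Uniform-stretch movie with known constant strain
#'
#' Stretches the texture by factors `(alpha_x, alpha_y)` about the frame
#' centre over `n_frames` linear steps.  True Lagrangian strain is spatially
#' uniform: `E11 = (alpha_x^2 - 1)/2`, `E22 = (alpha_y^2 - 1)/2`, `E12 = 0`.
#'
#' @inheritParams rigid_motion_sequence
#' @param alpha_x,alpha_y final stretch ratios along x and y.
#' @return [frame_sequence] with `truth_bundle` attribute.
#' @export
stretch_sequence <- function(texture, alpha_x = 1.1, alpha_y = 1,
                             n_frames = 2L, pixel_size = 1.15,
                             frame_interval = 2, noise_sd = 0.01,
                             seed = 1L) {
  shp <- dim(texture)
  center <- c((shp[2] - 1) / 2, (shp[1] - 1) / 2)
  xg <- matrix(rep(0:(shp[2] - 1), each = shp[1]), shp[1], shp[2])
  yg <- matrix(rep(0:(shp[1] - 1), times = shp[2]), shp[1], shp[2])
  pad <- ceiling(max(shp) * max(1 / min(alpha_x, alpha_y, 1) - 1, 0)) + 4L
  texp <- .mirror_pad(texture, pad)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  frames <- vector("list", n_frames)
  fracs <- seq(0, 1, length.out = n_frames)
  for (i in seq_len(n_frames)) {
    ax <- 1 + fracs[i] * (alpha_x - 1); ay <- 1 + fracs[i] * (alpha_y - 1)
    Xs <- center[1] + (xg - center[1]) / ax
    Ys <- center[2] + (yg - center[2]) / ay
    f <- bilinear_sample(texp, Xs + pad, Ys + pad, fill = 0.5)
    if (noise_sd > 0)
      f <- f + matrix(rnorm(length(f), sd = noise_sd), shp[1], shp[2])
    frames[[i]] <- pmin(pmax(f, 0), 1)
  }
  seqn <- frame_sequence(frames, pixel_size = pixel_size,
                         frame_interval = frame_interval,
                         reference_index = 1L)
  disp <- function(x, y, i) {
    ax <- 1 + fracs[i] * (alpha_x - 1); ay <- 1 + fracs[i] * (alpha_y - 1)
    list(u = (x - center[1]) * (ax - 1), v = (y - center[2]) * (ay - 1))
  }
  attr(seqn, "truth_bundle") <- list(kind = "stretch", center_px = center,
                                     displacement = disp,
                                     alpha = c(alpha_x, alpha_y))
  seqn
}

#' Lumen radius trajectory mimicking a contraction/relaxation experiment
#'
#' Logistic fall from the relaxed radius `R0_um` toward `r0_min_um` during
#' the agonist phase, then exponential recovery toward `R0_um` after the
#' relaxant is added at `t_relax_s`.  Mirrors the classic airway-caliber
#' curve: an initial steep phase of fast narrowing followed by a slower
#' asymptotic phase, then dilation.
#'
#' @param times time points (s).
#' @param R0_um relaxed lumen radius (um).
#' @param r0_min_um fully contracted radius (um).
#' @param t_relax_s time the relaxant is added (s; default 600).
#' @param t_half_s logistic midpoint of the contraction (s).
#' @param tau_contract_s logistic time constant of the contraction (s).
#' @param tau_relax_s exponential recovery time constant (s).
#' @return numeric vector of radii (um), starting at `R0_um`.
#' @export
r0_trajectory <- function(times, R0_um = 100, r0_min_um = 80,
                          t_relax_s = 600, t_half_s = 150,
                          tau_contract_s = 60, tau_relax_s = 120) {
  logis <- function(t) 1 / (1 + exp(-(t - t_half_s) / tau_contract_s))
  # normalise so the trajectory starts exactly at R0
  l0 <- logis(0)
  con <- pmin(pmax((logis(times) - l0) / (1 - l0), 0), 1)
  r <- R0_um - (R0_um - r0_min_um) * con
  post <- times > t_relax_s
  if (any(post)) {
    r_at <- R0_um - (R0_um - r0_min_um) *
      pmin(pmax((logis(t_relax_s) - l0) / (1 - l0), 0), 1)
    r[post] <- R0_um - (R0_um - r_at) *
      exp(-(times[post] - t_relax_s) / tau_relax_s)
  }
  r
}
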