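# Shared synthetic fixtures, built once per test run and cached.  The
# flow-based fixtures are the expensive part (seconds each), so every
# test file that needs e.g. the contracted-annulus displacement field
# reuses the same computation.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, create) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, create(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# -- canonical contraction experiment: lumen radius 100 -> 80 um,
#    area-preserving kinematics, calibration 1.15 um/px ------------------

ann_seq <- function() fixture("ann_seq", function() {
  simulate_scenario("annulus", seed = 11L, shape = c(440L, 440L),
                    n_frames = 2L)
})

ann_truth <- function() attr(ann_seq(), "truth_bundle")

ann_flow <- function() fixture("ann_flow", function() {
  estimate_displacement(ann_seq(), 2L)
})

ann_lumen <- function() fixture("ann_lumen", function() {
  m <- segment_lumen(ann_seq()$frames[[1]])
  list(mask = m, ellipse = fit_ellipse(m))
})

ann_strain <- function() fixture("ann_strain", function() {
  strain_field(ann_flow(), grid_spacing = 7, h = 7,
               mask = tissue_mask(ann_seq()$frames[[1]]),
               lumen_center = ann_lumen()$ellipse$center)
})

# -- rigid and affine movies -------------------------------------------

trans_seq <- function() fixture("trans_seq", function() {
  simulate_scenario("rigid", seed = 7L, shape = c(256L, 256L),
                    dx_px = 3, dy_px = -2, theta_deg = 0, n_frames = 2L)
})

rigid_seq <- function() fixture("rigid_seq", function() {
  simulate_scenario("rigid", seed = 7L, shape = c(256L, 256L),
                    dx_px = 3, dy_px = -2, theta_deg = 10, n_frames = 2L)
})

stretch_seq <- function() fixture("stretch_seq", function() {
  simulate_scenario("stretch", seed = 7L, shape = c(256L, 256L),
                    alpha_x = 1.1, n_frames = 2L)
})

rigid_flow <- function() fixture("rigid_flow", function() {
  estimate_displacement(rigid_seq(), 2L)
})

stretch_flow <- function() fixture("stretch_flow", function() {
  estimate_displacement(stretch_seq(), 2L)
})

# interior region where the full flow window has valid (non-occluded)
# support: excludes max displacement + flow window + strain stencil
interior_margin <- function(seq, extra = 0) {
  tb <- attr(seq, "truth_bundle")
  shp <- frame_shape(seq)
  xg <- matrix(rep(0:(shp[2] - 1), each = shp[1]), shp[1], shp[2])
  yg <- matrix(rep(0:(shp[1] - 1), times = shp[2]), shp[1], shp[2])
  td <- if (!is.null(tb$truth))
    truth_displacement(tb$truth, xg, yg, length(seq$frames),
                       tb$center_px, seq$pixel_size)
  else tb$displacement(xg, yg, length(seq$frames))
  ceiling(max(sqrt(td$u^2 + td$v^2)) + 15 + extra)
}

# analytic displacement field of a fixture at frame i (px units)
truth_field <- function(seq, i = length(seq$frames)) {
  tb <- attr(seq, "truth_bundle")
  shp <- frame_shape(seq)
  xg <- matrix(rep(0:(shp[2] - 1), each = shp[1]), shp[1], shp[2])
  yg <- matrix(rep(0:(shp[1] - 1), times = shp[2]), shp[1], shp[2])
  td <- if (!is.null(tb$truth))
    truth_displacement(tb$truth, xg, yg, i, tb$center_px, seq$pixel_size)
  else tb$displacement(xg, yg, i)
  displacement_field(td$u, td$v, 1L, i, seq$pixel_size)
}

# small movie used by the CLI tests (fast: ~2 s of flow per frame)
cli_movie_dir <- function() fixture("cli_movie_dir", function() {
  d <- file.path(tempdir(), "pclstrain-cli-movie")
  cmd_simulate("annulus", out_dir = d, seed = 21L, shape = c(256L, 256L),
               n_frames = 3L, R0_um = 60, r0_um = 48,
               tissue_outer_um = 120)
  d
})
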