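# Spokes construction and section-averaged displacement / strain.

circle_ellipse <- function(cx = 127.5, cy = 127.5, r = 40) {
  structure(list(center = c(cx, cy), a = r, b = r, angle = 0),
            class = "lumen_ellipse")
}

test_that("default spokes form 8 sections x 7 rays starting on the boundary", {
  spk <- build_spokes(circle_ellipse(), c(256, 256), pixel_size = 1,
                      radial_step_um = 7, max_length_um = 60)
  rays <- unique(spk[, c("section", "spoke")])
  expect_equal(nrow(rays), 56L)
  expect_equal(sort(unique(spk$section)), 1:8)
  starts <- spk[spk$step == 0, ]
  r0 <- sqrt((starts$x - 127.5)^2 + (starts$y - 127.5)^2)
  expect_true(all(abs(r0 - 40) < 1e-9))
  # constant spacing along each ray
  one <- spk[spk$section == 3 & spk$spoke == 2, ]
  gaps <- sqrt(diff(one$x)^2 + diff(one$y)^2)
  expect_true(all(abs(gaps - 7) < 1e-9))
  expect_true(all(abs(diff(one$distance_um) - 7) < 1e-9))
})

test_that("rays are truncated at the frame boundary", {
  spk <- build_spokes(circle_ellipse(cx = 20, cy = 20, r = 15),
                      c(120, 120), pixel_size = 1,
                      radial_step_um = 5, max_length_um = 500)
  expect_true(all(spk$x >= 2 & spk$x <= 117))
  expect_true(all(spk$y >= 2 & spk$y <= 117))
  expect_error(build_spokes(circle_ellipse(cx = -50, cy = -50), c(64, 64),
                            pixel_size = 1), "outside")
})

test_that("zero displacement gives zero spoke profiles", {
  z <- matrix(0, 256, 256)
  fld <- displacement_field(z, z, pixel_size = 1.15)
  spk <- build_spokes(circle_ellipse(), c(256, 256), pixel_size = 1.15,
                      radial_step_um = 8, max_length_um = 80)
  dp <- spoke_displacement_profile(fld, spk)
  expect_true(all(dp$mean_displacement_um == 0))
  expect_true(all(dp$sd_displacement_um == 0))
  sp <- spoke_strain_profile(fld, spk)
  expect_true(all(sp$mean_major == 0) && all(sp$mean_minor == 0))
})

test_that("uniform stretch yields uniform spoke strain in every section", {
  n <- 256
  alpha <- 1.1
  xg <- matrix(rep(0:(n - 1), each = n), n, n)
  fld <- displacement_field((alpha - 1) * xg, matrix(0, n, n),
                            pixel_size = 1)
  spk <- build_spokes(circle_ellipse(), c(n, n), pixel_size = 1,
                      radial_step_um = 7, max_length_um = 70)
  sp <- spoke_strain_profile(fld, spk, h = 7)
  expect_true(all(abs(sp$mean_major - 0.105) < 1e-3))
})

test_that("axisymmetric contraction: sections agree and match the truth", {
  sq <- ann_seq()
  tb <- ann_truth()
  truth <- tb$truth
  px <- sq$pixel_size
  fld <- ann_flow()
  spk <- build_spokes(ann_lumen()$ellipse, frame_shape(sq), px)

  dp <- spoke_displacement_profile(fld, spk)
  wall <- dp[dp$distance_um == 0, ]
  # inward wall displacement approx R0 - r0 = 20 um in all 8 sections
  expect_equal(nrow(wall), 8L)
  expect_true(all(abs(wall$mean_displacement_um - 20) < 1))
  # all sections' displacement profiles agree within 5% of the peak
  # (within the textured tissue annulus; beyond its outer radius there is
  # no texture to track)
  dtis <- dp[dp$distance_um <= 110, ]
  peak_disp <- max(dtis$mean_displacement_um)
  spread <- tapply(dtis$mean_displacement_um, dtis$distance_um,
                   function(z) diff(range(z)))
  expect_lt(max(spread), 0.05 * peak_disp)

  # strains along spokes match the closed forms (sample points whose
  # stencil sits fully in textured tissue, i.e. beyond the first step)
  sp <- spoke_strain_profile(fld, spk, h = 7)
  sub <- sp[sp$distance_um >= 8 & sp$distance_um <= 120, ]
  Rt <- truth$R0_um + sub$distance_um
  peak <- truth_E_rr(truth, truth$R0_um, 2)
  expect_lt(max(abs(sub$mean_major - truth_E_rr(truth, Rt, 2))),
            0.15 * peak)
  expect_lt(max(abs(sub$mean_minor - truth_E_tt(truth, Rt, 2))),
            0.15 * peak)
})

test_that("section SD shrinks with more spokes on a smooth field", {
  sq <- ann_seq()
  px <- sq$pixel_size
  fld <- ann_flow()
  sd_at <- function(nspokes) {
    spk <- build_spokes(ann_lumen()$ellipse, frame_shape(sq), px,
                        n_spokes = nspokes)
    dp <- spoke_displacement_profile(fld, spk)
    mean(dp$sd_displacement_um[dp$distance_um <= 60], na.rm = TRUE)
  }
  s3 <- sd_at(3); s12 <- sd_at(12)
  expect_gte(s3, 0)
  # averaging over more rays cannot inflate the within-section spread much
  expect_lt(s12, 1.5 * s3)
})

test_that("a stiff inclusion makes exactly its section deviate", {
  sq <- fixture("het_seq", function() {
    simulate_scenario("heterogeneous", seed = 3L, n_frames = 2L)
  })
  fld <- fixture("het_flow", function() estimate_displacement(sq, 2))
  ell <- fit_ellipse(segment_lumen(sq$frames[[1]]))
  spk <- build_spokes(ell, frame_shape(sq), sq$pixel_size)
  sp <- spoke_strain_profile(fld, spk, 7)
  sub <- sp[sp$distance_um >= 8 & sp$distance_um <= 150, ]
  per_sec <- tapply(abs(sub$mean_major), sub$section, mean)
  # the inclusion is centred in section 1
  others <- per_sec[-1]
  expect_gt(abs(per_sec[1] - mean(others)), 3 * sd(others))
})

test_that("section averages agree with the circumferential bin averages", {
  # axisymmetric field: the mean over all sections' spoke profiles at a
  # given distance matches the distance-binned circumferential average
  sq <- ann_seq()
  px <- sq$pixel_size
  fld <- ann_flow()
  spk <- build_spokes(ann_lumen()$ellipse, frame_shape(sq), px,
                      radial_step_um = 7.5, max_length_um = 90)
  sp <- spoke_strain_profile(fld, spk, 7)
  prof <- bin_average(ann_strain(), distance_map(ann_lumen()$mask, px), 15)
  for (k in 2:6) {
    d <- 15 * (k - 1) + 7.5            # spoke sample at the bin centre
    spoke_mean <- mean(sp$mean_major[abs(sp$distance_um - d) < 1e-9])
    expect_lt(abs(spoke_mean - prof$mean_major[k]),
              0.15 * max(abs(prof$mean_major), na.rm = TRUE))
  }
})
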