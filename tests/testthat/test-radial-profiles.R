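# Distance maps, distance-binned strain averages, kymographs.

test_that("the distance map is the exact Euclidean transform in um", {
  m <- matrix(FALSE, 20, 20)
  m[8:12, 8:12] <- TRUE
  d <- distance_map(m, pixel_size = 1.15)
  expect_equal(d[10, 10], 0)                      # inside the lumen
  expect_equal(d[10, 13], 1 * 1.15)               # 4-adjacent pixel
  expect_equal(d[13, 13], sqrt(2) * 1.15)         # diagonal neighbour
  expect_error(distance_map(matrix(FALSE, 5, 5), 1), "empty")
})

test_that("distance transform matches brute force on random masks", {
  set.seed(123)
  for (rep in 1:5) {
    n <- sample(16:64, 1)
    mask <- matrix(runif(n * n) < 0.04, n, n)
    if (!any(mask)) mask[sample(n, 1), sample(n, 1)] <- TRUE
    d <- distance_map(mask, pixel_size = 1)
    idx <- which(mask, arr.ind = TRUE)
    rows <- matrix(rep(1:n, n), n, n)
    cols <- t(rows)
    bf <- matrix(Inf, n, n)
    for (k in seq_len(nrow(idx)))
      bf <- pmin(bf, sqrt((rows - idx[k, 1])^2 + (cols - idx[k, 2])^2))
    expect_equal(d, bf)
  }
})

test_that("circular-lumen distances follow disc geometry", {
  n <- 101
  xg <- matrix(rep(0:(n - 1), each = n), n, n)
  yg <- matrix(rep(0:(n - 1), times = n), n, n)
  r <- sqrt((xg - 50)^2 + (yg - 50)^2)
  mask <- r <= 20
  d <- distance_map(mask, pixel_size = 2)
  outside <- r > 21 & r < 48
  expect_true(all(abs(d[outside] - (r[outside] - 20) * 2) <= 2))
})

uniform_strain_field <- function(lam_major = 0.2, n = 120) {
  # analytic displacement with constant strain: u = alpha x with
  # (alpha^2 + 2 alpha)/2 ... easier to build from the stretch ratio
  alpha <- sqrt(1 + 2 * lam_major) - 1
  xg <- matrix(rep(0:(n - 1), each = n), n, n)
  fld <- displacement_field(alpha * xg, matrix(0, n, n), pixel_size = 1)
  strain_field(fld, 7, 7, lumen_center = c(0, 0))
}

test_that("bin averages are arithmetic means over included points", {
  sf <- uniform_strain_field(0.2)
  mask <- matrix(TRUE, 120, 120)
  mask[1:60, ] <- TRUE
  dmap <- distance_map(matrix(c(TRUE, rep(FALSE, 120 * 120 - 1)), 120, 120),
                       pixel_size = 1)
  prof <- bin_average(sf, dmap, bin_width = 15)
  nonempty <- !is.na(prof$mean_major)
  expect_true(all(abs(prof$mean_major[nonempty] - 0.2) < 1e-9))
  # count-weighted mean over bins equals the global mean (conservation)
  sfd <- as.data.frame(sf)
  expect_equal(sum(prof$mean_major[nonempty] * prof$n[nonempty]) /
                 sum(prof$n[nonempty]),
               mean(sfd$lambda_major), tolerance = 1e-12)
})

test_that("a bin holding exactly two points averages them", {
  # minimal hand-built strain field: two grid points, strains 0.1 and 0.3
  sf <- structure(list(
    lambda_major = matrix(c(0.1, 0.3), 1, 2),
    lambda_minor = matrix(c(-0.05, -0.15), 1, 2),
    evec_x = matrix(1, 1, 2), evec_y = matrix(0, 1, 2),
    on_tissue = matrix(TRUE, 1, 2),
    grid_x = c(7, 14), grid_y = 7, spacing = 7L, h = 7L,
    pixel_size = 1, lumen_center = c(0, 0)), class = "strain_field")
  lum <- matrix(FALSE, 30, 30); lum[8, 8] <- TRUE
  prof <- bin_average(sf, distance_map(lum, 1), bin_width = 15)
  expect_equal(prof$mean_major[prof$n == 2], 0.2)
  expect_equal(prof$mean_minor[prof$n == 2], -0.1)
})

test_that("masked-out points are excluded, not averaged as zeros", {
  n <- 120
  alpha <- sqrt(1.4) - 1
  xg <- matrix(rep(0:(n - 1), each = n), n, n)
  fld <- displacement_field(alpha * xg, matrix(0, n, n))
  mask <- matrix(FALSE, n, n); mask[, 1:60] <- TRUE   # left half tissue
  sf <- strain_field(fld, 7, 7, mask = mask, lumen_center = c(0, 0))
  lum <- matrix(FALSE, n, n); lum[55:65, 55:65] <- TRUE
  prof <- bin_average(sf, distance_map(lum, 1), bin_width = 15)
  nonempty <- !is.na(prof$mean_major) & prof$n > 0
  expect_true(all(abs(prof$mean_major[nonempty] - 0.2) < 1e-9))
})

test_that("annulus wall-bin averages match the binned closed forms", {
  sf <- ann_strain()
  tb <- ann_truth()
  truth <- tb$truth
  px <- ann_seq()$pixel_size
  dmap <- distance_map(ann_lumen()$mask, px)
  prof <- bin_average(sf, dmap, bin_width = 15)

  # closed-form profile binned identically (same grid points, same bins)
  sfd <- as.data.frame(sf)
  d_um <- dmap[cbind(sfd$Y_px + 1, sfd$X_px + 1)]
  R_um <- sqrt((sfd$X_px - tb$center_px[1])^2 +
               (sfd$Y_px - tb$center_px[2])^2) * px
  keep <- sfd$on_tissue
  bin <- floor(d_um[keep] / 15) + 1
  tr_rr <- tapply(truth_E_rr(truth, R_um[keep], 2), bin, mean)
  tr_tt <- tapply(truth_E_tt(truth, R_um[keep], 2), bin, mean)
  peak <- truth_E_rr(truth, 100, 2)               # 0.28125 at the wall
  expect_equal(peak, 0.28125)
  nb <- 7                                          # first ~100 um
  expect_lt(max(abs(prof$mean_major[1:nb] - tr_rr[1:nb])), 0.15 * peak)
  expect_lt(max(abs(prof$mean_minor[1:nb] - tr_tt[1:nb])), 0.15 * peak)
  # headline sign structure: radial expansive, circumferential
  # compressive near the wall
  expect_gt(prof$mean_major[1], 0)
  expect_lt(prof$mean_minor[1], 0)
  # and magnitudes in the right neighbourhood of the closed forms
  expect_lt(abs(prof$mean_minor[1] - (-0.18)) / 0.18, 0.15)
})

test_that("kymographs stack profiles and propagate missing bins", {
  sf <- uniform_strain_field(0.2)
  lum <- matrix(FALSE, 120, 120); lum[55:65, 55:65] <- TRUE
  dmap <- distance_map(lum, 1)
  p1 <- bin_average(sf, dmap, 15)
  k1 <- kymograph(list(p1), times = 0)
  expect_equal(dim(k1$major), c(nrow(p1), 1L))
  expect_equal(k1$major[, 1], p1$mean_major)

  k3 <- kymograph(list(p1, p1, p1), times = c(0, 2, 4))
  expect_equal(k3$major[, 1], k3$major[, 3])
  expect_true(any(is.na(k3$major)) == any(is.na(p1$mean_major)))

  p2 <- bin_average(sf, dmap, 10)
  expect_error(kymograph(list(p1, p2), c(0, 2)), "bin widths")
})

test_that("fixed-distance series extract the right kymograph rows", {
  sf <- uniform_strain_field(0.2)
  lum <- matrix(FALSE, 120, 120); lum[55:65, 55:65] <- TRUE
  prof <- bin_average(sf, distance_map(lum, 1), 15)
  kym <- kymograph(list(prof, prof), c(0, 2))
  ts <- strain_time_series(kym, c(0, 7, 30), component = "major")
  expect_equal(unique(ts$bin_center_um[ts$distance_um == 0]), 7.5)
  # 7 um with 15 um bins falls in bin [0, 15) as well
  expect_equal(unique(ts$bin_center_um[ts$distance_um == 7]), 7.5)
  expect_equal(unique(ts$bin_center_um[ts$distance_um == 30]), 37.5)
  expect_error(strain_time_series(kym, 1e6), "outside")
})

test_that("wall-bin strain magnitude grows during a contraction ramp", {
  sq <- fixture("lumen_series_seq", function() {
    simulate_scenario("annulus", seed = 17L, shape = c(256L, 256L),
                      n_frames = 5L, R0_um = 60, r0_um = 48,
                      tissue_outer_um = 120)
  })
  lum <- segment_lumen(sq$frames[[1]])
  ell <- fit_ellipse(lum)
  tmask <- tissue_mask(sq$frames[[1]])
  dmap <- distance_map(lum, sq$pixel_size)
  profiles <- lapply(1:5, function(i) {
    fld <- estimate_displacement(sq, i)
    bin_average(strain_field(fld, 7, 7, mask = tmask,
                             lumen_center = ell$center), dmap, 15)
  })
  kym <- kymograph(profiles, sq$times)
  wall_minor <- kym$minor[1, ]
  expect_true(all(diff(abs(wall_minor)) > -0.005))  # non-decreasing ramp
  expect_lt(wall_minor[5], 0)
})
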