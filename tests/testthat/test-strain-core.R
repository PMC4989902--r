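# Deformation gradients, Lagrangian strain, principal decomposition.

make_field <- function(ufun, vfun, n = 64) {
  xg <- matrix(rep(0:(n - 1), each = n), n, n)
  yg <- matrix(rep(0:(n - 1), times = n), n, n)
  displacement_field(ufun(xg, yg), vfun(xg, yg))
}

test_that("central differences recover gradients of linear fields exactly", {
  z <- matrix(0, 64, 64)
  fld0 <- displacement_field(z, z)
  expect_equal(deformation_gradient_at(fld0, c(30, 30), 7), diag(2))

  fld <- make_field(function(x, y) 0.1 * x, function(x, y) 0 * x)
  F <- deformation_gradient_at(fld, c(25, 40), 7)
  expect_equal(F, matrix(c(1.1, 0, 0, 1), 2, 2), tolerance = 1e-12)

  # rigid rotation: F equals the rotation matrix (linear field, exact)
  th <- 10 * pi / 180
  c0 <- 31.5
  fldr <- make_field(
    function(x, y) cos(th) * (x - c0) - sin(th) * (y - c0) + c0 - x,
    function(x, y) sin(th) * (x - c0) + cos(th) * (y - c0) + c0 - y)
  Fr <- deformation_gradient_at(fldr, c(20, 44), 5)
  expect_equal(Fr, matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2),
               tolerance = 1e-10)

  expect_error(deformation_gradient_at(fld0, c(3, 30), 7), "stencil")
})

test_that("Lagrangian strain follows E = (F'F - I)/2", {
  expect_equal(unclass(lagrangian_strain(diag(2)))[c("E11", "E12", "E22")],
               list(E11 = 0, E12 = 0, E22 = 0))
  E <- lagrangian_strain(diag(c(1.1, 1)))
  expect_equal(E$E11, 0.105)
  expect_equal(E$E12, 0)
  expect_equal(E$E22, 0)
  # simple shear, expanded by hand: C = [[1, .2], [.2, 1.04]]
  Es <- lagrangian_strain(matrix(c(1, 0, 0.2, 1), 2, 2))
  expect_equal(c(Es$E11, Es$E12, Es$E22), c(0, 0.1, 0.02))
  # rigid motions are strain-free for any angle
  for (th in c(-0.4, 0.1, 1.2)) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    Er <- lagrangian_strain(R)
    expect_equal(c(Er$E11, Er$E12, Er$E22), c(0, 0, 0), tolerance = 1e-15)
  }
})

test_that("invariant-based eigenvalues match a generic eigensolver", {
  # spot checks against the quadratic formula evaluated directly
  p1 <- principal_strains(list(E11 = 0, E12 = 0.1, E22 = 0.02))
  expect_equal(p1$lambda_major, (0.02 + sqrt(0.0404)) / 2)   # 0.110499
  expect_equal(p1$lambda_minor, (0.02 - sqrt(0.0404)) / 2)   # -0.090499
  p2 <- principal_strains(list(E11 = 0.03, E12 = 0.04, E22 = -0.09))
  expect_equal(p2$lambda_major, (-0.06 + sqrt(0.0208)) / 2)  # 0.042111
  expect_equal(p2$lambda_minor, (-0.06 - sqrt(0.0208)) / 2)  # -0.102111
  expect_equal(p2$lambda_major + p2$lambda_minor, -0.06)

  # oracle equivalence on 1000 random symmetric tensors
  set.seed(42)
  worst_val <- 0; worst_vec <- 0
  for (i in 1:1000) {
    e <- runif(3, -0.5, 0.5)
    E <- list(E11 = e[1], E12 = e[2], E22 = e[3])
    p <- principal_strains(E)
    M <- matrix(c(e[1], e[2], e[2], e[3]), 2, 2)
    ref <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    worst_val <- max(worst_val, abs(p$lambda_major - ref[1]),
                     abs(p$lambda_minor - ref[2]))
    # eigenvector residual ||E w - lambda w||
    w <- p$major_eigenvector
    worst_vec <- max(worst_vec, sqrt(sum((M %*% w - p$lambda_major * w)^2)))
    # trace / determinant conservation
    expect_equal(p$lambda_major + p$lambda_minor, e[1] + e[3],
                 tolerance = 1e-12)
    expect_equal(p$lambda_major * p$lambda_minor, e[1] * e[3] - e[2]^2,
                 tolerance = 1e-12)
  }
  expect_lt(worst_val, 1e-12)
  expect_lt(worst_vec, 1e-10)
})

test_that("degenerate (repeated-eigenvalue) tensors are flagged", {
  p <- principal_strains(list(E11 = 0.05, E12 = 0, E22 = 0.05))
  expect_true(p$degenerate)
  expect_equal(p$lambda_major, p$lambda_minor)
  p0 <- principal_strains(list(E11 = 0, E12 = 0, E22 = 0))
  expect_true(p0$degenerate)
})

test_that("major eigenvectors are oriented toward the lumen", {
  expect_equal(orient_major_eigenvector(c(1, 0), c(200, 100), c(100, 100)),
               c(-1, 0))
  expect_equal(orient_major_eigenvector(c(-1, 0), c(200, 100), c(100, 100)),
               c(-1, 0))
  # exactly tangential: input sign kept
  expect_equal(orient_major_eigenvector(c(0, 1), c(200, 100), c(100, 100)),
               c(0, 1))
  expect_warning(
    v <- orient_major_eigenvector(c(1, 0), c(100, 100), c(100, 100)),
    "coincides")
  expect_equal(v, c(1, 0))
})

test_that("uniform stretch gives a uniform principal-strain field", {
  fld <- make_field(function(x, y) 0.1 * x, function(x, y) 0 * x, n = 120)
  sf <- strain_field(fld, grid_spacing = 7, h = 7,
                     lumen_center = c(59.5, 59.5))
  expect_true(all(abs(sf$lambda_major - 0.105) < 1e-6))
  expect_true(all(abs(sf$lambda_minor) < 1e-12))
})

test_that("strains vanish on masked-out grid points", {
  fld <- make_field(function(x, y) 0.1 * x, function(x, y) 0 * x, n = 120)
  mask <- matrix(FALSE, 120, 120)
  expect_warning(
    sf <- strain_field(fld, 7, 7, mask = mask, lumen_center = c(60, 60)),
    "empty")
  expect_true(all(sf$lambda_major == 0))
  mask[1:60, ] <- TRUE                      # top half is tissue
  sf2 <- strain_field(fld, 7, 7, mask = mask, lumen_center = c(60, 60))
  d <- as.data.frame(sf2)
  expect_true(all(d$lambda_major[!d$on_tissue] == 0))
  expect_true(all(abs(d$lambda_major[d$on_tissue] - 0.105) < 1e-6))
})

test_that("adding a constant displacement changes no strain", {
  fld <- ann_flow()
  sf1 <- strain_field(fld, 7, 7, lumen_center = c(219.5, 219.5))
  shifted <- displacement_field(fld$u + 12.3, fld$v - 4.56,
                                fld$reference_index, fld$target_index,
                                fld$pixel_size)
  sf2 <- strain_field(shifted, 7, 7, lumen_center = c(219.5, 219.5))
  # the constant cancels in the central differences; only the rounding of
  # the shifted displacements themselves remains
  expect_equal(sf1$lambda_major, sf2$lambda_major, tolerance = 1e-12)
  expect_equal(sf1$lambda_minor, sf2$lambda_minor, tolerance = 1e-12)
  # a power-of-two shift of integer-valued displacements is exact
  zi <- matrix(round(fld$u), nrow(fld$u), ncol(fld$u))
  f1 <- displacement_field(zi, zi)
  f2 <- displacement_field(zi + 64, zi - 32)
  s1 <- strain_field(f1, 7, 7, lumen_center = c(219.5, 219.5))
  s2 <- strain_field(f2, 7, 7, lumen_center = c(219.5, 219.5))
  expect_identical(s1$lambda_major, s2$lambda_major)
})

test_that("analytic rigid motions yield strains at numerical zero", {
  for (th_deg in c(0, 5, 15)) {
    th <- th_deg * pi / 180
    c0 <- 63.5
    fld <- make_field(
      function(x, y) cos(th) * (x - c0) - sin(th) * (y - c0) + c0 + 4 - x,
      function(x, y) sin(th) * (x - c0) + cos(th) * (y - c0) + c0 - 2 - y,
      n = 128)
    sf <- strain_field(fld, 7, 7, lumen_center = c(c0, c0))
    expect_lt(max(abs(sf$lambda_major), abs(sf$lambda_minor)), 1e-8)
  }
})

test_that("minor principal strain respects the -0.5 lower bound", {
  # strains of analytic deformation maps: C is positive semidefinite
  sq <- ann_seq()
  td <- truth_field(sq)
  sf <- strain_field(td, 7, 7, lumen_center = ann_truth()$center_px)
  expect_gte(min(sf$lambda_minor), -0.5)
})
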