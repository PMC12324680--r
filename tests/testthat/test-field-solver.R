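test_that("loop centre field matches the closed form mu0 i / (2 a)", {
  a <- 43.4e-3
  f <- loop_field(a, 1, x = 0, r = 0)
  expect_equal(f$Ba, MU0 / (2 * a), tolerance = 1e-12) # 14.48 uT
  expect_identical(f$Br, 0)
})

test_that("the radial component vanishes identically on the axis", {
  f <- loop_field(0.05, 2.3, x = c(-0.1, -0.01, 0, 0.02, 0.3), r = 0)
  expect_identical(f$Br, rep(0, 5))
  expect_equal(f$Ba, MU0 * 2.3 * 0.05^2 / (2 * (0.05^2 + f$x^2)^1.5))
})

test_that("elliptic-integral field matches the segment-sum Biot-Savart oracle", {
  withr::with_seed(42, {
    a <- 43.4e-3
    n_pts <- 100
    x <- runif(n_pts, -0.06, 0.06)
    r <- runif(n_pts, 0, 0.08)
    # keep points off the filament so both methods are well-conditioned
    keep <- sqrt((r - a)^2 + x^2) > 5e-3
    x <- x[keep]
    r <- r[keep]
    f <- loop_field(a, 1.7, x, r)
    for (j in seq_along(x)) {
      o <- bs_segment_loop(a, 1.7, x[j], r[j], n = 20000)
      scale <- sqrt(o$Ba^2 + o$Br^2)
      expect_lt(abs(f$Ba[j] - o$Ba) / scale, 1e-6)
      expect_lt(abs(f$Br[j] - o$Br) / scale, 1e-6)
    }
  })
})

test_that("pair field has Helmholtz mirror symmetry", {
  pair <- table1_pair()
  x <- c(0.002, 0.011, 0.02)
  r <- c(0.004, 0.009, 0.016)
  fp <- pair_field(pair, x, r)
  fm <- pair_field(pair, -x, r)
  expect_equal(fp$Ba, fm$Ba, tolerance = 1e-12) # Ba even in x
  expect_equal(fp$Br, -fm$Br, tolerance = 1e-12) # Br odd in x
  expect_identical(pair_field(pair, 0, 0)$Br, 0) # exact zero at the centre
})

test_that("pair field is exactly linear in current", {
  p1 <- table1_pair(current = 1)
  p2 <- table1_pair(current = 2)
  pts_x <- c(0, 0.004, -0.013)
  pts_r <- c(0.006, 0, 0.012)
  f1 <- pair_field(p1, pts_x, pts_r)
  f2 <- pair_field(p2, pts_x, pts_r)
  expect_identical(f2$Ba, 2 * f1$Ba)
  expect_identical(f2$Br, 2 * f1$Br)
})

test_that("far on-axis field approaches the dipole law", {
  pair <- table1_pair()
  loops <- discretize_winding(pair)
  m <- sum(loops$current * pi * loops$radius^2) # total dipole moment
  x_far <- 20 * 43.4e-3
  Ba <- pair_field(pair, x_far, 0)$Ba
  expect_equal(Ba, MU0 * m / (2 * pi * x_far^3), tolerance = 1e-2)
})

test_that("an ideal point-loop pair at Helmholtz spacing reproduces the closed form", {
  a <- 43.4e-3
  # two 96-turn filamentary loops at +/- a/2
  Ba <- 2 * loop_field(a, 96, a / 2, 0)$Ba
  expect_equal(Ba, (4 / 5)^1.5 * MU0 * 96 / a, tolerance = 1e-12) # 1.989 mT
  expect_equal(ideal_helmholtz_field(a, 96, 1), Ba, tolerance = 1e-12)
})

test_that("helmholtz_spacing returns the loop radius across three decades", {
  for (a in c(0.01, 0.0434, 1, 10)) {
    expect_equal(helmholtz_spacing(a) / a, 1, tolerance = 1e-6)
  }
})

test_that("field_map covers the dish lattice exactly once per point", {
  region <- sample_region("disk", radius = 17.5e-3, grid_step = 0.5e-3)
  fm <- field_map(table1_pair(), region)
  # independent lattice count: points of the 71 x 71 grid inside the disk
  g <- seq(-35, 35)
  n_expected <- sum(outer(g, g, function(a, b) a^2 + b^2) <= 35^2)
  expect_equal(nrow(fm), n_expected) # 3853
  expect_true(all(is.finite(fm$Ba)) && all(is.finite(fm$Br)))
  # reference pair at 1 A: inside the ideal-Helmholtz +/-25 % sanity band
  expect_true(all(abs(fm$Ba) > 1.5e-3 & abs(fm$Ba) < 2.5e-3))
})

test_that("zero current gives an all-zero map", {
  region <- sample_region("disk", radius = 10e-3, grid_step = 2e-3)
  fm <- field_map(table1_pair(current = 0), region)
  expect_true(all(fm$Ba == 0) && all(fm$Br == 0))
})

test_that("regions outside the bore and singular points are rejected", {
  expect_error(
    field_map(table1_pair(), sample_region("disk", radius = 45e-3)),
    "bore"
  )
  expect_error(loop_field(0.05, 1, x = 0, r = 0.05), "singular|filament")
})

test_that("homogeneity of a uniform map is zero and of a midplane disk has no radial divergence", {
  fake <- tibble::tibble(
    x = 0, y = c(0, 1e-3), z = 0, r = abs(c(0, 1e-3)),
    Ba = 1e-3, Br = 0
  )
  attr(fake, "Ba_center") <- 1e-3
  hm <- homogeneity(fake)
  expect_equal(hm$axial_divergence, 0)
  expect_equal(hm$radial_divergence, 0)
  expect_true(hm$Ba_mean >= hm$Ba_min && hm$Ba_mean <= hm$Ba_max)
  # midplane disk of a mirror-symmetric pair: Br = 0 up to roundoff
  fm <- field_map(table1_pair(), sample_region("disk", radius = 10e-3,
                                               grid_step = 2e-3))
  expect_lt(homogeneity(fm)$radial_divergence, 1e-15)
})

test_that("axial divergence grows with region radius", {
  pair <- table1_pair()
  divs <- vapply(c(5e-3, 10e-3, 17.5e-3), function(rad) {
    fm <- field_map(pair, sample_region("cylinder", radius = rad,
                                        height = 5e-3, grid_step = 2.5e-3))
    homogeneity(fm)$axial_divergence
  }, numeric(1))
  expect_true(all(diff(divs) > 0))
})

test_that("current_for_field inverts the centre field by linearity", {
  pair <- table1_pair()
  expect_identical(current_for_field(pair, 0), 0)
  B1 <- pair_field(table1_pair(current = 1), 0, 0)$Ba
  expect_equal(current_for_field(pair, 2 * B1), 2, tolerance = 1e-12)
  # amperes for a weak-field exposure of 480 uT
  i480 <- current_for_field(pair, 480e-6)
  expect_gt(i480, 0.23)
  expect_lt(i480, 0.25)
})

test_that("distributed spacing search lands near the mean winding radius", {
  w <- winding_spec()
  region <- sample_region("cylinder", radius = 10e-3, height = 4e-3,
                          grid_step = 2e-3)
  s_opt <- helmholtz_spacing(
    method = "distributed", winding = w, region = region, tol = 1e-4
  )
  a_mean <- w$inner_radius + w$n_layers * w$wire$diameter / 2
  expect_equal(s_opt / a_mean, 1, tolerance = 0.05)
})
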