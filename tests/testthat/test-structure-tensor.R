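make_grating <- function(orientation_deg, n = 96, wavelength = 8) {
  # stripes oriented at orientation_deg; the gradient points 90 deg away
  gdir <- (orientation_deg + 90) * pi / 180
  xs <- matrix(rep(seq_len(n), each = n), n)
  ys <- matrix(rep(seq_len(n), times = n), n)
  as_gray_image(
    0.5 + 0.5 * sin(2 * pi * (xs * cos(gdir) + ys * sin(gdir)) / wavelength)
  )
}

test_that("a constant image has zero energy and zero coherency", {
  of <- structure_tensor(as_gray_image(matrix(0.7, 32, 32)))
  expect_true(all(abs(of$energy) < 1e-20))
  expect_true(all(of$coherency == 0))
})

test_that("a diagonal grating yields coherency near 1 at its orientation", {
  of <- structure_tensor(make_grating(45))
  interior <- 15:80
  expect_gt(stats::median(of$coherency[interior, interior]), 0.98)
  expect_equal(stats::median(of$angle[interior, interior]), 45,
               tolerance = 0.02)
  # and a horizontal grating reports 0 degrees
  of0 <- structure_tensor(make_grating(0))
  expect_equal(stats::median(abs(of0$angle[interior, interior])), 0,
               tolerance = 0.02)
})

test_that("rotating an image by 90 degrees shifts angles and preserves the score", {
  img <- synthesize_fibers(n_fibers = 120, kappa = 3, mean_angle = 20,
                           seed = 11, dim = c(128, 128))
  rot <- as_gray_image(t(unclass(img))[ncol(img):1, ])
  s1 <- alignment_score(img)$score
  s2 <- alignment_score(rot)$score
  expect_lt(abs(s1 - s2) / s1, 0.02)
  # dominant orientation moves by 90 (mod 180)
  dom <- function(im) {
    of <- structure_tensor(im, sigma_window = 8)
    w <- of$energy * of$coherency
    # energy-weighted axial mean via angle doubling
    0.5 * atan2(sum(w * sin(2 * of$angle * pi / 180)),
                sum(w * cos(2 * of$angle * pi / 180))) * 180 / pi
  }
  d <- abs(dom(img) - dom(rot)) %% 180
  expect_equal(min(d, 180 - d), 90, tolerance = 2)
})

test_that("the score is exactly invariant to global intensity scaling", {
  img <- synthesize_fibers(n_fibers = 100, kappa = 2, seed = 4,
                           dim = c(96, 96))
  s1 <- alignment_score(img)
  s2 <- alignment_score(as_gray_image(unclass(img) * 7.3))
  expect_equal(s1$score, s2$score, tolerance = 1e-12)
  expect_identical(s1$n_pixels_used, s2$n_pixels_used)
})

test_that("parallel stripes score near 100 and filtered noise scores low", {
  expect_gte(alignment_score(make_grating(30, n = 128))$score, 95)
  withr::with_seed(9, {
    noise <- matrix(stats::runif(128^2), 128)
    smooth <- t(EBImage::gblur(t(noise), sigma = 2))
    expect_lte(alignment_score(as_gray_image(smooth))$score, 20)
  })
})

test_that("alignment score orders isotropic, intermediate and parallel networks", {
  s <- vapply(c(0, 4, 1000), function(k) {
    alignment_score(synthesize_fibers(kappa = k, seed = 1))$score
  }, numeric(1))
  expect_lte(s[1], 25) # isotropic
  expect_gte(s[3], 90) # near-parallel
  expect_true(all(diff(s) > 0))
})

test_that("coherency stays within [0, 1] on arbitrary inputs", {
  withr::with_seed(21, {
    imgs <- list(
      matrix(stats::runif(32^2), 32),
      matrix(stats::rexp(48 * 32), 48, 32),
      outer(seq_len(40), seq_len(40), `+`) / 80, # smooth ramp
      {
        m <- matrix(0, 64, 64)
        m[cbind(sample(64, 30, TRUE), sample(64, 30, TRUE))] <- 10
        m # sparse bright dots
      }
    )
    for (m in imgs) {
      of <- structure_tensor(as_gray_image(m))
      expect_true(all(of$coherency >= 0 & of$coherency <= 1))
      expect_true(all(is.finite(of$angle)))
      expect_true(all(of$angle > -90 - 1e-9 & of$angle <= 90 + 1e-9))
    }
  })
})

test_that("masks restrict scoring and degenerate inputs error", {
  img <- synthesize_fibers(n_fibers = 80, kappa = 8, seed = 6,
                           dim = c(96, 96))
  mask <- matrix(FALSE, 96, 96)
  mask[30:70, 30:70] <- TRUE
  res <- alignment_score(img, mask = mask)
  expect_lte(res$n_pixels_used, sum(mask))
  expect_error(alignment_score(img, mask = matrix(TRUE, 10, 10)), "mask")
  expect_error(structure_tensor(matrix(1, 20, 20), sigma_window = 5),
               "support")
  expect_error(alignment_score(as_gray_image(matrix(1, 64, 64))),
               "foreground")
})

test_that("per-image scoring maps tidily over images and files", {
  imgs <- list(
    aligned = synthesize_fibers(n_fibers = 60, kappa = 1000, seed = 1,
                                dim = c(96, 96)),
    random = synthesize_fibers(n_fibers = 60, kappa = 0, seed = 1,
                               dim = c(96, 96))
  )
  tab <- alignment_scores(imgs)
  expect_identical(tab$image_id, c("aligned", "random"))
  expect_gt(tab$score[1], tab$score[2])
  dir <- tempfile()
  dir.create(dir)
  write_gray_image(imgs$aligned, file.path(dir, "aligned.png"))
  write_gray_image(imgs$random, file.path(dir, "random.png"))
  tab2 <- alignment_scores(list.files(dir, full.names = TRUE))
  expect_setequal(tab2$image_id, c("aligned", "random"))
  unlink(dir, recursive = TRUE)
})
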