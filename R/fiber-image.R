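# Grayscale image container, TIFF/PNG I/O, and the seeded synthetic
# fiber-image generator used to exercise the alignment pipeline.

#' Coerce a matrix to a grayscale image
#'
#' Validates a numeric matrix as a grayscale intensity image: at least
#' 16 x 16, finite, nonnegative. Row index is the image y coordinate,
#' column index x.
#'
#' @param x A numeric matrix.
#' @return The matrix with class `gray_image` prepended.
#' @export
as_gray_image <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("expected a numeric matrix")
  if (any(dim(x) < 16)) stop("image must be at least 16 x 16 pixels")
  if (!all(is.finite(x))) stop("image intensities must be finite")
  if (any(x < 0)) stop("image intensities must be nonnegative")
  class(x) <- c("gray_image", class(x))
  x
}

#' Read a grayscale image from TIFF or PNG
#'
#' Multi-channel images are averaged to a single luminance channel.
#'
#' @param path File path ending in `.tif`, `.tiff` or `.png`.
#' @return A `gray_image` matrix with intensities in the file's native
#'   normalized range.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext, " (use TIFF or PNG)")
  )
  if (length(dim(arr)) == 3) {
    nchan <- min(dim(arr)[3], 3) # drop any alpha channel
    arr <- apply(arr[, , seq_len(nchan), drop = FALSE], c(1, 2), mean)
  }
  as_gray_image(arr)
}

#' Write a grayscale image to TIFF or PNG
#'
#' Intensities are clipped to `[0, 1]` for encoding.
#'
#' @param img A `gray_image` (or numeric matrix).
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  m <- pmin(pmax(unclass(img), 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(m, path),
    png = png::writePNG(m, path),
    stop("unsupported image format: .", ext, " (use TIFF or PNG)")
  )
  invisible(path)
}

# von Mises sampler (Best & Fisher 1979 wrapped-Cauchy envelope).
# Local to the generator; kappa = 0 degenerates to the circular uniform.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) {
    return((stats::runif(n, -pi, pi) + mu + pi) %% (2 * pi) - pi)
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  rr <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + rr * z) / (rr + z)
      cc <- kappa * (rr - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- mu + sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  (out + pi) %% (2 * pi) - pi
}

# Add one anti-aliased line segment to an intensity matrix. The profile is
# Gaussian across the segment with sigma = width/2.
render_segment <- function(img, x0, y0, x1, y1, width, intensity) {
  h <- nrow(img)
  wd <- ncol(img)
  pad <- ceiling(3 * width / 2) + 1
  cx <- max(1, floor(min(x0, x1)) - pad):min(wd, ceiling(max(x0, x1)) + pad)
  cy <- max(1, floor(min(y0, y1)) - pad):min(h, ceiling(max(y0, y1)) + pad)
  if (length(cx) == 0 || length(cy) == 0) return(img)
  px <- rep(cx, each = length(cy))
  py <- rep(cy, times = length(cx))
  dx <- x1 - x0
  dy <- y1 - y0
  len2 <- dx^2 + dy^2
  tt <- pmin(pmax(((px - x0) * dx + (py - y0) * dy) / len2, 0), 1)
  d2 <- (px - (x0 + tt * dx))^2 + (py - (y0 + tt * dy))^2
  sigma <- width / 2
  img[cbind(py, px)] <- img[cbind(py, px)] +
    intensity * exp(-d2 / (2 * sigma^2))
  img
}

#' Synthesize a fluorescent fiber image
#'
#' Renders bright anti-aliased line segments over a dark noisy background,
#' emulating fluorescently labelled cytoskeletal fibers. Fiber orientations
#' follow an axial von Mises distribution: angles are drawn on the doubled
#' circle with concentration `kappa` and halved, so `kappa = 0` gives
#' isotropic fibers and large `kappa` near-parallel ones. Fully
#' deterministic for a given `seed` (the generator never touches the
#' global random state outside the call).
#'
#' @param n_fibers Number of segments.
#' @param kappa Axial von Mises concentration (>= 0).
#' @param mean_angle Mean fiber orientation, degrees (image x axis = 0,
#'   counterclockwise positive).
#' @param fiber_length Segment length, pixels (> 0).
#' @param fiber_width Full fiber width, pixels; the cross-profile is a
#'   Gaussian of sigma `fiber_width / 2`.
#' @param background_noise_sd Standard deviation of additive Gaussian
#'   background noise (intensities are clipped at zero afterwards).
#' @param dim Image size `c(rows, cols)`.
#' @param fiber_intensity Peak added intensity per fiber.
#' @param seed Integer seed; required.
#' @return A `gray_image` matrix.
#' @export
#' @examples
#' img <- synthesize_fibers(n_fibers = 40, kappa = 8, seed = 1,
#'                          dim = c(64, 64))
synthesize_fibers <- function(n_fibers = 300,
                              kappa = 4,
                              mean_angle = 0,
                              fiber_length = 60,
                              fiber_width = 2,
                              background_noise_sd = 0.05,
                              dim = c(256, 256),
                              fiber_intensity = 1,
                              seed) {
  if (missing(seed)) stop("a seed is required for reproducible synthesis")
  stopifnot(
    "kappa must be a single nonnegative number" =
      is.numeric(kappa) && length(kappa) == 1 && kappa >= 0,
    "fiber_length must be positive" = fiber_length > 0,
    "fiber_width must be positive" = fiber_width > 0,
    n_fibers >= 1, background_noise_sd >= 0, all(dim >= 16)
  )
  withr::with_seed(as.integer(seed), {
    h <- dim[1]
    w <- dim[2]
    img <- matrix(0, h, w)
    # axial von Mises: double the angle, sample, halve
    theta <- rvonmises(n_fibers, 2 * mean_angle * pi / 180, kappa) / 2
    xc <- stats::runif(n_fibers, 1, w)
    yc <- stats::runif(n_fibers, 1, h)
    for (i in seq_len(n_fibers)) {
      dx <- cos(theta[i]) * fiber_length / 2
      dy <- sin(theta[i]) * fiber_length / 2
      img <- render_segment(
        img, xc[i] - dx, yc[i] - dy, xc[i] + dx, yc[i] + dy,
        fiber_width, fiber_intensity
      )
    }
    if (background_noise_sd > 0) {
      img <- img + matrix(stats::rnorm(h * w, 0, background_noise_sd), h, w)
    }
    as_gray_image(pmax(img, 0))
  })
}
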