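# Off-axis magnetic field of circular loops and coaxial pairs, via the
# complete-elliptic-integral closed form, plus field maps, homogeneity
# summaries and Helmholtz spacing optimization.

MU0 <- 4e-7 * pi # vacuum permeability, N A^-2

#' Magnetic field of a single circular loop
#'
#' Axial (`Ba`) and radial (`Br`) components of the field of a filamentary
#' circular loop of radius `radius` carrying `current`, at axial distance
#' `x` from the loop plane and radial distance `r` from its axis. Uses the
#' closed form in complete elliptic integrals K and E with modulus
#' `k^2 = 4*alpha/Q`, `alpha = r/a0`, `beta = x/a0`,
#' `Q = (1 + alpha)^2 + beta^2`; on the axis (`r = 0`) the exact closed
#' form `Ba = mu0 i a0^2 / (2 (a0^2 + x^2)^(3/2))`, `Br = 0` is used.
#'
#' @param radius Loop radius `a0` in metres (> 0).
#' @param current Loop current in amperes.
#' @param x,r Evaluation point: axial and radial distances in metres.
#'   Vectors are recycled to a common length; `r >= 0`.
#' @param singular_tol Evaluation points within this distance (metres) of
#'   the wire filament raise an error.
#' @return A tibble with columns `x`, `r`, `Ba`, `Br` (teslas).
#' @export
#' @examples
#' # center of a 43.4 mm loop at 1 A: mu0 * i / (2 * a0)
#' loop_field(43.4e-3, 1, x = 0, r = 0)
loop_field <- function(radius, current, x, r, singular_tol = 1e-9) {
  stopifnot(
    "radius must be a single positive number" =
      is.numeric(radius) && length(radius) == 1 && radius > 0,
    is.numeric(current), length(current) == 1,
    is.numeric(x), is.numeric(r), all(r >= 0)
  )
  n <- max(length(x), length(r))
  x <- rep_len(x, n)
  r <- rep_len(r, n)
  if (any(sqrt((r - radius)^2 + x^2) < singular_tol)) {
    stop("field evaluation point lies on the wire filament (singular)")
  }
  Ba <- Br <- numeric(n)
  on_axis <- r < 1e-12 # avoid gamma = x/r overflow
  if (any(on_axis)) {
    Ba[on_axis] <- MU0 * current * radius^2 /
      (2 * (radius^2 + x[on_axis]^2)^1.5)
  }
  if (any(!on_axis)) {
    xo <- x[!on_axis]
    ro <- r[!on_axis]
    alpha <- ro / radius
    beta <- xo / radius
    Q <- (1 + alpha)^2 + beta^2
    m <- 4 * alpha / Q # elliptic parameter k^2
    if (any(m >= 1)) stop("elliptic parameter k^2 >= 1 (point on filament)")
    ke <- pracma::ellipke(m)
    B0 <- MU0 * current / (2 * radius)
    pref <- B0 / (pi * sqrt(Q))
    denom <- Q - 4 * alpha # = (1 - alpha)^2 + beta^2
    Ba[!on_axis] <- pref *
      (ke$e * (1 - alpha^2 - beta^2) / denom + ke$k)
    Br[!on_axis] <- pref * (xo / ro) *
      (ke$e * (1 + alpha^2 + beta^2) / denom - ke$k)
  }
  tibble::tibble(x = x, r = r, Ba = Ba, Br = Br)
}

#' Magnetic field of a coil pair
#'
#' Superposition of [loop_field()] over every filament of the discretized
#' pair. Linear in the drive current.
#'
#' @param pair A [coil_pair()].
#' @param x,r Evaluation points (metres), recycled to a common length.
#'   `x` is measured from the pair midpoint.
#' @param loops Optional precomputed [discretize_winding()] result.
#' @return A tibble with columns `x`, `r`, `Ba`, `Br` (teslas).
#' @export
pair_field <- function(pair, x, r, loops = NULL) {
  if (is.null(loops)) loops <- discretize_winding(pair)
  n <- max(length(x), length(r))
  x <- rep_len(x, n)
  r <- rep_len(r, n)
  Ba <- Br <- numeric(n)
  for (j in seq_len(nrow(loops))) {
    f <- loop_field(loops$radius[j], loops$current[j], x - loops$axial_offset[j], r)
    Ba <- Ba + f$Ba
    Br <- Br + f$Br
  }
  tibble::tibble(x = x, r = r, Ba = Ba, Br = Br)
}

#' Define the sampling region over the culture dish
#'
#' A disk (single axial plane) or cylinder (stack of planes) centred on the
#' coil axis, sampled on a square lattice of pitch `grid_step`. Defaults
#' describe a 35 mm culture dish: radius 17.5 mm.
#'
#' @param shape `"disk"` or `"cylinder"`.
#' @param radius Region radius in metres.
#' @param height Cylinder height in metres (required for cylinders).
#' @param axial_center Axial position of the region centre, metres from the
#'   pair midpoint.
#' @param grid_step Lattice pitch in metres.
#' @return An object of class `sample_region`.
#' @export
sample_region <- function(shape = c("disk", "cylinder"),
                          radius = 17.5e-3,
                          height = NULL,
                          axial_center = 0,
                          grid_step = 0.5e-3) {
  shape <- match.arg(shape)
  stopifnot(
    "radius must be a single positive number" =
      is.numeric(radius) && length(radius) == 1 && radius > 0,
    "grid_step must be a single positive number" =
      is.numeric(grid_step) && length(grid_step) == 1 && grid_step > 0
  )
  if (shape == "cylinder") {
    stopifnot(
      "a cylinder region needs a positive height" =
        !is.null(height) && is.numeric(height) && height > 0
    )
  } else {
    height <- 0
  }
  structure(
    list(
      shape = shape, radius = radius, height = height,
      axial_center = axial_center, grid_step = grid_step
    ),
    class = "sample_region"
  )
}

# Lattice points of a region: tibble(x, y, z, r), deterministic ordering.
region_grid <- function(region) {
  g <- seq(-region$radius, region$radius, by = region$grid_step)
  xs <- if (region$shape == "disk") {
    region$axial_center
  } else {
    seq(region$axial_center - region$height / 2,
        region$axial_center + region$height / 2,
        by = region$grid_step)
  }
  grid <- tidyr::expand_grid(x = xs, y = g, z = g)
  grid$r <- sqrt(grid$y^2 + grid$z^2)
  dplyr::filter(grid, .data$r <= region$radius + 1e-12)
}

#' Map the pair field over a sample region
#'
#' Evaluates the pair field at every lattice point of the region.
#' Axisymmetry is exploited internally (the field is computed once per
#' unique `(x, r)` combination), so dense disk grids are cheap.
#'
#' @param pair A [coil_pair()].
#' @param region A [sample_region()]; must lie strictly inside the bore.
#' @return A tibble of class `coil_field_map` with columns `x`, `y`, `z`,
#'   `r` (metres) and `Ba`, `Br` (teslas), plus attributes `Ba_center`
#'   (field at the region centre on the axis) and `region`.
#' @export
#' @examples
#' \donttest{
#' fm <- field_map(coil_pair(), sample_region("disk"))
#' mean(abs(fm$Ba)) * 1e3 # mean field in mT
#' }
field_map <- function(pair, region) {
  stopifnot(inherits(region, "sample_region"))
  if (region$radius >= pair$winding$inner_radius) {
    stop("sample region does not lie strictly inside the coil bore")
  }
  loops <- discretize_winding(pair)
  grid <- region_grid(region)
  key <- paste(grid$x, round(grid$r, 12))
  uniq <- !duplicated(key)
  fu <- pair_field(pair, grid$x[uniq], grid$r[uniq], loops = loops)
  idx <- match(key, key[uniq])
  out <- grid
  out$Ba <- fu$Ba[idx]
  out$Br <- fu$Br[idx]
  center <- pair_field(pair, region$axial_center, 0, loops = loops)
  structure(
    out,
    Ba_center = center$Ba,
    current = pair$current,
    region = region,
    class = c("coil_field_map", class(out))
  )
}

#' Summarise field homogeneity over a map
#'
#' Axial divergence is the maximum absolute deviation of `Ba` from its
#' value at the region centre; radial divergence is the maximum `|Br|`.
#' Both are uniformity metrics (not the vector-calculus operator).
#'
#' @param map A [field_map()] result.
#' @return A one-row tibble: `Ba_center`, `Ba_mean`, `Ba_min`, `Ba_max`,
#'   `axial_divergence`, `radial_divergence` (teslas) and `n_points`.
#' @export
homogeneity <- function(map) {
  stopifnot(nrow(map) > 0)
  Ba_center <- attr(map, "Ba_center")
  if (is.null(Ba_center)) {
    # fall back to the grid point nearest the axis at the axial centre
    i <- which.min(map$r + abs(map$x - stats::median(map$x)))
    Ba_center <- map$Ba[i]
  }
  tibble::tibble(
    Ba_center = Ba_center,
    Ba_mean = mean(map$Ba),
    Ba_min = min(map$Ba),
    Ba_max = max(map$Ba),
    axial_divergence = max(abs(map$Ba - Ba_center)),
    radial_divergence = max(abs(map$Br)),
    n_points = nrow(map)
  )
}

# On-axis field of a filamentary pair: d^2 Ba / dx^2 at the midpoint,
# up to a positive prefactor. Used by helmholtz_spacing().
pair_axial_curvature <- function(spacing, radius) {
  d <- spacing / 2
  s2 <- radius^2 + d^2
  -3 * s2^(-2.5) + 15 * d^2 * s2^(-3.5)
}

#' Helmholtz spacing of a loop pair
#'
#' Finds the coaxial separation that zeroes the second axial derivative of
#' the on-axis field at the midpoint of a filamentary loop pair — the
#' Helmholtz condition, whose solution is the loop radius itself. The
#' `"distributed"` method instead minimises the axial divergence of a real
#' multilayer winding over a sample region.
#'
#' @param radius Loop radius in metres (method `"analytic"`).
#' @param method `"analytic"` (filamentary pair, root of the curvature) or
#'   `"distributed"` (numeric search over a winding).
#' @param winding,region For `"distributed"`: a [winding_spec()] and
#'   [sample_region()].
#' @param current Drive current for the distributed search (the optimum is
#'   current-independent).
#' @param tol Relative solver tolerance.
#' @return Spacing in metres.
#' @export
#' @examples
#' helmholtz_spacing(43.4e-3) * 1e3 # 43.4 mm: spacing equals the radius
helmholtz_spacing <- function(radius,
                              method = c("analytic", "distributed"),
                              winding = NULL, region = NULL, current = 1,
                              tol = 1e-9) {
  method <- match.arg(method)
  if (method == "analytic") {
    stopifnot(
      "radius must be a single positive number" =
        is.numeric(radius) && length(radius) == 1 && radius > 0
    )
    root <- stats::uniroot(
      pair_axial_curvature, c(0.2 * radius, 3 * radius),
      radius = radius, tol = tol * radius
    )
    return(root$root)
  }
  stopifnot(inherits(winding, "winding_spec"), inherits(region, "sample_region"))
  a_mean <- winding$inner_radius + winding$n_layers * winding$wire$diameter / 2
  obj <- function(s) {
    hm <- homogeneity(field_map(coil_pair(winding, s, current), region))
    hm$axial_divergence
  }
  stats::optimize(obj, c(0.5 * a_mean, 2 * a_mean), tol = tol * a_mean)$minimum
}

#' Current needed for a target centre field
#'
#' Exact by linearity: the target divided by the centre field per ampere.
#'
#' @param pair A [coil_pair()] (its `current` field is ignored).
#' @param B_target Target axial field at the pair centre, teslas (>= 0).
#' @return Current in amperes.
#' @export
#' @examples
#' current_for_field(coil_pair(), 480e-6) # amperes for a 480 uT exposure
current_for_field <- function(pair, B_target) {
  stopifnot(is.numeric(B_target), length(B_target) == 1, B_target >= 0)
  unit <- coil_pair(pair$winding, pair$spacing, current = 1)
  B_target / pair_field(unit, 0, 0)$Ba
}

#' Ideal-filament Helmholtz centre field
#'
#' Closed-form centre field of two N-turn point loops at the Helmholtz
#' condition (spacing = radius): `(4/5)^(3/2) * mu0 * N * i / a0`. Reported
#' alongside distributed-winding results for transparency.
#'
#' @param radius Loop radius, metres.
#' @param n_turns Turns per coil.
#' @param current Amperes.
#' @return Field in teslas.
#' @export
ideal_helmholtz_field <- function(radius, n_turns, current = 1) {
  (4 / 5)^1.5 * MU0 * n_turns * current / radius
}
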