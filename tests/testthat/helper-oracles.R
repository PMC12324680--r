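# Independent oracles, deliberately naive: a segment-sum Biot-Savart line
# integral for the loop field, and full-enumeration Mann-Whitney p values.
# Both avoid the code paths they check.

# Field of a circular loop (radius a, current i, loop in the z = 0 plane,
# centred on the origin) at the point (r, 0, x), by summing n straight
# segments. Truncation error ~ (2*pi/n)^2.
bs_segment_loop <- function(a, i, x, r, n = 20000) {
  phi <- (seq_len(n) - 0.5) * 2 * pi / n
  px <- a * cos(phi)
  py <- a * sin(phi)
  dl <- 2 * pi * a / n
  tx <- -sin(phi)
  ty <- cos(phi)
  rx <- r - px
  ry <- -py
  rz <- x
  rr3 <- (rx^2 + ry^2 + rz^2)^1.5
  f <- 1e-7 * i * dl / rr3 # mu0 / (4 pi) = 1e-7
  # t x rvec with t = (tx, ty, 0)
  list(
    Br = sum(f * (ty * rz)),           # x component = radial at (r, 0, x)
    Ba = sum(f * (tx * ry - ty * rx))  # z component = axial
  )
}

# Exact two-sided Mann-Whitney p value by enumerating every assignment of
# the pooled observations to the first group.
mw_enumerate <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  rks <- rank(pooled)
  u_of <- function(idx) sum(rks[idx]) - n_a * (n_a + 1) / 2
  u_obs <- u_of(seq_len(n_a))
  us <- utils::combn(length(pooled), n_a, u_of)
  list(
    U = u_obs,
    p = min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  )
}

table1_pair <- function(current = 1) {
  coil_pair(
    winding_spec(
      inner_radius = 40e-3, axial_width = 16e-3, n_turns = 96,
      wire = wire_spec(0.71e-3, conductor_diameter = 0.6438e-3)
    ),
    spacing = 43.4e-3, current = current
  )
}

MU0 <- 4e-7 * pi
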