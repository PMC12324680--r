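# Electrical behavior of the coil pair: RL step response, switching limit,
# impedance matching, and an advisory inductance estimate.

#' Electrical parameters of the drive circuit
#'
#' Measured series resistance, inductance and drive voltage of the coil
#' pair. Defaults are the packaged design's measured values.
#'
#' @param R Series resistance, ohms (> 0).
#' @param L Inductance, henries (>= 0).
#' @param V Drive voltage, volts.
#' @return An object of class `electrical_params`.
#' @export
electrical_params <- function(R = 2.74, L = 870e-6, V = 2.75) {
  stopifnot(
    "R must be a single positive number" =
      is.numeric(R) && length(R) == 1 && R > 0,
    "L must be a single nonnegative number" =
      is.numeric(L) && length(L) == 1 && L >= 0,
    is.numeric(V), length(V) == 1
  )
  structure(list(R = R, L = L, V = V), class = "electrical_params")
}

#' RL step-response current
#'
#' Current at time `t` after applying the drive voltage to the series RL
#' circuit: `(V/R) * (1 - exp(-t R / L))`.
#'
#' @param params An [electrical_params()].
#' @param t Time(s) since switch-on, seconds (>= 0); vectorized.
#' @return Current in amperes.
#' @export
#' @examples
#' step_current(electrical_params(), t = c(0, 1e-3, 1))
step_current <- function(params, t) {
  stopifnot(inherits(params, "electrical_params"), all(t >= 0))
  (params$V / params$R) * (1 - exp(-t * params$R / params$L))
}

#' Time to reach a fraction of the asymptotic current
#'
#' Inverse of [step_current()]: `-(L/R) * log(1 - frac)`.
#'
#' @inheritParams step_current
#' @param frac Fraction of `V/R` to reach, strictly in (0, 1); vectorized.
#' @return Time in seconds.
#' @export
time_to_fraction <- function(params, frac) {
  stopifnot(inherits(params, "electrical_params"))
  if (any(frac <= 0 | frac >= 1)) {
    stop("frac must lie strictly between 0 and 1")
  }
  -(params$L / params$R) * log(1 - frac)
}

#' Maximum square-wave switching frequency
#'
#' Largest whole-number frequency whose period accommodates a full on+off
#' toggle: `floor(1 / toggle_time)`. The toggle time is an experimental
#' input (for the packaged design it is dominated by the supply, not by
#' L/R, at ~400 time constants).
#'
#' @param toggle_time Measured full on+off toggle time, seconds (> 0).
#' @return Integer frequency in hertz.
#' @export
#' @examples
#' max_switch_frequency(0.130) # 7 Hz for a 130 ms toggle
max_switch_frequency <- function(toggle_time) {
  stopifnot(
    "toggle_time must be a single positive number" =
      is.numeric(toggle_time) && length(toggle_time) == 1 && toggle_time > 0
  )
  as.integer(floor(1 / toggle_time))
}

#' Impedance magnitude at a drive frequency
#'
#' `|Z| = sqrt(R^2 + (2 pi f L)^2)`.
#'
#' @inheritParams step_current
#' @param f Frequency in hertz (>= 0); vectorized.
#' @return Impedance magnitude in ohms.
#' @export
impedance <- function(params, f) {
  stopifnot(inherits(params, "electrical_params"), all(f >= 0))
  sqrt(params$R^2 + (2 * pi * f * params$L)^2)
}

#' Drive voltage for a target AC current (impedance matching)
#'
#' `V = i * |Z|(f)`; at DC this is Ohm's law.
#'
#' @inheritParams impedance
#' @param i Target current amplitude, amperes.
#' @return Voltage in volts.
#' @export
#' @examples
#' voltage_for_current(electrical_params(), i = 1, f = 7)
voltage_for_current <- function(params, i, f) {
  i * impedance(params, f)
}

#' Switching analysis summary
#'
#' Time constant, rise time to a stated fraction of the asymptotic
#' current, and the admissible switching frequency for a measured toggle
#' time.
#'
#' @inheritParams step_current
#' @param toggle_time Measured on+off toggle time, seconds.
#' @param rise_fraction Fraction of `V/R` defining `t_rise`.
#' @return A one-row tibble: `tau`, `t_rise`, `toggle_time` (s), `f_max`
#'   (Hz), `i_final` (A).
#' @export
switching_analysis <- function(params, toggle_time = 0.130,
                               rise_fraction = 0.99) {
  tibble::tibble(
    tau = params$L / params$R,
    t_rise = time_to_fraction(params, rise_fraction),
    toggle_time = toggle_time,
    f_max = max_switch_frequency(toggle_time),
    i_final = params$V / params$R
  )
}

#' Advisory inductance estimate for one winding
#'
#' Wheeler's multilayer air-coil approximation applied to one winding of
#' the pair: `L [uH] = 0.8 a^2 N^2 / (6a + 9b + 10c)` with the mean winding
#' radius `a`, winding length `b` and winding depth `c` in inches. Accurate
#' to roughly +/-30 percent for chunky multilayer coils; it is advisory
#' only and never stands in for a measured inductance. Mutual coupling
#' between the two coils is neglected.
#'
#' @param pair A [coil_pair()].
#' @return Estimated per-winding inductance in henries.
#' @export
estimate_inductance <- function(pair) {
  w <- pair$winding
  depth <- w$n_layers * w$wire$diameter
  a_in <- (w$inner_radius + depth / 2) / 0.0254
  b_in <- w$axial_width / 0.0254
  c_in <- depth / 0.0254
  0.8 * a_in^2 * w$n_turns^2 / (6 * a_in + 9 * b_in + 10 * c_in) * 1e-6
}
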