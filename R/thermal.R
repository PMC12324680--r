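# Heat dissipation into the cooling water and condensation safety (dew
# point) for operation inside a cell incubator.

#' Coolant specification
#'
#' Cooling-water properties and operating point. The default 1 L/min flow
#' and 30 C supply are package defaults chosen to keep a worst-case 1 A
#' run both cool (sub-0.1 K rise) and condensation-safe inside a 37 C /
#' 60 % RH incubator.
#'
#' @param flow_rate Volumetric flow in litres per minute (> 0).
#' @param inlet_temp Supply temperature, degrees Celsius.
#' @param specific_heat J/(kg K); default water.
#' @param density kg/m^3; default water.
#' @return An object of class `coolant_spec`.
#' @export
coolant_spec <- function(flow_rate = 1, inlet_temp = 30,
                         specific_heat = 4186, density = 998) {
  stopifnot(
    "flow_rate must be a single positive number (zero flow = no cooling)" =
      is.numeric(flow_rate) && length(flow_rate) == 1 && flow_rate > 0,
    is.numeric(inlet_temp), length(inlet_temp) == 1,
    specific_heat > 0, density > 0
  )
  structure(
    list(
      flow_rate = flow_rate, inlet_temp = inlet_temp,
      specific_heat = specific_heat, density = density
    ),
    class = "coolant_spec"
  )
}

#' Incubator air state
#'
#' @param temperature Air temperature, degrees Celsius.
#' @param relative_humidity Relative humidity in percent, in (0, 100].
#' @return An object of class `incubator_air`.
#' @export
incubator_air <- function(temperature = 37, relative_humidity = 60) {
  stopifnot(
    is.numeric(temperature), length(temperature) == 1,
    "relative_humidity must lie in (0, 100]" =
      is.numeric(relative_humidity) && length(relative_humidity) == 1 &&
        relative_humidity > 0 && relative_humidity <= 100
  )
  structure(
    list(temperature = temperature, relative_humidity = relative_humidity),
    class = "incubator_air"
  )
}

#' Resistive power dissipated in the coils
#'
#' `i^2 R`; vectorized over current.
#'
#' @param current Amperes.
#' @param resistance Series resistance, ohms (> 0).
#' @return Power in watts.
#' @export
dissipated_power <- function(current, resistance = 2.74) {
  stopifnot(
    "resistance must be a single positive number" =
      is.numeric(resistance) && length(resistance) == 1 && resistance > 0
  )
  current^2 * resistance
}

#' Steady-state coolant temperature rise
#'
#' Worst-case lumped model: all dissipated power enters the water, so
#' `dT = P / (mdot c_p)` with the mass flow from the volumetric rate.
#'
#' @param power Dissipated power, watts (>= 0).
#' @param coolant A [coolant_spec()].
#' @return Temperature rise in kelvin.
#' @export
#' @examples
#' coolant_temperature_rise(dissipated_power(1, 2.74), coolant_spec(1))
coolant_temperature_rise <- function(power, coolant = coolant_spec()) {
  stopifnot(all(power >= 0), inherits(coolant, "coolant_spec"))
  mdot <- coolant$flow_rate * coolant$density / 60000 # L/min -> kg/s
  power / (mdot * coolant$specific_heat)
}

# Magnus fit constants (Sonntag 1990), valid over incubator conditions.
MAGNUS_A <- 17.62
MAGNUS_B <- 243.12 # degrees C

#' Dew-point temperature of humid air
#'
#' Magnus relation: `Td = b g / (a - g)` with
#' `g = ln(RH/100) + a T / (b + T)`, a = 17.62, b = 243.12 C. At 100 % RH
#' the dew point equals the air temperature exactly.
#'
#' @param air An [incubator_air()].
#' @return Dew point in degrees Celsius.
#' @export
#' @examples
#' dew_point(incubator_air(37, 60)) # just under 28 C
dew_point <- function(air) {
  stopifnot(inherits(air, "incubator_air"))
  g <- log(air$relative_humidity / 100) +
    MAGNUS_A * air$temperature / (MAGNUS_B + air$temperature)
  MAGNUS_B * g / (MAGNUS_A - g)
}

#' Is a cooled surface condensation-safe?
#'
#' TRUE iff the surface stays above the dew point of the surrounding air
#' by at least `margin`.
#'
#' @param surface_temp Coolant-wetted surface temperature, degrees Celsius.
#' @param air An [incubator_air()].
#' @param margin Safety margin in kelvin (default 0).
#' @return Logical.
#' @export
condensation_safe <- function(surface_temp, air, margin = 0) {
  surface_temp > dew_point(air) + margin
}

#' Thermal and condensation report
#'
#' Assembles the dissipated power, worst-case coolant temperature rise,
#' dew point and condensation verdict for an operating point. Pure: the
#' same inputs always yield the identical report.
#'
#' @param current Drive current, amperes.
#' @param resistance Series resistance, ohms.
#' @param coolant A [coolant_spec()].
#' @param air An [incubator_air()].
#' @param surface_temp Cooled-surface temperature, degrees Celsius;
#'   defaults to the coolant inlet temperature.
#' @param margin Condensation safety margin, kelvin.
#' @return A one-row tibble: `power` (W), `coolant_dT` (K), `dew_point`
#'   (C), `surface_temp` (C), `condensation_safe` (logical).
#' @export
#' @examples
#' thermal_report(1, 2.74, coolant_spec(1, 30), incubator_air(37, 60))
thermal_report <- function(current, resistance = 2.74,
                           coolant = coolant_spec(),
                           air = incubator_air(),
                           surface_temp = coolant$inlet_temp,
                           margin = 0) {
  power <- dissipated_power(current, resistance)
  tibble::tibble(
    power = power,
    coolant_dT = coolant_temperature_rise(power, coolant),
    dew_point = dew_point(air),
    surface_temp = surface_temp,
    condensation_safe = condensation_safe(surface_temp, air, margin)
  )
}
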