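# Full design report: orchestrates the field, circuit and thermal models
# for a validated configuration and checks user budgets.

#' Full design report for a configuration
#'
#' Deterministically aggregates the field solver (map + homogeneity over
#' the configured region, with the ideal-filament Helmholtz value printed
#' alongside for transparency), the electrical analysis (time constant,
#' switching limit, impedance matching, advisory geometry predictions) and
#' the thermal/condensation analysis, then evaluates pass/fail flags
#' against any user budgets.
#'
#' @param cfg A [load_config()] result.
#' @return An object of class `design_report` (JSON-serializable via
#'   [write_report()]): `field`, `electrical`, `thermal` one-row tibbles
#'   and a `budgets` tibble of logical flags.
#' @export
#' @examples
#' \donttest{
#' cfg <- load_config(system.file("extdata", "table1.yaml",
#'                                package = "helmcoil"))
#' full_report(cfg)
#' }
full_report <- function(cfg) {
  stopifnot(inherits(cfg, "design_config"))
  op <- cfg$raw$operating
  fm <- field_map(cfg$pair, cfg$region)
  hm <- homogeneity(fm)
  field <- tibble::tibble(
    current_a = cfg$pair$current,
    Ba_center_mT = hm$Ba_center * 1e3,
    Ba_mean_mT = hm$Ba_mean * 1e3,
    ideal_loop_Ba_mT = ideal_helmholtz_field(
      cfg$pair$spacing, cfg$pair$winding$n_turns, cfg$pair$current
    ) * 1e3,
    axial_divergence_uT = hm$axial_divergence * 1e6,
    radial_divergence_uT = hm$radial_divergence * 1e6,
    n_grid_points = hm$n_points
  )
  sw <- switching_analysis(cfg$params, op$toggle_time_ms * 1e-3)
  electrical <- tibble::tibble(
    R_ohm = cfg$params$R,
    L_uH = cfg$params$L * 1e6,
    tau_ms = sw$tau * 1e3,
    t_rise99_ms = sw$t_rise * 1e3,
    f_max_hz = sw$f_max,
    impedance_ohm = impedance(cfg$params, op$frequency_hz),
    drive_voltage_v = voltage_for_current(
      cfg$params, cfg$pair$current, op$frequency_hz
    ),
    predicted_R_ohm = resistance_from_geometry(cfg$pair),
    estimated_L_per_coil_uH = estimate_inductance(cfg$pair) * 1e6
  )
  thermal <- thermal_report(
    cfg$pair$current, cfg$params$R, cfg$coolant, cfg$air,
    margin = cfg$raw$budgets$condensation_margin_k
  )
  bud <- cfg$raw$budgets
  budgets <- tibble::tibble(
    coolant_dT_ok = thermal$coolant_dT <= bud$max_coolant_dt_k,
    condensation_ok = thermal$condensation_safe,
    axial_divergence_ok = if (is.null(bud$axial_divergence_ut)) {
      NA
    } else {
      field$axial_divergence_uT <= bud$axial_divergence_ut
    }
  )
  structure(
    list(
      field = field, electrical = electrical, thermal = thermal,
      budgets = budgets
    ),
    class = "design_report"
  )
}

#' @export
print.design_report <- function(x, ...) {
  cat("<design_report>\n")
  cat(sprintf(
    "  field:   center %.4f mT, mean %.4f mT (ideal filament pair %.4f mT)\n",
    x$field$Ba_center_mT, x$field$Ba_mean_mT, x$field$ideal_loop_Ba_mT
  ))
  cat(sprintf(
    "           divergence: axial %.2f uT, radial %.2f uT over %d points\n",
    x$field$axial_divergence_uT, x$field$radial_divergence_uT,
    x$field$n_grid_points
  ))
  cat(sprintf(
    "  circuit: tau %.3g ms, f_max %d Hz, drive %.3f V at the operating point\n",
    x$electrical$tau_ms, x$electrical$f_max_hz, x$electrical$drive_voltage_v
  ))
  cat(sprintf(
    "  thermal: %.3g W, coolant dT %.4f K, dew point %.2f C, %s\n",
    x$thermal$power, x$thermal$coolant_dT, x$thermal$dew_point,
    if (x$thermal$condensation_safe) "condensation-safe" else "NOT condensation-safe"
  ))
  invisible(x)
}

#' Serialize a design report (or any report tibble) to JSON
#'
#' @param report A `design_report`, tibble or list of tibbles.
#' @param path Output file; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
write_report <- function(report, path = NULL) {
  if (inherits(report, "design_report")) report <- unclass(report)
  js <- jsonlite::toJSON(report, dataframe = "columns", auto_unbox = FALSE,
                         digits = 10, pretty = TRUE, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Export a field map as a tidy CSV
#'
#' Columns `x_mm`, `y_mm`, `z_mm`, `r_mm`, `Ba_mT`, `Br_mT`.
#'
#' @param map A [field_map()] result.
#' @param path Output CSV path.
#' @return The exported tibble, invisibly.
#' @export
write_field_map <- function(map, path) {
  out <- tibble::tibble(
    x_mm = map$x * 1e3, y_mm = map$y * 1e3, z_mm = map$z * 1e3,
    r_mm = map$r * 1e3, Ba_mT = map$Ba * 1e3, Br_mT = map$Br * 1e3
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
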