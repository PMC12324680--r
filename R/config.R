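# YAML design configuration: explicit unit-suffixed keys, strict schema
# (unknown keys rejected), defaults filled, validated into the package's
# domain objects.

config_defaults <- function() {
  list(
    coil = list(
      wire_diameter_mm = 0.71,
      wire_conductor_diameter_mm = 0.71,
      wire_resistivity_ohm_m = COPPER_RESISTIVITY,
      holder_inner_diameter_mm = 80,
      winding_width_mm = 16,
      n_turns = 96,
      spacing_mm = 43.4
    ),
    operating = list(
      current_a = 1,
      frequency_hz = 0,
      toggle_time_ms = 130,
      drive_voltage_v = 2.75,
      resistance_ohm = 2.74,
      inductance_uh = 870
    ),
    coolant = list(flow_lpm = 1, inlet_temp_c = 30),
    air = list(temp_c = 37, relative_humidity_pct = 60),
    region = list(
      shape = "cylinder",
      radius_mm = 17.5,
      height_mm = 5,
      axial_center_mm = 0,
      grid_step_mm = 0.5
    ),
    alignment = list(
      sigma_gradient_px = 1,
      sigma_window_px = 8,
      energy_quantile = 0.5
    ),
    budgets = list(
      axial_divergence_ut = NULL,
      max_coolant_dt_k = 0.1,
      condensation_margin_k = 0
    )
  )
}

# Merge user values over defaults, collecting every unknown key.
merge_config <- function(user) {
  defaults <- config_defaults()
  bad <- character(0)
  for (sec in names(user)) {
    if (!sec %in% names(defaults)) {
      bad <- c(bad, sec)
      next
    }
    for (key in names(user[[sec]])) {
      if (!key %in% names(defaults[[sec]])) {
        bad <- c(bad, paste(sec, key, sep = "."))
      } else {
        defaults[[sec]][key] <- user[[sec]][key]
      }
    }
  }
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  defaults
}

validate_config <- function(raw) {
  problems <- character(0)
  need_pos <- list(
    "coil.wire_diameter_mm" = raw$coil$wire_diameter_mm,
    "coil.wire_conductor_diameter_mm" = raw$coil$wire_conductor_diameter_mm,
    "coil.wire_resistivity_ohm_m" = raw$coil$wire_resistivity_ohm_m,
    "coil.holder_inner_diameter_mm" = raw$coil$holder_inner_diameter_mm,
    "coil.winding_width_mm" = raw$coil$winding_width_mm,
    "coil.n_turns" = raw$coil$n_turns,
    "coil.spacing_mm" = raw$coil$spacing_mm,
    "operating.toggle_time_ms" = raw$operating$toggle_time_ms,
    "operating.resistance_ohm" = raw$operating$resistance_ohm,
    "coolant.flow_lpm" = raw$coolant$flow_lpm,
    "region.radius_mm" = raw$region$radius_mm,
    "region.grid_step_mm" = raw$region$grid_step_mm,
    "alignment.sigma_gradient_px" = raw$alignment$sigma_gradient_px,
    "alignment.sigma_window_px" = raw$alignment$sigma_window_px
  )
  for (nm in names(need_pos)) {
    v <- need_pos[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      problems <- c(problems, paste0(nm, " must be a positive number"))
    }
  }
  need_nonneg <- list(
    "operating.current_a" = raw$operating$current_a,
    "operating.frequency_hz" = raw$operating$frequency_hz,
    "operating.inductance_uh" = raw$operating$inductance_uh
  )
  for (nm in names(need_nonneg)) {
    v <- need_nonneg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      problems <- c(problems, paste0(nm, " must be a nonnegative number"))
    }
  }
  rh <- raw$air$relative_humidity_pct
  if (!is.numeric(rh) || rh <= 0 || rh > 100) {
    problems <- c(problems, "air.relative_humidity_pct must lie in (0, 100]")
  }
  if (!raw$region$shape %in% c("disk", "cylinder")) {
    problems <- c(problems, "region.shape must be 'disk' or 'cylinder'")
  }
  q <- raw$alignment$energy_quantile
  if (!is.numeric(q) || q < 0 || q >= 1) {
    problems <- c(problems, "alignment.energy_quantile must lie in [0, 1)")
  }
  if (length(problems) > 0) {
    stop("invalid config:\n  ", paste(problems, collapse = "\n  "))
  }
  invisible(raw)
}

#' Load and validate a design configuration
#'
#' Reads a YAML design config with explicit unit-suffixed keys, fills in
#' packaged defaults, rejects unknown keys (every offending key is named),
#' and validates each field. The packaged `table1.yaml` describes the
#' reference water-cooled design.
#'
#' @param path Path to a YAML file.
#' @return An object of class `design_config`: the raw merged values
#'   (`$raw`) plus constructed [coil_pair()], [electrical_params()],
#'   [coolant_spec()], [incubator_air()] and [sample_region()] objects.
#' @export
#' @examples
#' cfg <- load_config(system.file("extdata", "table1.yaml",
#'                                package = "helmcoil"))
#' cfg$pair
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user) || !is.list(user)) {
    stop("config file is empty or not a YAML mapping: ", path)
  }
  as_design_config(merge_config(user))
}

# Build the domain objects from validated raw values.
as_design_config <- function(raw) {
  validate_config(raw)
  co <- raw$coil
  wire <- wire_spec(
    diameter = co$wire_diameter_mm * 1e-3,
    conductor_diameter = co$wire_conductor_diameter_mm * 1e-3,
    resistivity = co$wire_resistivity_ohm_m
  )
  winding <- winding_spec(
    inner_radius = co$holder_inner_diameter_mm / 2 * 1e-3,
    axial_width = co$winding_width_mm * 1e-3,
    n_turns = co$n_turns,
    wire = wire
  )
  reg <- raw$region
  region <- sample_region(
    shape = reg$shape,
    radius = reg$radius_mm * 1e-3,
    height = if (reg$shape == "cylinder") reg$height_mm * 1e-3 else NULL,
    axial_center = reg$axial_center_mm * 1e-3,
    grid_step = reg$grid_step_mm * 1e-3
  )
  structure(
    list(
      raw = raw,
      pair = coil_pair(winding, co$spacing_mm * 1e-3, raw$operating$current_a),
      params = electrical_params(
        R = raw$operating$resistance_ohm,
        L = raw$operating$inductance_uh * 1e-6,
        V = raw$operating$drive_voltage_v
      ),
      coolant = coolant_spec(raw$coolant$flow_lpm, raw$coolant$inlet_temp_c),
      air = incubator_air(raw$air$temp_c, raw$air$relative_humidity_pct),
      region = region
    ),
    class = "design_config"
  )
}

#' Save a design configuration to YAML
#'
#' Writes the raw (unit-suffixed) values so that
#' `load_config(save_config(cfg, f))` round-trips to an equal config.
#'
#' @param cfg A `design_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "design_config"))
  raw <- cfg$raw
  # drop NULL-valued budget entries (yaml cannot represent them faithfully)
  raw$budgets <- raw$budgets[!vapply(raw$budgets, is.null, logical(1))]
  yaml::write_yaml(raw, path)
  invisible(path)
}
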