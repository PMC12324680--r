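# Physical description of the coil pair and its discretization into
# filamentary circular loops. All quantities are SI (m, A, ohm) internally;
# display units (mm, mT, uT) appear only at interfaces.

COPPER_RESISTIVITY <- 1.68e-8 # ohm m, annealed copper at 20 C

#' Specify the winding wire
#'
#' Describes the wire a coil is wound from. `diameter` is the packing
#' diameter (insulation included), which sets how many turns fit per layer;
#' `conductor_diameter` is the bare copper diameter, which sets the
#' current-carrying cross-section. For enamelled magnet wire the two differ
#' by the insulation build (e.g. 22 AWG: 0.644 mm conductor packing at
#' roughly 0.71 mm).
#'
#' @param diameter Packing (overall) wire diameter in metres.
#' @param conductor_diameter Bare conductor diameter in metres. Defaults to
#'   `diameter` (uninsulated wire).
#' @param resistivity Conductor resistivity in ohm metres; defaults to
#'   copper.
#' @return An object of class `wire_spec`.
#' @export
#' @examples
#' wire_spec(diameter = 0.71e-3, conductor_diameter = 0.6438e-3)
wire_spec <- function(diameter = 0.71e-3,
                      conductor_diameter = diameter,
                      resistivity = COPPER_RESISTIVITY) {
  stopifnot(
    "wire diameter must be a single positive number" =
      is.numeric(diameter) && length(diameter) == 1 && diameter > 0,
    "conductor diameter must be positive and not exceed the packing diameter" =
      is.numeric(conductor_diameter) && length(conductor_diameter) == 1 &&
        conductor_diameter > 0 && conductor_diameter <= diameter,
    "resistivity must be a single positive number" =
      is.numeric(resistivity) && length(resistivity) == 1 && resistivity > 0
  )
  structure(
    list(
      diameter = diameter,
      conductor_diameter = conductor_diameter,
      resistivity = resistivity
    ),
    class = "wire_spec"
  )
}

#' Specify a multilayer winding
#'
#' One coil of the pair: `n_turns` turns of `wire` wound in square packing
#' on a cylindrical holder of inner radius `inner_radius`, filling an axial
#' width `axial_width`. Turns per layer is `floor(axial_width / diameter)`;
#' the number of layers follows.
#'
#' @param inner_radius Holder inner radius in metres (half the holder inner
#'   diameter).
#' @param axial_width Axial width available for the winding, in metres.
#' @param n_turns Number of turns (integer, >= 1).
#' @param wire A [wire_spec()].
#' @return An object of class `winding_spec` with derived fields
#'   `turns_per_layer` and `n_layers`.
#' @export
#' @examples
#' winding_spec() # the packaged 96-turn, 80 mm-bore winding
winding_spec <- function(inner_radius = 40e-3,
                         axial_width = 16e-3,
                         n_turns = 96,
                         wire = wire_spec()) {
  stopifnot(
    "inner_radius must be a single positive number" =
      is.numeric(inner_radius) && length(inner_radius) == 1 && inner_radius > 0,
    "axial_width must be at least one wire diameter" =
      is.numeric(axial_width) && length(axial_width) == 1 &&
        axial_width >= wire$diameter,
    "n_turns must be a single integer >= 1" =
      is.numeric(n_turns) && length(n_turns) == 1 && n_turns >= 1 &&
        n_turns == round(n_turns),
    inherits(wire, "wire_spec")
  )
  turns_per_layer <- floor(axial_width / wire$diameter)
  structure(
    list(
      inner_radius = inner_radius,
      axial_width = axial_width,
      n_turns = as.integer(n_turns),
      wire = wire,
      turns_per_layer = as.integer(turns_per_layer),
      n_layers = as.integer(ceiling(n_turns / turns_per_layer))
    ),
    class = "winding_spec"
  )
}

#' Specify a coaxial coil pair
#'
#' Two identical windings on a shared axis, mirror-symmetric about the
#' midplane, carrying equal co-directed current. The default geometry is the
#' packaged design: 96 turns of 0.71 mm wire on an 80 mm bore, centroid
#' spacing 43.4 mm.
#'
#' @param winding A [winding_spec()]; both coils are identical.
#' @param spacing Centroid-to-centroid separation along the axis, in metres.
#' @param current Drive current in amperes (equal in both coils).
#' @return An object of class `coil_pair`.
#' @export
coil_pair <- function(winding = winding_spec(),
                      spacing = 43.4e-3,
                      current = 1) {
  stopifnot(
    inherits(winding, "winding_spec"),
    "spacing must be a single positive number" =
      is.numeric(spacing) && length(spacing) == 1 && spacing > 0,
    "current must be a single finite number" =
      is.numeric(current) && length(current) == 1 && is.finite(current)
  )
  structure(
    list(winding = winding, spacing = spacing, current = current),
    class = "coil_pair"
  )
}

#' @export
print.coil_pair <- function(x, ...) {
  w <- x$winding
  cat(sprintf(
    paste0(
      "<coil_pair> %d turns/coil (%d layers x %d turns), bore radius %.1f mm\n",
      "  wire %.2f mm (conductor %.3f mm), spacing %.1f mm, current %g A\n"
    ),
    w$n_turns, w$n_layers, w$turns_per_layer, w$inner_radius * 1e3,
    w$wire$diameter * 1e3, w$wire$conductor_diameter * 1e3,
    x$spacing * 1e3, x$current
  ))
  invisible(x)
}

# Relative axial offsets (m, about the winding centroid) of the turns of one
# winding. Full layers are centered; the partial last layer fills from the
# `start` end (-1: the more negative offsets first).
winding_axial_offsets <- function(winding, start = -1) {
  tpl <- winding$turns_per_layer
  n <- winding$n_turns
  t <- winding$wire$diameter
  counts <- c(rep(tpl, winding$n_layers - 1), n - (winding$n_layers - 1) * tpl)
  slots <- ((seq_len(tpl) - 0.5) - tpl / 2) * t
  unlist(lapply(counts, function(m) {
    if (start < 0) slots[seq_len(m)] else rev(slots)[seq_len(m)]
  }))
}

#' Discretize a coil pair into filamentary loops
#'
#' Each turn becomes one circular filament at its wire center: layer `j`
#' sits at radius `inner_radius + (j - 1/2) * diameter`, and the turns of a
#' layer fill the winding width in square packing. The partial last layer
#' fills from the end of each winding farther from the midplane, mirrored
#' between the two windings so the pair is exactly mirror-symmetric about
#' the midplane.
#'
#' @param pair A [coil_pair()].
#' @param max_layers Reject geometries needing more than this many layers
#'   (guards against inconsistent specs such as a winding width far too
#'   small for the turn count).
#' @return A tibble with one row per loop: `loop`, `coil` (`"A"`/`"B"`),
#'   `radius` and `axial_offset` in metres, and `current` in amperes.
#' @export
#' @examples
#' loops <- discretize_winding(coil_pair())
#' nrow(loops) # 192 filaments for the 96-turn pair
discretize_winding <- function(pair, max_layers = 25) {
  stopifnot(inherits(pair, "coil_pair"))
  w <- pair$winding
  if (w$turns_per_layer < 1) {
    stop("winding width is narrower than one wire diameter; nothing fits")
  }
  if (w$n_layers > max_layers) {
    stop(sprintf(
      "geometry needs %d layers (> max_layers = %d); turn count and winding width are inconsistent",
      w$n_layers, max_layers
    ))
  }
  counts <- c(
    rep(w$turns_per_layer, w$n_layers - 1),
    w$n_turns - (w$n_layers - 1) * w$turns_per_layer
  )
  radii <- rep(
    w$inner_radius + (seq_len(w$n_layers) - 0.5) * w$wire$diameter,
    times = counts
  )
  rel <- winding_axial_offsets(w)
  half <- pair$spacing / 2
  tibble::tibble(
    loop = seq_len(2L * w$n_turns),
    coil = rep(c("A", "B"), each = w$n_turns),
    radius = c(radii, radii),
    # winding B mirrors winding A about the midplane
    axial_offset = c(-half + rel, half - rel),
    current = pair$current
  )
}

#' Total wire length of the pair
#'
#' Sum of the circumferences of all filamentary loops, plus an optional
#' lead length.
#'
#' @inheritParams discretize_winding
#' @param lead_length Extra straight wire (leads), metres.
#' @return Length in metres.
#' @export
wire_length <- function(pair, lead_length = 0) {
  stopifnot(lead_length >= 0)
  loops <- discretize_winding(pair)
  sum(2 * pi * loops$radius) + lead_length
}

#' Predicted DC resistance of the series pair
#'
#' `rho * L / A` with the conductor cross-section from the wire's bare
#' diameter and the wound length from the discretization. Compare against a
#' measured resistance; the prediction ignores temperature rise and contact
#' resistance.
#'
#' @inheritParams wire_length
#' @return Resistance in ohms.
#' @export
#' @examples
#' resistance_from_geometry(coil_pair(winding_spec(
#'   wire = wire_spec(0.71e-3, conductor_diameter = 0.6438e-3)
#' )))
resistance_from_geometry <- function(pair, lead_length = 0) {
  wire <- pair$winding$wire
  area <- pi * (wire$conductor_diameter / 2)^2
  wire$resistivity * wire_length(pair, lead_length) / area
}
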