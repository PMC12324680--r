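# helmcoil

Design computations for water-cooled Helmholtz coil pairs used to expose
cultured cells to weak, uniform magnetic fields inside an incubator —
together with the image-analysis readout such experiments need: a
structure-tensor score of cytoskeletal fiber alignment and the rank-based
statistics to compare exposed and control cell populations.

It is written for two audiences: instrument builders who need to predict
the field, homogeneity, electrical behavior and thermal safety of a coil
pair before winding it, and cell biologists who need a reproducible,
scriptable alignment score for fluorescence micrographs of F-actin.

## What it computes

**Field model.** Each multilayer winding is discretized into filamentary
circular loops (square packing). The field of a loop of radius
*a₀* carrying current *i*, at axial distance *x* and radial distance *r*,
is the classical closed form in complete elliptic integrals *K(k)*,
*E(k)*:

    Ba = B₀/(π√Q) · [ E(k) (1 − α² − β²)/(Q − 4α) + K(k) ]
    Br = B₀ γ/(π√Q) · [ E(k) (1 + α² + β²)/(Q − 4α) − K(k) ]

with α = r/a₀, β = x/a₀, γ = x/r, Q = (1+α)² + β², k² = 4α/Q and
B₀ = μ₀ i/(2a₀); on the axis the exact on-axis formula is used. Pair
fields are superpositions over all loops; the implementation is verified
in the test suite against an independent segment-sum Biot–Savart line
integral to 10⁻⁶ relative accuracy. On top of this sit field maps over a
culture-dish region, a homogeneity report (maximum axial deviation from
the centre value; maximum radial magnitude), the Helmholtz-spacing
optimizer (spacing = coil radius for a filamentary pair), RL step
response and switching-frequency limits, impedance matching, coolant heat
balance, and Magnus-formula dew-point condensation safety.

**Alignment readout.** A grayscale image is reduced to per-pixel
structure-tensor components (Gaussian-derivative gradients, Gaussian
window); the alignment score is 100 × the energy-weighted mean coherency
over foreground pixels — 0 % for isotropic textures, approaching 100 %
for parallel fibers. Groups of per-image scores are compared with a
two-sided Mann–Whitney U test (exact for small tie-free samples), and
fluorescence ratios carry compound-error propagation. A seeded synthetic
generator renders fiber images with axial von Mises orientation
concentration κ, so the whole pipeline is testable without microscope
data.

## Worked example

```r
library(helmcoil)

cfg <- load_config(system.file("extdata", "table1.yaml", package = "helmcoil"))
full_report(cfg)
#> <design_report>
#>   field:   center 2.0004 mT, mean 1.9891 mT (ideal filament pair 1.9890 mT)
#>            divergence: axial 34.53 uT, radial 18.33 uT over 42383 points
#>   circuit: tau 0.318 ms, f_max 7 Hz, drive 2.740 V at the operating point
#>   thermal: 2.74 W, coolant dT 0.0394 K, dew point 27.95 C, condensation-safe
current_for_field(cfg$pair, 480e-6)
#> [1] 0.2399656
```

The report says: at 1 A the as-built pair produces about 2.00 mT at the
dish centre (the ideal filamentary Helmholtz closed form gives 1.99 mT),
varying by ~35 μT axially and ~18 μT radially over a 35 mm dish volume;
the RL time constant is 0.32 ms and a measured 130 ms on/off toggle
limits square-wave switching to 7 Hz; the 2.74 W dissipated at 1 A warms
1 L/min of cooling water by under 0.04 K, and a 30 °C coolant stays above
the 27.95 °C dew point of 37 °C / 60 % RH incubator air, so no
condensation forms. A 480 μT cell exposure needs 0.24 A.

The image pipeline, end to end on synthetic data:

```r
imgs <- lapply(1:6, function(s) synthesize_fibers(kappa = if (s <= 3) 8 else 0, seed = s))
names(imgs) <- sprintf("cell%02d", 1:6)
scores <- alignment_scores(imgs)
scores
#>   image_id score n_pixels_used
#> 1   cell01  90.4         20402
#> 2   cell02  89.8         20402
#> 3   cell03  89.4         20402
#> 4   cell04  28.1         20402
#> 5   cell05  30.0         20402
#> 6   cell06  26.4         20402
glance(mann_whitney(scores$score[1:3], scores$score[4:6]))
#>   U p_value ratio_of_medians exact                method
#> 1 9     0.1              3.2  TRUE Mann-Whitney U, exact
```

Concentrated-orientation images (κ = 8) score ~90 %, isotropic ones
(κ = 0) ~28 %; with three images per group the exact two-sided
Mann–Whitney p bottoms out at 0.1 (U = 9 is complete separation).

A thin CLI wraps the same functions
(`inst/cli/biocoil design|fieldmap|homogeneity|circuit|thermal|dewpoint|align|simulate-fibers`).

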