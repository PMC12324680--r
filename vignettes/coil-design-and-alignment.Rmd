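---
title: "Coil-pair design computations and the fiber-alignment readout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coil-pair design computations and the fiber-alignment readout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helmcoil)
```

helmcoil models a water-cooled Helmholtz coil pair built for weak-field
bioelectromagnetics experiments inside a cell incubator, and implements
the image-analysis readout used downstream of such exposures: a
structure-tensor fiber-alignment score with rank-based group statistics.
This vignette documents the models, their assumptions, the tunable
parameters and their defaults, the numerical choices, and what the
package's synthetic data can and cannot tell you about real experiments.

## The field model

A multilayer winding is replaced by filamentary circular loops, one per
turn, each at its wire centre. For a loop of radius $a_0$ carrying
current $i$, the field at axial distance $x$ and radial distance $r$ is
the classical elliptic-integral closed form,
$$B_a = \frac{B_0}{\pi\sqrt{Q}}\left[E(k)\frac{1-\alpha^2-\beta^2}{Q-4\alpha}+K(k)\right],
\qquad
B_r = \frac{B_0\,\gamma}{\pi\sqrt{Q}}\left[E(k)\frac{1+\alpha^2+\beta^2}{Q-4\alpha}-K(k)\right],$$
with $\alpha=r/a_0$, $\beta=x/a_0$, $\gamma=x/r$,
$Q=(1+\alpha)^2+\beta^2$, $B_0=\mu_0 i/2a_0$ and elliptic parameter
$k^2=4\alpha/Q$. Two conventions deserve a note:

* **Elliptic argument.** Published transcriptions of this formula often
  garble whether $k$ or $k^2$ equals $4\alpha/Q$. We use
  $k^2 = 4\alpha/Q$ and settle the question not by transcription but by
  an independent oracle: the test suite sums $2\times10^4$ straight
  Biot–Savart segments around the loop and requires agreement to
  $10^{-6}$ relative at 100 random off-filament points. The elliptic
  integrals themselves come from `pracma::ellipke`.
* **On-axis branch.** For $r < 10^{-12}$ m the exact on-axis expression
  $B_a = \mu_0 i a_0^2 / 2(a_0^2+x^2)^{3/2}$, $B_r = 0$ is used, which
  avoids the $\gamma = x/r$ overflow and makes the on-axis radial field
  an exact zero rather than a rounded one. Points within $10^{-9}$ m of
  the filament raise an error: the field is genuinely singular there and
  no answer is better than a large wrong one.

Everything internal is SI (T, m, A); millimetres, millitesla and
microtesla appear only in interfaces (configs, CSV/JSON exports,
printing).

### Discretization choices

Turns pack squarely: `floor(width / wire_diameter)` turns per layer
(22 for the packaged design's 16 mm width and 0.71 mm wire), layer $j$
at radius `inner_radius + (j − ½) · wire_diameter`. The packaged 96-turn
winding therefore has four full layers and a partial fifth of 8 turns.
The partial layer is placed at the end of each winding *away* from the
midplane, mirrored between the two windings: with any other deterministic
choice the pair would not be exactly mirror-symmetric, and the exact
zero of $B_r$ at the centre — a structural property the tests pin down —
would hold only approximately. Square rather than hexagonal packing
slightly overestimates the winding depth; the error is absorbed in the
advisory tolerances quoted below.

The wire carries two diameters: the packing diameter (insulation
included, 0.71 mm), which sets the geometry, and the bare conductor
diameter (0.6438 mm for 22 AWG), which sets the resistance. Conflating
them underestimates the winding resistance by ~20 %. With the conductor
diameter, $\rho L/A$ over the ~50.1 m of wound wire predicts 2.59 Ω for
the series pair, about 5 % below the measured 2.74 Ω — leads, contact
resistance and temperature account for the gap.

### Homogeneity and its strong dependence on the assumed volume

`homogeneity()` reports the *axial divergence* — the maximum absolute
deviation of $B_a$ from its value at the region centre — and the
*radial divergence*, the maximum $|B_r|$, both uniformity metrics over a
sampled region (not the vector-calculus operator). The default region
for headline numbers is a cylinder of radius 17.5 mm (a 35 mm culture
dish) and height 5 mm (approximate medium depth) centred on the
midplane, sampled at 0.5 mm: a flat midplane disk would report exactly
zero radial divergence by symmetry, so any nonzero radial figure implies
a volume.

Two facts matter when comparing such figures across sources:

```{r divergence-vs-radius}
pair <- coil_pair() # the packaged as-built design at 1 A
for (rad in c(10e-3, 12.5e-3, 17.5e-3)) {
  hm <- homogeneity(field_map(pair, sample_region(
    "cylinder", radius = rad, height = 5e-3, grid_step = 0.5e-3
  )))
  cat(sprintf("radius %4.1f mm: axial %5.2f uT, radial %5.2f uT\n",
              rad * 1e3, hm$axial_divergence * 1e6,
              hm$radial_divergence * 1e6))
}
```

First, the divergences grow steeply (roughly quadratically, then
quartically) with region radius, so a homogeneity figure is meaningless
without its volume. Second, the as-built pair is slightly *over-spaced*:
the coils sit 43.4 mm apart — the builders' round number for "the coil
radius" — while the current-weighted mean winding radius on the 80 mm
holder bore is only ≈ 41.6 mm. The residual quadratic axial curvature
this detuning leaves behind dominates the divergence over dish-sized
regions. Even a perfectly tuned filamentary pair at radius = spacing =
43.4 mm retains tens of μT of variation over the full 17.5 mm × 5 mm
cylinder:

```{r ideal-pair-divergence}
a <- 43.4e-3
cyl <- sample_region("cylinder", radius = 17.5e-3,
                     height = 5e-3, grid_step = 0.5e-3)
ideal <- function(x, r) {
  f1 <- loop_field(a, 96, x - a / 2, r)
  f2 <- loop_field(a, 96, x + a / 2, r)
  tibble::tibble(Ba = f1$Ba + f2$Ba, Br = f1$Br + f2$Br)
}
grid <- helmcoil:::region_grid(cyl)
f <- ideal(grid$x, grid$r)
c(axial_uT = max(abs(f$Ba - ideal(0, 0)$Ba)) * 1e6,
  radial_uT = max(abs(f$Br)) * 1e6)
```

Single-digit-μT uniformity claims for a coil pair of this size are
therefore only consistent with a region of roughly 10–12 mm radius (or
with line profiles along the axes); over the full dish volume this
model — and any filamentary model of the same envelope — computes
roughly an order of magnitude more. The package reports what the stated
geometry implies and prints the region alongside, rather than tuning
either to match external figures.

`helmholtz_spacing()` finds the separation zeroing the on-axis second
derivative for a filamentary pair by root-finding on the analytic
curvature (the answer is the loop radius, to the $10^{-6}$ relative
solver tolerance, across at least three decades of radius); a
`"distributed"` variant minimises the axial divergence of a real winding
over a stated region, which lands near the mean winding radius rather
than the nominal spacing.

## Electrical model

The drive circuit is a series RL with measured parameters
($R = 2.74\ \Omega$, $L = 870\ \mu$H, $V = 2.75$ V by default, i.e.
1 A asymptotic current): step response $(V/R)(1-e^{-tR/L})$ with
$\tau = L/R \approx 0.32$ ms, impedance $|Z| = \sqrt{R^2+(2\pi f L)^2}$
and matching voltage $V = i|Z|$. The full on/off toggle time is treated
as a *measured input* (130 ms for the packaged design), not something
derivable from $R$ and $L$ — it is ~400 time constants, i.e. dominated
by the supply. The admissible square-wave frequency is
`floor(1/toggle_time)`, the most conservative whole-number rate whose
period accommodates the toggle; 130 ms gives 7 Hz.

Two Table-quantity interpretations are deliberate and recorded here
because the source labels are ambiguous: the measured resistance and
voltage drop are taken as *series-pair* values (they are Ohm's-law
consistent at 1 A: 2.75 V / 2.74 Ω), whereas the measured 870 μH is
taken as *per coil*, because Wheeler's multilayer formula on one winding
predicts ≈ 1.18 mH (within its ±30 % class, ratio 1.35) while any
series-pair interpretation would be off by a factor ≥ 2.7.
`estimate_inductance()` is advisory only and never replaces a measured
value.

## Thermal and condensation model

Heat: worst case, all $i^2R$ enters the cooling water, so the steady
rise is $\Delta T = P/\dot m c_p$ with $\dot m$ from the volumetric
flow. At 1 A and 1 L/min this is 0.039 K — comfortably under the 0.1 K
resolution of a dish-side thermocouple. The 1 L/min default flow and
30 °C supply are package defaults (the as-built values are not
published); 30 °C is chosen to clear the dew point below.

Condensation: the dew point uses the Magnus relation with the
Sonntag 1990 constants $a = 17.62$, $b = 243.12\ °C$,
$T_d = b\gamma/(a-\gamma)$, $\gamma = \ln(\mathrm{RH}/100)+aT/(b+T)$.
At 37 °C and 60 % RH this gives 27.95 °C, hence the design rule that
coil-enclosure surfaces must stay above ≈ 28 °C inside an incubator. The
fit is exact at saturation ($T_d = T$ at 100 % RH) and accurate to a few
hundredths of a degree over incubator conditions, far inside the margin
any sane design would leave.

## The fiber-alignment readout

`structure_tensor()` computes Gaussian-derivative gradients at scale
$\sigma_g$ (default 1 px), forms $g_x^2, g_xg_y, g_y^2$, and averages
them with a Gaussian window $\sigma_w$ into per-pixel tensor components
$J_{xx}, J_{xy}, J_{yy}$. From these: the structure orientation
$\theta = \tfrac12\operatorname{atan2}(2J_{xy}, J_{xx}-J_{yy}) + 90°$
wrapped to $(-90°, 90°]$ (along the fibers; pinned by a test on
rendered fibers of known angle), the coherency
$\sqrt{(J_{yy}-J_{xx})^2+4J_{xy}^2}/(J_{xx}+J_{yy}) \in [0,1]$, and the
energy $J_{xx}+J_{yy}$. Energy below $(10^{-8}\,\max|I|)^2$ is floored
to zero so that flat regions have well-defined zero coherency instead of
FFT roundoff noise.

`alignment_score()` summarises an image as
$100 \times \sum e_p c_p / \sum e_p$ over foreground pixels (energy
above the 50th percentile by default, optionally inside a cell mask,
excluding a $3(\sigma_g+\sigma_w)$-pixel border where replicate padding
biases the filters). The score is exactly invariant to global intensity
scaling and invariant to 90° rotation within 2 %.

**Window scale.** The score's default is $\sigma_w = 8$ px, larger than
the 2 px canonical for per-pixel orientation estimation (which
`structure_tensor()` keeps). The reason is what the score must measure:
with a 2 px window, each window sees a single fiber, which is locally
smooth, so even a completely isotropic fiber network scores ≈ 55 % — the
statistic degenerates into "are fibers locally line-like?", which is
true of any fiber image. At 8 px the window spans several fiber
spacings of the synthetic networks, and the score behaves like an
alignment measure: ≈ 25 % for isotropic networks, ≈ 96 % for
near-parallel ones, strictly increasing in between. Users matching a
specific published workflow should set $\sigma_g$, $\sigma_w$ and the
energy quantile explicitly; all are echoed in the result row.

### The synthetic generator and what passing tests mean

`synthesize_fibers()` renders anti-aliased line segments (Gaussian cross
profile, $\sigma$ = half the fiber width) at uniform random positions
with orientations from an *axial* von Mises distribution — angles are
sampled on the doubled circle (Best–Fisher 1979 sampler, hand-written
since no installed package provides one) with concentration $\kappa$ and
halved, so orientation and orientation + 180° are identified, as for
real fibers. Gaussian background noise is added and intensities clipped
at zero. Defaults — 300 fibers of length 60 px and width 2 px on a
256 × 256 frame, noise SD 0.05 — describe a dense, confluent
stress-fiber network at a realistic labelling noise level; everything is
seeded and bit-reproducible.

The generator emulates the *geometry* of fluorescent F-actin images:
bright anisotropic ridges, orientation dispersion under a single
concentration knob, crossings, Poisson-ish clutter. It does **not**
emulate cell boundaries or masks, intensity variation along fibers,
out-of-focus blur, photobleaching gradients, nuclei or other organelle
signal, or fiber curvature. Tests passing on these images therefore
demonstrate the *pipeline's* correctness and parameter-recovery
behavior (score monotone in $\kappa$, Spearman ρ ≥ 0.9 across
$\kappa \in \{0,1,2,4,8,1000\}$ averaged over 10 seeds), not that any
particular biological score value will reproduce: real whole-cell scores
depend on masking, magnification and window choices.

### Group statistics

`mann_whitney()` is a two-sided Mann–Whitney U with the conventions
stated explicitly (the field's software often leaves them implicit):
midranks for ties; exact enumeration when the smaller group has ≤ 8
observations and the pooled sample is tie-free; otherwise the normal
approximation with tie correction and continuity correction. The exact
branch is verified in the tests against a hand-written full-enumeration
oracle, and the normal branch must agree with enumeration within 0.02
at $n = 8 + 8$. Degenerate input (all pooled values identical) returns
$p = 1$ with a warning rather than NaN. Results carry broom-style
`tidy()` (per-group n, median, mean, SD — the quantities a truncated
violin plot displays; see `autoplot()`) and `glance()` (U, p, ratio of
medians) methods.

`fluorescence_ratio()` propagates first-order compound error on a ratio
of means, and `combine_ratios()` pools replicate ratios by
inverse-variance weighting with the propagated SD — the standard choice
when replicates come with heterogeneous uncertainties; it requires
strictly positive SDs and errors otherwise rather than silently
degenerating.

## Problem sizes and runtime

The shipped tests and the acceptance script use the full 0.5 mm dish
lattices (3,853 points for the midplane disk, 42,383 for the cylinder —
deduplicated internally to unique $(x, r)$ pairs by axisymmetry, which
makes the dense maps take about a second), 100-point oracle comparisons
at $2\times10^4$ segments, and 60 default-size synthetic images for the
monotonicity property. The whole suite runs in about a minute on one
core.

## Known limitations

* Filamentary loops ignore the finite wire cross-section and any
  magnetic or eddy-current response of the surroundings (enclosure,
  incubator walls); these effects are sub-percent at the fields and
  frequencies involved but are not modelled.
* The thermal model is a lumped worst case; it brackets, not predicts,
  the winding temperature. The advisory surface-temperature path through
  a convection coefficient is deliberately not exposed as a headline
  number.
* The inductance estimate is a Wheeler-class approximation (±30 %) and
  neglects the mutual inductance of the pair.
* The alignment score is one defensible reduction of the orientation
  field; workflows built on orientation-histogram dispersion will give
  systematically different numbers on the same images.
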