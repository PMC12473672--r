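---
title: "Models and methods: duckweed frond light acclimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: duckweed frond light acclimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frondscape)
```

# The problem

Duckweeds acclimate to ambient light in the few days it takes a frond to
emerge from its mother's meristematic pocket and mature. Whether that
acclimation is a conserved process or varies among clones of the same
species is a question at three scales: culture-level growth, frond-level
morphology and pigments, and pixel-level photochemistry along the
base-to-tip axis of individual fronds. `frondscape` implements the
quantitative workflow for all three, driven by a synthetic-data
generator whose ground truth makes every stage testable by parameter
recovery.

# Growth and morphometric indices

Frond number grows exponentially, so the relative growth rate is
estimated as `RGR = (ln FN7 - ln FN0) / t` from two counts `t` days
apart (`t` comes from the day fields, not a hard-coded 7). Doubling
time is `ln 2 / RGR`. Colony size is `FN/CN`, senescence the percentage
of fronds with any yellowing, frond area the ellipse `a * b * pi` from
half-length and half-width, and FMA the dry mass per projected area
(mg cm^-2). The two light regimes are summarised by their daily light
integrals, `PPFD * photoperiod * 3600 / 1e6` mol m^-2 d^-1 — 8.64 and
21.00 for 100 and 243 umol m^-2 s^-1 under the continuous (24 h)
photoperiod used here.

Assumptions: counts are censuses (no detection error model), and
morphometric sampling uses a fixed number of representative mature
fronds per vessel, averaged on a vessel basis before statistics.

# Fast (OJIP) fluorescence kinetics

A fast transient is summarised by landmarks at the standard JIP-test
times — F0 at 50 us, F300 at 300 us, FJ at 2 ms, FI at 30 ms, Fm at the
global maximum — extracted by linear interpolation in log-time, where
transients are near piecewise linear. Landmark times are arguments, not
constants, because instruments differ. The derived chain is

* phi_Po (Fv/Fm) = (Fm - F0)/Fm, Vj = (FJ - F0)/(Fm - F0),
  Mo = 4 ms^-1 (F300 - F0)/(Fm - F0), Sm = Area/(Fm - F0)
* TRo/RC = Mo/Vj, ABS/RC = TRo/RC / phi_Po, ETo/RC = TRo/RC (1 - Vj),
  DIo/RC = ABS/RC - TRo/RC
* PI_abs = (phi_Po Vj / Mo) (phi_Po/(1 - phi_Po)) ((1 - Vj)/Vj)

with Area the complementary area between the transient and the Fm
plateau up to the time of Fm, in AU·ms to match the per-ms convention
of Mo. Conservation (ABS/RC = TRo/RC + DIo/RC) is asserted on outputs,
and the whole chain is cross-checked against an independently coded
re-derivation on random landmark sets.

One naming caveat: this pipeline reports `phi_pav` as the *time needed
to reach maximal fluorescence in ms*, following the instrument-table
reading adopted throughout the workflow. Standard JIP nomenclature uses
Phi_Pav for an average yield; the deliberate mismatch is flagged in the
function documentation so downstream users do not mistake the unit.

# Quenching partition and rapid light curves

Slow-kinetics records partition absorbed excitation into
Y(II) = (Fm' - F)/Fm', Y(NO) = F/Fm and Y(NPQ) = F/Fm' - F/Fm, which sum
to 1 algebraically; the closure is still asserted to 1e-9 on every
record and to 1e-6 on every imaged pixel, as a guard against data
corruption rather than algebra. ETR = Y(II) × PPFD × 0.5 × 0.84 with the
conventional even photosystem split and 0.84 absorptance, both exposed
as arguments (nominal actinic intensities for imaging records default
to 81/231 umol m^-2 s^-1 for low/high-light samples).

Rapid light curves (13 steps, 0–700 umol m^-2 s^-1) are fitted with the
exponential rise to maximum `ETR(I) = a (1 - exp(-b I))`, reported as
rETRmax = a, alpha = a·b (the derivative at zero irradiance) and
Ek = 1/b. Positivity is enforced by fitting log-parameters;
initialisation uses the maximal observed ETR and the first non-zero
secant slope, with up to 5 perturbed restarts on non-convergence. The
fit is performed on ETR by default; fitting relative ETR (without the
0.5·0.84 factors) only rescales `a` and leaves alpha/Ek interpretation
intact, so the formula constants are passed through rather than baked
in.

# Pigments

Extract absorbances at 663.2, 646.8 and 470.0 nm are corrected by the
750 nm turbidity reading and decoded with the Wellburn 80%-acetone
coefficient set for 0.1–0.5 nm spectral resolution (Chl a = 12.25
A663.2 − 2.79 A646.8; Chl b = 21.50 A646.8 − 5.10 A663.2; Car = (1000
A470 − 1.82 Chl a − 85.02 Chl b)/198, ug/mL), then rescaled to a fresh
mass basis. The equations are held as a 3×3 matrix whose invertibility
is checked on construction; the synthetic generator inverts the same
matrix, giving an exact round-trip oracle. The trace ammonia in the
extraction solvent is treated as not altering the coefficients.
Xanthophyll ratios follow their definitions: VAZ/Car, Z/VAZ (flagged
undefined, not zero, when the VAZ pool is empty), Chl a/b and
Car/Chl a+b — the latter on whatever basis (molar or mass) the inputs
carry, since the composition tables are consumed, not produced.

# The synthetic generator

The generator emulates the study's measurement structure with known
truth:

* **Counts** — Poisson around the exponential mean (noise-free mode:
  rounded expectations); colony counts binomial with mean FN/3,
  matching typical colony sizes of ~3 fronds; senescence binomial with
  a rate ramping to ~5% by day 7.
* **OJIP transients** — monotone piecewise-cubic (Hyman) interpolation
  in log-time through the landmark knots, flat before 50 us and after
  the 0.3 s maximum. This guarantees landmark exactness and
  monotonicity without asserting unmodelled kinetics between steps.
  Canonical times are included in the sample grid so noise-free
  landmark re-extraction is exact.
* **RLCs** — the saturating exponential plus Gaussian noise (2% of
  rETRmax in the pipeline defaults), with Y(II) back-computed through
  the ETR formula.
* **Imaging scenes** — non-overlapping rotated ellipses on a 640×480
  canvas at 4.6 px mm^-1, background sentinel −1. Within-frond Y(II)
  follows a logistic maturation in frond length with an additive
  basipetal ramp: `YII(u, L) = yii_young + (yii_mature − yii_young)
  logistic((L − l50)/s) + g (u − 0.5) logistic((L − l50)/s)`, with
  l50 = 2.75 mm (the middle of the 2.5–3 mm range where the apical
  high-performance zone appears), s = 0.4 mm and gradient amplitude
  g = 0.05–0.08. Both a length trend and a base-to-tip gradient are
  observed in this system, but no functional form is established, so a
  logistic — the simplest saturating curve with an onset — was chosen
  once and not revisited. Frond lengths are drawn uniformly from
  1.1 mm to ~5% above the clone's mature mean so regressions have
  leverage across the imaged size range. Y(NPQ) is a fixed clone
  share of 1 − Y(II) and Y(NO) the remainder, so closure holds by
  construction even after Y(II) noise.
* **Default design** — 4 clones × 2 lights with RGR 0.36–0.55 day^-1,
  mature Y(II) 0.66–0.68 (low light) vs 0.54–0.56 (high light),
  young-frond Y(II) 0.51–0.61 vs 0.43–0.48, higher rETRmax/FMA and
  lower chlorophyll under high light — the value ranges this study
  system exhibits.

What the generator does **not** emulate: frond texture and gibbosity
(3-D inflation), roots, optical blur, mother–daughter colony geometry
(fronds are rendered independently since the imaging arrangement of
colonies is not standardised), instrument-specific normalisations, and
detection error in counting. Passing tests therefore demonstrate that
the analysis stages recover known parameters under idealised geometry
and Gaussian/Poisson noise — not that they are robust to segmentation
errors or optical artefacts in real images.

# Imaging analysis choices

Transects are straight segments from base to tip anchor (fronds are
near-elliptical and transects are drawn as lines in practice), sampled
at 1-px steps with nearest-pixel lookup, restricted to the frond's own
label; crossings of background are flagged as gaps, not interpolated.
Positions are Euclidean pixel distances from the base, converted at
4.6 px mm^-1. Fronds shorter than 6 px (1.30 mm) are excluded — the
resolution floor below which a transect carries too few pixels.

The ontogeny map pools pixels into equal-count frond-size classes
(default 8, ties broken by frond id) by 0.25-mm position bins; cells
beyond a frond's length stay empty, giving the triangular occupied
region, and overlapping pixels reduce by their median (robust to the
skewed tails of yield distributions). Top size classes with fewer than
3 fronds are dropped (at most 2). A tensor-product spline smooth is
fitted over occupied cells for display only; empty cells are never
extrapolated, and all quantitative statements use the raw median grid.

# Statistics

The decision cascade reproduces the standard comparison protocol:
median-centred Levene (Brown–Forsythe) and Shapiro–Wilk checks — the
latter on model residuals, the statistically standard target, since raw
responses mix factor means — with natural-log transformation when
either rejects at alpha = 0.05. The two-way ANOVA uses the balanced
sequential decomposition (types coincide on balanced designs;
unbalanced input triggers a warning), with
`omega^2 = (SS − df·MS_err)/(SS_tot + MS_err)` reported unclamped
(negative values are informative for null terms), and 0 by convention
on all-constant data. Branches: interaction → per-light one-way
ANOVAs; clone main effect only → pooled clone comparison (one-way
ANOVA, or Kruskal–Wallis in pigment mode with its smaller n = 4);
light main effect → per-clone two-sample F- and t-tests. Post hoc
pairwise p-values are Bonferroni-multiplied by the number of pairs in
the executed branch (6 for 4 clones). Degenerate subgroups yield NA
p-values rather than aborting the cascade. Ontogeny light contrasts
use a common-slope ANCOVA (`response ~ length + light`) on
frond-averaged data.

# Problem sizes and verification

The test suite and the acceptance script run the generator-based
checks at desk scale: 10^4 random quenching records plus a 25-frond
scene for closure; 100 random landmark sets against the JIP oracle; 50
random balanced tables against the brute-force ANOVA decomposition;
200 noisy RLC fits (median relative error of alpha and rETRmax ~2%,
bound 5%); 20 seeds × 30-frond scenes for the ontogeny slope and
apical-vs-basal gradient recovery (20/20 on the default truth); and
the full 0.36–0.55 day^-1 RGR round-trip (max error < 0.1%). These
sizes were chosen as the smallest that make the stochastic rates
stable; all are arguments and can be scaled up.

# Known limitations

* The linear ontogeny regression is a first-order summary of a
  saturating maturation curve; its prediction at 1 mm underestimates
  the generator's `yii_young` slightly (~0.41 vs 0.43 on default
  truth) because the logistic is convex at small lengths. The
  calibration checks therefore use a band, not a point.
* Real quenching imports may violate Fm' <= Fm under instrument drift;
  such records are rejected, not corrected.
* The RLC model has no photoinhibition (downturn) term; curves with a
  high-irradiance decline will fit with biased plateaus.
* The cascade treats the two repeated experiments as pooled replicates
  (n = 6), not as a blocking factor; a mixed model is out of scope.
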