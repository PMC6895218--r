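---
title: "Methods: stereological oocyte packing density and fecundity accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stereological oocyte packing density and fecundity accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, the numerical
conventions, and the design choices made where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The estimation problem

Fecundity studies in batch-spawning fishes traditionally count only the
large, late-stage oocytes. Packing-density theory extends counting to
*every* stage — down to previtellogenic oocytes of a few tens of
micrometres — by combining three measurements per female `j` and stage
`i`:

* `Vv_ij`, the fraction of ovary volume occupied by the stage, estimated
  stereologically;
* `k_ij`, the mean shape factor (long/short axis of a prolate spheroid);
* `cODv_ij`, the volume-based mean diameter, corrected for embedding
  shrinkage.

The packing density (oocytes per gram of ovary) is

```
log10(OPD_ij) = log10[ Vv_ij * (1/rho_o) * (1+k_ij)^3 / (8 k_ij) ]
                + C - 3*log10(cODv_ij)
```

and the whole-ovary stage number is `NO_ij = OPD_ij * GWf_j`.

**Interpretation of the constant.** The left-hand side is read as
`log10(OPD)`; the constant `C` is dimensional bookkeeping, not a free
parameter. One oocyte of arithmetic diameter `OD` and shape factor `k`
has short axis `S = 2 OD/(1+k)` and prolate-spheroid volume
`(pi/6) k S^3 = (pi/6) OD^3 * 8k/(1+k)^3` µm³. Dividing the per-gram
ovary volume `(1/rho) * 1e12` µm³ by that volume gives
`OPD = Vv * (1/rho) * (1+k)^3/(8k) * (6/pi) * 1e12 / cODv^3`, whose
log10 matches the display above with `C = 12 + log10(6/pi) = 12.28103…`,
printed as 12.28 in the literature. The package defaults to the printed
constant (`constant_mode = "printed"`) for fidelity to the published
formula and offers `"exact"` for oracle tests; the two differ by the
fixed factor `10^(12.28 - C) ≈ 0.9976`, i.e. about −0.24 %.

**Specific gravity.** `rho_o` is 1.061 g cm⁻³ when the most advanced
oocyte (MAO) is previtellogenic or in nucleus migration and 1.072 g cm⁻³
for cortical-alveoli/vitellogenic MAO. No value exists for hydrated
ovaries; since hydrated oocytes are excluded from packing-density
estimation anyway (their extreme shrinkage and irregular shape defeat
measurement), `specific_gravity("HYO")` falls back to 1.072 *with a
warning* and is configurable — flagged, not silently guessed.

## 2. Stereology

**Volume fractions.** Grid hits are pooled over fields as a ratio of
sums: hits on the component divided by points on sectioned tissue (total
points minus hits on empty space and outside the ovarian wall). The
ratio-of-sums convention (rather than the mean of per-field ratios) is
unbiased when valid-point counts differ between fields. Hits on
"missing oocytes" count in the denominator — they are sectioned tissue —
and are not reassigned to stages.

**Grids.** Two lattices are predefined: 240 points at 77.1 µm spacing
(`grid_a()`) and 370 points at 65.7 µm (`grid_b()`). `select_grid()`
encodes the pilot logic: keep the cheaper grid when paired estimates
agree within a configurable relative tolerance (default 5 %), otherwise
keep the conservative denser grid — the case that matters when small
previtellogenic profiles slip between coarse grid points. The published
pilot reports a significant difference without printing the underlying
tolerance, so the tolerance is configuration, not a constant.

**Field effort.** `stabilization_curve()` reports
`d_n = |cummean_n − mean_N| / mean_N` and the smallest `n` from which
the curve stays within a threshold (±0.05 by default). The pilot finding
that seven fields suffice is reproduced in simulation by
`stabilization_replicates()` (acceptance target t8). Seven fields and
ten measured oocytes per stage are advisory minimums: fewer inputs warn
but compute.

**Shape and size.** Only oocytes sectioned through the nucleus enter
`shape_factor()` and `volume_based_diameter()`; off-nucleus sections
understate both axes. `ODv = (mean OD^3)^(1/3)` is the diameter whose
sphere has the sample's mean volume — by the power-mean inequality it
never falls below the plain mean, which the tests assert.

**Shrinkage.** Embedding shrinks oocytes, and the published pipeline
chooses between externally derived correction factors (resin vs
paraffin) by comparing corrected vitellogenic numbers with whole-mount
batch-fecundity estimates. Those factor values are not printed in the
source this package follows, so `shrinkage_model()` treats coefficients
as user configuration; the default identity model warns loudly every
time it is applied, because an uncorrected diameter biases OPD by the
*cube* of the shrinkage. `compare_correction_models()` implements the
selection logic (mean absolute relative deviation against a reference,
argmin wins, ties keep input order); its signature takes the uncorrected
diameters alongside the uncorrected numbers because a diameter-scale
model must be applied to diameters before its cubic effect on numbers
can be evaluated.

## 3. Synthetic ovaries: what is emulated, and what is not

`simulate_population()` materializes every oocyte: per-stage counts are
exactly `round(true_opd × mass)`; diameters and shape factors are
lognormal with user means and CVs (shape factors truncated at 1); the
per-stage true volume fraction is the exact ratio of summed spheroid
volumes to ovary volume. Specs whose total packing fraction exceeds 0.55
are rejected as geometrically infeasible.

**Placement.** Oocytes are packed as spheres of equal volume by random
sequential adsorption (RSA) in a slab that is **periodic in all three
directions**, then cut by the plane z = 0; a sphere of radius R cut at
distance d leaves a profile of radius `sqrt(R² − d²)`. Two geometric
points matter:

* *Why periodic?* In a hard-walled box, RSA rejection accepts candidates
  more easily near the walls (fewer neighbours there), enriching the
  walls and depleting the interior that the sampling window sees. During
  development this produced a measurable (≈13 % at packing 0.25)
  underestimate of section area fractions. Periodic boundaries restore
  exact translation invariance: each accepted centre is marginally
  uniform and the expected area fraction in the window equals the true
  volume fraction — the Delesse property the generator exists to
  guarantee. The lateral margin of one maximal radius ensures wrapped
  periodic images can never intrude into the window.
* *Jamming.* RSA cannot pack monodisperse spheres beyond a volume
  fraction of ≈0.38 (and placement slows sharply well before). The
  simulated pilot therefore samples true fractions on 0.20–0.32 rather
  than the nominal upper end of dense ovaries; the stabilization
  statistic is a *relative* deviation and does not depend on the level.
  Real ovaries pack tighter than RSA allows; the generator trades that
  realism for exact, provable ground truth.

**Shape.** Spheres are used for 3-D placement; the shape factor `k`
enters only the emitted axis measurements (`S = 2 OD/(1+k)`, `L = kS`,
the equatorial — "through-nucleus" — section) and the analytic volume.
Full triaxial sectioning would add elliptic-profile machinery without
adding test value, since the shape term of the density formula is
exercised analytically.

**Grid counting.** `count_grid_hits()` lays the lattice at a uniform
random offset within one cell and classifies each point as exactly one
component (nearest-centre tie-break; background tissue otherwise), so
hit totals always sum to the point count.

**Cohorts.** `simulate_cohort()` draws capture months uniformly over the
year, phases from a monthly frequency table built around three
contiguous spawning seasons (default SS1 December–May, SS2 June–August,
SS3 September–November — the published account gives only
"winter-spring, summer, autumn", so exact boundaries are configuration),
lengths uniform on 34–84 cm, and eviscerated weight `EW = a·TL^b` with
multiplicative lognormal noise. Defaults: `b = 3.01` (the isometric
scaling observed for the stock), `a = 0.0065` g cm⁻ᵇ (a 60 cm female
weighs ≈1.5 kg eviscerated), noise sd 0.07 log10 units — chosen once so
that the log–log fit attains r² ≈ 0.96, the tightness reported for the
validating regression; with lengths recorded to 0.1 cm the noiseless
limit recovers the exponent exactly to recording precision. Gonad
weights follow phase-dependent linear models in TL with unequal slopes
(ripe ovaries grow faster with length), sized so a spawning-capable
60 cm female carries ≈45 g of ovary.

**True packing densities** per stage and phase
(`default_opd_by_phase()`) are declared synthetic: the real
stage-specific size/density table of the studied stock lives in survey
supplements not reproduced here. The defaults preserve the field's
structure — smallest previtellogenic stages outnumber vitellogenic
stages by an order of magnitude, secondary stages peak at spawning
capability and collapse afterwards, early- and late-vitellogenic
densities match (the premise of the batch-fecundity proxy), and the
pooled-PVO to VTO ratio sits inside the published worked-table envelope.
Each detectable stage lands at a volume fraction of roughly 0.01–0.06.

**Survey rendering.** For whole cohorts, `simulate_survey_data()` draws
grid hits multinomially per field with probabilities equal to the true
stage volume fractions (exactly the sampling model of point counting on
a random section, and the binomial oracle the tests use), modulated by a
between-field density CV (default 0.05) and an empty-space fraction
(default 0.05). The fully geometric render path is exercised by the
tests at small scale; it is the ground-truth instrument, not the bulk
generator. Measurement tables are emitted at the embedded scale through
a true shrinkage model (default multiplicative 0.8, emulating paraffin);
the matching correction is its exact inverse, and feeding the wrong
(identity) correction inflates recovered numbers by `1/0.8³ ≈ 1.95` —
the error the model-comparison operation is designed to catch.

What a green test does **not** establish: realism of ovarian
micro-architecture (lamellae, vasculature), of dense (>0.38) packing, of
stage-size tables for any real stock, or of the biological season
boundaries; those are all configuration or declared-synthetic defaults.

## 4. Standardization

Three routes, as in the published pipeline: raw `NO_i` split into length
classes (half-open `[lo, hi)`, so 64.9 cm belongs to 45–65 and 65.0 cm
to 65–85); `NO_i/TL³` justified by the allometric fit (log base 10
throughout — the base changes `a`, never `b`); and `NO_i/EW` retained as
cross-validation where eviscerated weight exists. The third route models
`GWf ~ phase + TL + phase:TL` by least squares with a slope-homogeneity
F-test and feeds predicted gonad weights into `pNO = OPD × pGWf`. GWf
(formalin-fixed) is the default response, configurable, since the
published text uses fresh and fixed symbols interchangeably.

## 5. Fecundity accounting and phenology

`accumulate_batches()` walks VTO → +EVTO → +CA → +PVO4c → +PVO4b →
+PVO4a → +PVO1-3 (PVO1–3 pooled; nucleus-migration and hydrated oocytes
excluded), with `PF_m = 2·ΣNO_i` unrounded and
`batches_m = round(PF_m/BF)`. Numerical conventions, fixed by matching
every populated cell of the published worked table:

* **Month length 30 days** (62 batches × 4 d / 30 = 8.27 → "8.3";
  80 × 4/30 = 10.67 → "11"); not stated in the source text, derived from
  its arithmetic.
* **Round half up, once, at the cumulative level.** Base R's banker's
  rounding and per-stage rounding both fail to reproduce the printed
  cells; `round_half_up()` at the cumulative level reproduces all of
  them (asserted exhaustively in the tests).
* **Durations: one decimal below ten months, nearest integer from 9.95**
  (9.6 stays "9.6"; 10.13 prints "10"; 10.67 prints "11").
* The factor 2 in `PF` and in per-stage batches encodes the mid-season
  sampling assumption: females sampled across a whole season have, on
  average, already released half their batches.
* The spawning interval (4 days) is exposed as a parameter; the source
  flags it as an untestable constant.

Phenology: spawning fraction is actively-spawning over mature (all
phases except immature; actively-spawning counts as mature), banded
<10 / 10–30 / 30–50 % for display. Season assignment is total — every
record maps to exactly one season — with two boundary overrides:
regenerating/regressing females in a season's first month belong to the
preceding season; developing females without postovulatory follicles in
a season's last month belong to the next, wrapping at the year boundary.
The tests assert the overrides never fire mid-season.

## 6. Numerical and degenerate-input conventions

* `Vv = 0` returns `OPD = 0` without touching the logarithm; zero valid
  grid points is an error, not a zero.
* Batch fecundity with both vitellogenic pools zero is an error
  (downstream ratios are undefined), and `BF ≤ 0` is rejected before any
  division.
* Stages missing from the accumulation ladder count as zero with a
  warning; hydrated-oocyte rows carry a reason code instead of numbers.
* All randomness flows through explicit integer seeds; one master seed
  fans out via `split_seed()` (`set.seed(master)` then `sample.int`),
  keeping every derived seed below 2³¹.
* Every stochastic simulation in the test suite is scaled down from its
  full acceptance size (e.g. 50–60 replicates instead of 200) and says
  so; `scripts/acceptance.R` runs the full sizes.

## 7. Known limitations

* The end-to-end recovery guarantee is about *accuracy of the mean*:
  with 7 × 370 grid points a stage at `Vv = 0.02` carries a binomial
  relative error of ≈14 % per ovary, so single-ovary estimates at the
  detection floor scatter beyond 10 % no matter the implementation; the
  tests therefore check the mean over replicates and the suite documents
  per-replicate degradation below `Vv ≈ 0.05`.
* RSA packing cannot reach truly dense biological packing (see §3); volume
  fractions above ≈0.32 per simulation must be assembled from multiple
  stages or accepted as infeasible.
* Wicksell unfolding (profile-size to particle-size inversion) is out of
  scope; the generator sidesteps it by emitting equatorial measurements.
* Shrinkage-correction coefficients ship empty by design; analyses of
  real material must supply embedding-medium specific values.
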