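---
title: "Models and methods behind hydrolov"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hydrolov}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrolov)
```

`hydrolov` analyzes how the hydration shell of a LOV photosensor domain
reorganizes upon activation. This vignette explains the models each stage
implements, the assumptions behind them, the defaults and why they were
chosen, what the synthetic-data generators do and do not emulate, and the
numerical decisions a maintainer would want recorded.

## Water-structure classification by three-body angles

The order parameter throughout the MD arm is the three-body angle (3BA):
for a central water oxygen, the angle it subtends with every unordered pair
of hydrogen-bonded neighbor oxygens. Its distribution separates the
structural archetypes of liquid water: tetrahedrally coordinated,
low-density water peaks near 109.5°, high-density bulk-like packing shows
the icosahedral adjacent-vertex angle arccos(1/√5) ≈ 63.4°, and water
hydrogen-bonded flat against a surface approaches planar geometry. The
classification windows are wrap 100–120°, icosahedral 50–70°, and bound
150–170°; everything else is "unclassified", so the four fractions always
sum to one.

Two conventions here are deliberate choices where the field has no single
standard, and both are configurable:

* **Hydrogen-bond criterion.** O–O ≤ 3.5 Å *and* at least one of the two
  waters donates a hydrogen within 30° of its O→O axis. This is the common
  geometric definition for 3-site water models; the distance corresponds
  to the first minimum of the O–O radial distribution function.
* **Shell cutoff.** A water belongs to a residue's shell when its oxygen
  is within 4.5 Å of any heavy atom of that residue — a first-shell
  convention. A water may sit in several shells; no partitioning is
  attempted, since the per-residue profiles are read comparatively.

Neighbor sets are capped at the four nearest hydrogen-bonded oxygens,
bounding the per-water angle count at C(4,2) = 6 and matching tetrahedral
coordination. Class fractions are **angle-level** by default — each 3BA is
one vote — because "fraction of tetrahedral water" is a population
statement about angles; a **water-level** majority mode
(`hydration_profile(..., mode = "water")`) is provided because the two
statistics genuinely differ: a tetrahedral cluster casts six votes where
an icosahedral face casts three, so angle-level fractions over-weight
highly coordinated waters. Round-trip tests against generator labels use
the water-level mode for exactly this reason.

Residence times are **first-passage**: for each water × residue pair, the
first continuous run of shell occupancy, measured as occupied frames ×
frame spacing. A water already in the shell at the first frame counts from
that frame (for exponential dwell processes the residual lifetime has the
same distribution, so this introduces no bias); a run still open at the
last frame is discarded rather than truncated; re-entries are ignored.
Sampling at interval `dt` merges in-shell runs separated by excursions
shorter than `dt` and drops visits shorter than `dt`, which biases the
estimate upward by roughly `2 P(dwell_out < dt)` — about +2% at
`dt = mean_dwell/50`, well inside the 10% recovery tolerance the tests
assert.

## Trajectory segmentation

* **SASA** is Shrake–Rupley: per heavy atom, the fraction of `n_points`
  (default 960) Fibonacci-lattice points on the sphere of radius
  r_vdW + probe (Bondi radii, probe 1.4 Å) not buried in any neighboring
  inflated sphere. The deterministic lattice makes results reproducible at
  fixed `n_points`; doubling `n_points` moves a two-sphere test case by
  < 0.5%.
* **Change points** use binary segmentation with an L2 cost and a
  per-breakpoint penalty. The default penalty is 2·σ̂²·log n with σ̂²
  estimated from first differences (mean(diff(x)²)/2), which is robust to
  the very steps being sought. A constant series yields no breakpoints for
  any positive penalty; single-split results equal an exhaustive search
  (tested).
* **Clustering** is the Daura greedy algorithm: repeatedly take the frame
  with the most neighbors within an RMSD cutoff (default 0.2 nm,
  heavy-atom Kabsch superposition) as a cluster center and remove it with
  its neighbors. Ties break to the lowest frame index, making the
  partition order-stable (tested under frame permutation).
* **Residue displacement** removes translation only (common center of
  gravity, here the unweighted heavy-atom centroid) before measuring
  per-residue centroid distances. Translation-only is the default because
  the displacement is defined *relative to the center of gravity* of the
  reference; a Kabsch rotational fit is available (`rotate = TRUE`) since
  either convention is defensible, and on partially unfolded structures
  the rotational fit can hide genuine helix excursions.

## High-pressure chemical-shift analysis

Each (residue, nucleus) series is fit by OLS to δ(p) = a + bp + cp². The
linear coefficient tracks partial-molar-volume changes, the quadratic
coefficient compressibility changes; a residue with c ≠ 0 is read as
shifting toward a pressure-favored state not populated at ambient
pressure. Per nucleus, residues with |c| > mean + 1.645·SD are flagged
(the multiplier captures the top ~10% under a normal model). The composite
score z-sums |c| across nuclei with the carbonyl aligned to residue i−1,
because an HNCO peak correlates amide ¹H/¹⁵N of residue i with ¹³C′ of
i−1. "Normalization" is a per-nucleus z-score of |c| (a robust median/MAD
variant is available via `normalization = "robust"`), putting
ppm-scale-diverse nuclei on one scale; residues missing a nucleus
contribute zero for it and carry a completeness flag, with no imputation.

One caution the tests make explicit: at ~10% prevalence of genuine
nonlinearity, the mean + 1.645·SD threshold is inflated by the signal
itself, so the composite threshold alone sits near 90% sensitivity at
coefficient SNR 5. Detection in the recovery tests therefore counts a
residue that clears *either* the composite or any per-nucleus threshold —
both thresholds are computed and reported precisely because neither alone
is canonical.

## Bulk-suppressed ¹⁷O inversion recovery

The suppression sequence is modeled as a periodic cycle: inversion with
efficiency f ∈ (0.5, 1], delay τ, read pulse θ, recovery until TR. The
steady-state longitudinal magnetization before the read pulse has the
closed form

M⁻ = M₀ [(1−E₁) + (1−2f)(1−E₂)E₁] / [1 − (1−2f) cosθ E₁E₂],

with E₁ = e^(−τ/T₁), E₂ = e^(−(TR−τ)/T₁); the signal is sinθ·M⁻. As
TR/T₁ → ∞ this reduces to the single-shot expression
sinθ(1 − 2f e^(−τ/T₁)), whose zero crossing is τ_zc = T₁ ln 2f. The
closed form is tested to 1e−10 against an iterate-to-convergence
simulation of the sequence. The model reproduces the qualitative
suppression behavior relied on experimentally: at short TR, low flip
angles suppress the slow (bulk) component more selectively than high
ones, because cosθ > 0 carries residual longitudinal magnetization
constructively between cycles for the component the delay was tuned to
null.

The spectral dimension is abstracted away: components enter as
(T₁, amplitude, label) with shift-range labels bound < wrap < bulk in
order of increasing T₁. Inversion efficiency defaults to f = 1; the
experimentally quoted operating delay of a real instrument may correspond
to f < 1 or an empirically located minimum, so τ_zc is treated as a free
setting rather than derived.

Multi-component fitting is nonlinear least squares on log-T₁ with
amplitudes started from a linear solve, multi-started from log-spaced T₁
seeds scaled by {0.5, 1, 2}. **Identifiability is reported, not
assumed**: the fit is flagged non-identifiable when adjacent 95% CIs on
T₁ overlap or when any component's amplitude falls below 2% of the total
(the signature of an over-parameterized exponential sum). This matters
scientifically: a T₁ pair at ratio 1.3 — like the bound/wrap hydration
pair — cannot be separated from a single composite recovery curve at 1%
noise no matter the optimizer, a classic ill-posedness of exponential
analysis; experimentally such pairs are resolved spectrally, fitting each
shift range separately. The tests assert exact recovery of all three
hydration T₁ values from noise-free curves, 5%-accurate recovery of the
well-separated wrap/bulk pair under 1% noise, and the non-identifiability
flag for the close triple under noise.

## DEER two-Gaussian distance analysis

The forward model is V(t) = [1 − λ + λ(KP)(t)]·e^(−kt), with the kernel
K(t,r) = ∫₀¹ cos[(1−3u²)ω(r)t] du, ω(r) = 2πD/r³, and
D = μ₀g²β²/(4πh) ≈ 52.04 MHz·nm³ computed from physical constants at run
time. Orientation averaging uses 201-point Gauss–Legendre quadrature on
u ∈ [0,1]; at the fastest-oscillating corner of the default grid
(r = 1.5 nm, t = 3 µs, ~290 rad of phase) 201 nodes keep the quadrature
error below 1e−10, verified against a ~2.6×10⁵-point trapezoid oracle.
P(r) is two Gaussians on r ∈ [1.5, 8] nm (grid step 0.05 nm), renormalized
on the grid; the background is 3D-homogeneous (pure exponential), the
simplest model consistent with a dilute frozen solution. Fitting is
bounded least squares over (m₁, s₁, m₂, s₂, w₂, λ, k), multi-started over
increasing mean pairs from {2, 2.5, 3, 3.5, 4.5} nm; means within one grid
step of the boundary are flagged. The extended state is reported two ways
— the raw weight of the larger-mean Gaussian and the window-integrated
P(r) mass in 3–5 nm — since quoted extended-state percentages could be
either; for well-separated components they agree to < 0.1%. No
Tikhonov/model-free inversion is provided: the parametric two-Gaussian
model is the published analysis being implemented.

## Kinetics

Photocycle and population recoveries share one model,
a∞ + (a₀ − a∞)e^(−t/τ), fit by Levenberg–Marquardt with τ initialized
from a log-linearized tail fit. Constant series are flagged (`no_trend`)
rather than fit; non-monotone series are fit but flagged (`weak_trend`).
Both τ and the half-time τ·ln 2 are reported for population kinetics
because recovery times are quoted in both conventions. Time-constant
ratios carry delta-method errors (validated against a 10⁵-draw Monte
Carlo); the ratio is additionally rounded to one decimal, the precision at
which slow-photocycle factors are conventionally quoted.

## What the synthetic data emulate — and what they do not

Every generator is a pure function of its spec, including the seed
(`withr::with_seed`, no global RNG state). The geometry generator builds
*clusters*: a central water with neighbors placed exactly at tetrahedral
vertices, an icosahedral face, or a planar arrangement, at an O–O distance
of 2.8 Å, hydrogens on a rigid 3-site geometry (O–H 0.9572 Å, H–O–H
104.52°) oriented so exactly the intended hydrogen bonds fire. Free
hydrogens are steered over a 72-candidate cone away from non-partner
oxygens so no accidental bond forms. Angular jitter rotates neighbor
directions by N(0, jitter²) about random perpendicular axes. `n_waters`
is a budget consumed in whole clusters (5/13/3 waters); the realized count
is recorded.

The telegraph trajectory gives each residue bead an independent pool of
waters alternating between an in-shell and a far position with exponential
dwell times; the stationary in-shell probability is set so the expected
occupancy matches the requested value. The shift-table generator plants quadratic
coefficients in a chosen fraction of residues (all three nuclei); the
relaxometry, DEER, and decay generators run their stage's own forward
models with truth retained.

None of this emulates real MD or spectrometer physics: there are no water
dynamics between classified configurations, no exchange between
populations, no orientation selection or pulse imperfections in DEER, no
lineshapes in ¹⁷O. Passing tests therefore demonstrate that each analysis
stage correctly inverts its own forward model at the stated noise levels,
and that the geometric operators agree with independent oracles — not
that the pipeline would recover these quantities from raw experimental
data, whose artifacts are out of scope.

## Problem sizes and reproducibility

The test suite and the acceptance script are sized to run in about a
minute on one core: geometry round-trips use ~200-water frames; the
telegraph recovery uses 40 residues × 5000 frames × 1 ps (≈360 completed
first visits, putting the Monte-Carlo error of the mean dwell near 2.5%);
planted-signal recovery uses 40 residues × 11 pressures × 3 nuclei over
40–100 seeds; DEER Monte-Carlo uses 50 noise replicates of a 200-point
trace. The demo pipeline writes every stage's CSV/JSON outputs plus a
combined `report.json` that is byte-identical across runs with the same
configuration and seed; the configuration is echoed into the report so any
stage can be re-run from its serialized inputs.

## Known limitations

* Hydrogen-bond and shell-cutoff definitions are declared conventions, not
  derived from the data; profiles shift quantitatively (not qualitatively)
  under reasonable alternatives.
* Angle-level versus water-level fractions differ by construction;
  comparisons across studies must fix the convention.
* The composite nonlinearity threshold is self-inflating at high signal
  prevalence (see above).
* Close T₁ pairs from a single composite curve are fundamentally
  non-identifiable at realistic noise; the flag is the honest output.
* The DEER background is exponential only; excluded-volume or fractal
  backgrounds are not modeled.
* PDB parsing keeps residue numbers verbatim and assumes waters named
  HOH/WAT/SOL/TIP3; crystallographic waters without hydrogens are read
  but cannot enter hydrogen-bond analysis.
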