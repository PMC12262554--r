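# hydrolov

Hydration-shell structure and activation analytics for LOV photoreceptors.

Blue-light photosensor domains of the LOV family (such as the second LOV
domain of *Avena sativa* phototropin 1, AsLOV2, residues 403–546) convert
photon absorption into mechanical actuation: the A′α and Jα helices undock
and the spin-label distance between them grows from ~2.2 nm into the
3–5 nm range. A growing body of evidence ties this transition to a
concerted change in the hydration shell — the eviction of low-entropy,
tetrahedrally coordinated "wrap" water into bulk. Testing that picture
requires a heterogeneous toolchain: water-structure classification from MD
frames, shell residence times, trajectory segmentation, high-pressure NMR
shift analysis, ¹⁷O relaxometry, DEER distance fitting, and photocycle
kinetics. `hydrolov` implements that toolchain as one tested R package,
with a synthetic-data module that generates every input with known ground
truth, so the full pipeline runs and is verifiable without any external
data.

## What the package computes

**Water-shell structure (MD arm).** For each water oxygen, the three-body
angles (3BA) subtended by pairs of hydrogen-bonded neighbor oxygens
(O–O ≤ 3.5 Å and a donor O–H within 30° of the O→O axis, both
configurable). Angles are classified into archetype windows: tetrahedral
*wrap* water (100–120°, ideal 109.47°), icosahedral bulk-like water
(50–70°, ideal arccos(1/√5) = 63.43°), and near-planar *bound* water
(150–170°). Per-residue hydration profiles average class fractions over
shell waters (within 4.5 Å of any residue heavy atom); residence times are
first-passage — a water's first continuous stay in a shell, re-entries
excluded. Residues losing more than half of the mean reference wrap
fraction are flagged.

**Trajectory segmentation.** Shrake–Rupley SASA, penalized binary-segmentation
change-point detection on SASA series, Daura greedy RMSD clustering
(Kabsch superposition), and residue-wise displacement relative to the
center of gravity of a reference structure.

**High-pressure NMR.** Per residue and nucleus (¹H, ¹⁵N, ¹³C′), ordinary
least squares of the chemical shift on pressure, δᵢ(p) = aᵢ + bᵢp + cᵢp²;
|cᵢ| is thresholded at mean + 1.645 SD per nucleus, and a composite
nonlinearity score per peptide group sums the per-nucleus z-scores of
¹Hᵢ + ¹⁵Nᵢ + ¹³C′ᵢ₋₁ (the three nuclei one HNCO peak reports on).

**¹⁷O relaxometry.** Closed-form steady-state signal of the
bulk-suppression sequence (inversion with efficiency *f*, delay τ, read
pulse θ, recovery to TR), zero-crossing τ_zc = T₁ ln 2f and its inverse,
multi-start k-component T₁ decomposition with identifiability flags, and
single-exponential recovery of the wrap/bulk/bound population amplitudes.

**DEER.** The dipolar kernel K(t,r) = ∫₀¹ cos[(1−3u²)·2πD t/r³] du with
D = μ₀g²β²/4πh ≈ 52.04 MHz·nm³, two-Gaussian P(r) forward model with
modulation depth and exponential background, bounded multi-start
least-squares fitting, and the extended-state fraction (P(r) mass in
3–5 nm, plus the raw extended-component weight).

**Kinetics.** Shared single-exponential recovery fitting
(a∞ + (a₀−a∞)e^(−t/τ)) for photocycle and population series, with
delta-method time-constant ratios.

## Worked example

```r
library(hydrolov)

# a synthetic hydration shell: 70% tetrahedral, 30% icosahedral clusters,
# each anchored to a pseudo-residue
frame <- gen_water_geometry(geometry_spec("mixed", 120,
  mix_fractions = c(tetrahedral = 0.7, icosahedral = 0.3),
  anchor_residues = TRUE, seed = 42))
prof <- hydration_profile(frame)
head(prof[, c("residue", "shell_count", "frac_wrap",
              "frac_icosahedral", "frac_bound")], 4)
#>   residue shell_count frac_wrap frac_icosahedral frac_bound
#> 1     119           7         0                1          0
#> 2     120           7         0                1          0
#> 3     121           4         1                0          0
#> 4     122           7         0                1          0
mean(prof$frac_wrap)
#> 0.571

# three-component T1 decomposition of a bulk-suppressed inversion recovery
comps <- data.frame(T1_ms = c(2.21, 7.95, 1.69), amplitude = c(1, 1, 1),
                    label = c("wrap", "bulk", "bound"))
curve <- gen_inversion_recovery(relax_spec(
  comps, delays = exp(seq(log(0.2), log(50), length.out = 25)), seed = 42))
fit_T1_components(curve, k = 3)
#>    label T1_ms amplitude
#> x1 bound  1.69         1
#> x2  wrap  2.21         1
#> x3  bulk  7.95         1
```

Each pure cluster classifies entirely into its archetype window (fractions
1/0/0), and the mean wrap fraction reflects the generator's realized
mixture. The T₁ decomposition recovers the three generating relaxation
times, with the slowest (bulk-like, 7.95 ms) component cleanly separated;
the label order follows the shift-range convention bound < wrap < bulk.

The full demo pipeline (every stage on synthetic inputs, CSV/JSON outputs
plus a combined report):

```r
report <- run_pipeline(run_config(overrides = list(out_dir = "out", seed = 1)))
```

or from a shell via the thin CLI at `inst/cli/hydrolov.R`:

```sh
Rscript inst/cli/hydrolov.R run --seed 1 --out-dir out
```

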