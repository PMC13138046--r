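# fibrilkit

Quantitative analysis of collagen I fibrillogenesis kinetics and
fibril-network architecture, for researchers studying how nanoparticles —
extracellular vesicles (EVs), plasma-membrane vesicles, liposomes — modulate
collagen self-assembly.

Collagen I gelation shows up in oscillatory rheology as a sigmoidal storage
modulus G′(t): a nucleation (lag) phase, a growth phase, and a plateau. The
resulting hydrogel is a fibril network whose architecture is visible in
confocal reflectance microscopy. `fibrilkit` turns both kinds of raw data
into the standard quantitative readouts:

* **Gelation kinetics** — `analyze_gelation()` segments G′(t) using its
  first derivative dG′/dt: the nucleation phase ends at the first of two
  consecutive points exceeding `mean + 2·SD` of a 5-point baseline; the
  peak growth rate is `max dG′/dt` (the inflection point); the plateau
  starts when the derivative falls back below the same threshold. Endpoint
  moduli are averaged over 0.16–2.5 Hz of the endpoint frequency sweep.
  For a logistic curve `G′(t) = g0 + (gmax−g0)/(1+exp(−(t−t_mid)/τ))` the
  peak rate is `(gmax−g0)/(4τ)`, which anchors the recovery tests.
* **Network morphometry** — `analyze_network()` runs bandpass → Otsu
  threshold → per-slice skeletonization, then measures fibril content
  (foreground fraction), mesh size (the coefficient λ of an exponential
  fit `A·e^(−s/λ)` to the histogram of inter-fibril gap lengths along x
  and y), junctions per fibril (crossing-number junction detection), and
  mean skeleton-branch length.
* **Colocalization** — `coloc_report()` detects labelled particles,
  computes pseudo-3D nearest-fibril and nearest-junction distances
  (in-plane distance, candidate fibrils from slices z−1, z, z+1) and the
  fraction of particles within 500 nm of a fibril axis or junction.
* **Concentration & statistics** — `count_field()` / `to_volumetric()`
  convert pseudo-2D particle counts to volumetric concentrations via the
  depth of field (≈ 0.7 µm); `welch_t()`, `anova_tukey()` (one/two-way,
  Tukey–Kramer post hoc, type-II SS), `pearson_dose()` and
  `flag_outliers()` cover the comparison suite.
* **Synthetic data** — `gen_gelation_curve()`, `gen_fibril_stack()` (an
  isotropic Poisson line process with known centrelines and junctions) and
  `place_particles()` generate seeded fixtures with ground truth; every
  estimator is validated against them.

## Worked example

```r
library(fibrilkit)

# --- gelation kinetics on a synthetic run -------------------------------
sw  <- gen_gelation_curve(gelation_truth(seed = 42))
kin <- analyze_gelation(sw, gen_frequency_sweep(80, 12, noise_sd = 0.5,
                                                seed = 42))
kin
#> Gelation kinetics
#>   nucleation end : 420 s
#>   peak growth    : 0.4545 Pa/s at t = 540 s
#>   plateau start  : 750 s
#>   endpoint G'/G'': 80.28 / 12.06 Pa (band 0.16-2.5 Hz, n = 11)
```

The curve's true inflection is at 600 s with true peak rate
100/(4·60) ≈ 0.417 Pa/s; at 2 % noise the detected peak lands within two
sampling intervals and the rate within a few percent. The nucleation end at
420 s is where the derivative first clears its baseline threshold for two
consecutive points.

```r
# --- network morphometry and colocalization on a synthetic stack --------
st <- gen_fibril_stack(network_truth(n_slices = 5,
                                     image_shape = c(256, 256), seed = 42))
analyze_network(st)
#> Fibril network metrics
#>   fibril content        : 0.1230
#>   mesh size             : 4.37 um
#>   junctions per fibril  : 12.2
#>   mean branch length    : 3.85 um

pp <- place_particles(st, particle_placement("on_fibril", 60,
                                             jitter_um = 0.15, seed = 7))
coloc_report(pp$stack)
#> Particle-fibril colocalization
#>   particles             : 59 (0 unreachable)
#>   mean fibril distance  : 0.123 um
#>   fibril-associated     : 1.000 (<= 0.5 um)
#>   junction-associated   : 0.237
```

The stack's line intensity (0.4 µm⁻¹) implies a mean mesh of
π/(2·0.4) ≈ 3.9 µm; the fitted 4.37 µm reflects this single stack's
realized line count. Particles placed on fibrils with 0.15 µm jitter are
all fibril-associated at the 500 nm threshold, while only those near
crossings are junction-associated.

```r
# --- concentration conversion -------------------------------------------
to_volumetric(0.0182, depth_of_field = 0.7)[c("volumetric_density",
                                              "per_microliter")]
#> $volumetric_density   0.026      # particles/um^3
#> $per_microliter       2.6e7      # particles/uL
```

A command-line wrapper over the same functions (verbs `simulate`, `rheo`,
`network`, `coloc`, `count`, `run`) is installed at
`system.file("cli", "fibrilkit.R", package = "fibrilkit")`.

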