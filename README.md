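# phasesync

Directional periodicity analysis and a grid-to-place model of goal-directed
navigation in conceptual space.

## What this package is for

Entorhinal grid cells fire on a hexagonal lattice with a population-wide
orientation, which appears in fMRI as a **sixfold** (60°-periodic)
modulation of entorhinal activity by movement direction. This package is
built around the hypothesis that projections from that sixfold code
structure a **threefold** (120°-periodic) vectorial representation in the
hippocampus, visible both in hippocampal activity and in behavioral
performance as a function of movement direction. It provides, for
computational neuroscientists and neuroimaging methodologists:

* a grid-cell population model (sum of three cosine gratings 60° apart),
  path codes formed by summing population activity along straight
  trajectories, an orientation alignment profile `δ(ψ)` with three peaks at
  the grid axes, a goal-directed vector field
  `C(R) = cos(δ_c Φ_R + δ_ε) + exp(−‖R−q‖²/2σ²)`, and a winner-take-all
  navigation simulation over random goals;
* the full directional statistics stack: quadrature (sin kθ / cos kθ) GLMs
  with orientation estimation `φ = atan2(β_sin, β_cos)/k`, odd/even-session
  cross-validated alignment, direction-bin GLMs, fold-spectrum FFT analysis
  (detrend + periodic Hann + DFT) with label-shuffle permutation nulls and
  max-statistic FWE correction, directional amplitude–phase coupling with
  circular-lag surrogates, zero-phase least-squares FIR band-pass, PLV/PLI
  phase locking, and circular statistics (Rayleigh, pairwise phase
  consistency, circular–circular correlation);
* a synthetic-data module that emulates the study design (288 ring-sampled
  directions, 8 sessions × 36 trials + 4 lures, TR 2 s, double-gamma HRF,
  von Mises voxel orientations) with known ground truth.

Everything is plain-text in and out (TSV event tables and matrices, JSON
results); no imaging data are read.

## Worked example

Simulate a direction-tuned voxel with a planted sixfold orientation of 23°
at unit noise, recover the orientation on odd sessions, and test the
alignment on held-out even sessions:

```r
library(phasesync)

starts <- sample_ring_starts(seed = 1)               # 288 ring starts
events <- make_event_design(starts$direction_deg, seed = 2)
series <- simulate_voxel(events, fold = 6, phi_deg = 23,
                         amplitude = 1, noise_sd = 1, seed = 3)
cv <- crossval_alignment(series, events, k = 6)
#> estimated orientation: 22.3 deg | held-out aligned beta: 0.894
```

The held-out beta (0.894) estimates the planted modulation amplitude (1);
control folds stay near zero (k = 3: −0.056, k = 4: +0.094, k = 5: −0.009,
k = 7: +0.078), so the effect is selective for the planted symmetry.
A behavioral vector with a planted threefold periodicity is detected
against a 5000-shuffle null:

```r
beh <- simulate_behavior(starts$direction_deg, fold = 3, phase_deg = 15,
                         amplitude = 1, noise_sd = 1, seed = 4)
rs  <- circular_resample(beh$direction_deg, beh$score, 36)
detect_periodicity(rs$values, rs$directions, n_perm = 5000, seed = 5)
#> behavior argmax fold: 3 | significant folds: 3
```

Peak-aligned sixfold/threefold curves couple maximally in the phase bin
centered at 0° (coupling strength 0.325 there, the largest of the nine
bins), and a reduced navigation run already shows the threefold path-length
spectrum:

```r
ca <- coupling_alignment(cos(6 * th), cos(3 * th))   # th: 360-point grid
#> coupling argmax bin: 0 deg | strength at 0: 0.325

sim <- run_simulation(n_goals = 10, n_starts = 48, n_perm = 500, seed = 6)
#> model argmax fold: 3 | fold-3 magnitude: 28.4 | FWE threshold: 15.9
```

See `vignettes/phasesync-methods.Rmd` for the model's assumptions, the
meaning of each tunable parameter, and known limitations.

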