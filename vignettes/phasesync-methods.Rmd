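---
title: "Directional periodicity in the entorhinal-hippocampal circuit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directional periodicity in the entorhinal-hippocampal circuit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasesync)
```

# The scientific problem

Entorhinal grid cells tile space with hexagonal firing fields whose
orientation is nearly constant across the population. In fMRI this code
shows up as a *sixfold* (60-degree-periodic) modulation of entorhinal
activity as a function of movement direction. `phasesync` implements a
computational account of how that sixfold metric code could structure
*threefold* (120-degree-periodic) vectorial representations downstream in
the hippocampus, together with the complete analysis stack needed to detect
and characterize directional periodicities of any fold: quadrature GLMs,
direction-binned GLMs, fold-spectrum FFT analysis with permutation
correction, directional amplitude-phase coupling, phase-locking measures,
and circular statistics. Everything runs on synthetic data with known
ground truth; no neuroimaging data files are involved.

The task environment is a 45 x 45 lattice of object variants defined by two
morphable features (feature ratios 0.12 to 1.88 in steps of 0.04), with the
goal prototype at the central cell (22, 22). Trial start locations sit on a
peripheral ring and each trial's movement defines a direction in [0, 360)
degrees, with 0 degrees pointing East.

# The grid-code model

A grid cell with spatial phase offset $c$ responds at agent location $r$
with

$$G_r(c) = \sum_{i=1}^{3} A \cos\!\big(\omega\, k_i \cdot (r - c)\big),$$

the sum of three cosine gratings whose unit wave vectors $k_i$ are 60
degrees apart. One cell per lattice cell gives a 45 x 45 population with
common orientation and varying phase. We parameterize *orientation* as the
angle of the first grid axis (the band direction along which a path excites
a coherent planar wave); wave vectors are perpendicular to the axes, so the
default orientation of 15 degrees places the axes at {15, 75, 135} and one
of them at 135 degrees, the canonical aligned direction in the model
illustrations. The scale $\omega = 2\pi/\text{period}$ uses a default
period of 9 cells, giving five pattern repetitions across the space - small
enough for several firing fields per cell, large enough to resolve the
bands on the lattice. Amplitude $A = 1$.

A straight path from $r$ to the goal $q$ produces a *path code*

$$V(c) = \sum_{r' \in \mathrm{trajectory}(r,q)} G_{r'}(c),$$

the population pattern summed over the locations along the path. Because
$G$ is even in $r - c$, the path code is identical for a direction $\phi$
and $\phi + 180^\circ$: path codes represent *orientation*
$\psi = \phi \bmod 180^\circ$, not direction. `path_code()` rasterizes
lattice endpoints with a deterministic supercover line; the orientation
profile below instead samples the continuous segment at unit spacing, which
avoids lattice rounding jitter in a quantity that is differentiated with
respect to angle.

## The orientation alignment profile

The scalar alignment signal $\delta(\psi)$ asks how strongly the path code
of a ring-to-center path at orientation $\psi$ coheres. The defining
equation sums path-code activity over locations but leaves the reduction
from a 45 x 45 pattern to a scalar open. We provide two poolings:

* **energy** (default): $\delta = \sum_c V(c)^2$. Aligned paths produce a
  coherent planar wave whose energy is maximal; the profile over
  $\psi \in [0, 180)$ has exactly three prominence-filtered peaks, one per
  grid axis, and a dominant non-DC Fourier component at 3 cycles per 180
  degrees.
* **max**: $\delta = \max_c V(c)$, a single downstream unit pooling its
  best-aligned afferents. This shares the threefold fundamental but adds
  genuine secondary maxima at axis-perpendicular orientations (where one
  grating's Dirichlet sum peaks), which is why it is not the default: the
  clean three-peak phenomenology belongs to the energy reading.

```{r delta, eval = FALSE}
dp <- delta_profile(grid_params())     # 1-degree sampling, radius 21
delta_peaks(dp)                        # 15 75 135
```

The peak prominence filter keeps maxima whose prominence exceeds 5% of the
profile range; under energy pooling the result is insensitive to this value
over at least 0.05-0.2.

## Goal field and navigation

The hippocampal goal representation combines the threefold directional
structure inherited from the grid axes with goal proximity:

$$C(R) = \cos(\delta_c \Phi_R + \delta_\varepsilon)
       + \exp\!\left(-\frac{\lVert R - q\rVert^2}{2\sigma^2}\right),$$

with $\Phi_R$ the allocentric direction from $R$ toward the goal,
$\delta_c = 3$, and $\sigma$ the space radius (22 cells). A threefold
cosine over the full circle can prefer only one of each axis's two opposite
directions; we fix $\delta_\varepsilon = -\delta_c \cdot \text{orientation}$
(default -45 degrees), placing preferred directions at {15, 135, 255}. The
opposite convention is a pure relabeling. At $R = q$ the direction is
undefined and the cosine term is set to its circular mean (0).

Navigation is winner-take-all: from the current cell the agent inspects the
ring of lattice cells at Chebyshev radius $s$ (starting at 1), moves to the
strongest field value if it beats the current cell, and otherwise grows $s$
by 1 up to 5. Ties break by a fixed clockwise-from-East ordering, making
runs exactly reproducible. Performance is the summed Euclidean step length.

The full protocol (`run_simulation()`) draws 100 goals uniformly from the
lattice interior (margin $\lceil \sigma/4 \rceil = 6$ cells) and pairs each
with 120 starts on a ring *around that goal*, radius
$\min(21, \text{distance to boundary} - 1)$. The goal-centered ring mirrors
the task design, which samples start variants on a ring around the
prototype precisely to control distance: with starts ringed around the
space center instead, start-goal distance varies as a cosine of direction
for off-center goals and its onefold spectral power swamps every other
structure. Path lengths are indexed by start-to-goal direction, resampled
onto a uniform 36-point grid by periodic linear interpolation, Fourier
transformed, and the mean magnitude across goals is tested against a
label-shuffle permutation threshold.

# The analysis stack

## Quadrature GLM and cross-validated alignment

Event-related BOLD-like signals are modeled per session with an intercept,
a linear drift, an unmodulated onset regressor over the direction trials,
and the parametric modulators $\sin(k\theta)$ and $\cos(k\theta)$, all
convolved with the canonical double-gamma HRF (peak delay 6 s, undershoot
delay 16 s, unit dispersions, undershoot ratio 1/6 - the standard
parameterization, adopted because the literature rarely states more than
"double gamma"). The onset regressor matters: the forward model has a
per-trial baseline response, and omitting the column would leak baseline
variance into the modulators, breaking the exact noiseless round trip that
the test suite demands (orientation recovered to < 1e-6 degrees for folds
3-7).

Orientation is estimated as $\varphi = \mathrm{atan2}(\beta_{\sin},
\beta_{\cos})/k$ on $[0, 360/k)$; the two-argument arctangent resolves the
quadrant ambiguity of the printed one-argument form. Session- or voxel-wise
estimates are averaged as circular means in $k\varphi$ space.
Cross-validation estimates $\varphi$ on odd-numbered sessions and refits
even sessions with the single aligned modulator
$\cos(k(\theta - \varphi))$; on noiseless forward data the held-out beta
equals the planted amplitude exactly, and with planted fold 6 at unit
signal-to-noise the fold-6 held-out beta beats folds {3,4,5,7} in at least
90% of simulated runs.

## Fold spectra and permutation thresholds

Direction-binned values (36 bins of 10 degrees by default; 20-degree bins
available) are sorted by direction, linearly detrended, tapered with a
*periodic* Hann window, and Fourier transformed; magnitudes are indexed by
fold (cycles per 360 degrees), 0 through Nyquist. The periodic (DFT-exact)
window is chosen over the symmetric variant because its spectrum has
support only on {-1, 0, 1}, so a pure fold-k tone leaks exactly into
k plus/minus 1 and nowhere else. Detrending is a least-squares line fit, the
minimal reading of "detrended". Two consequences are documented rather than
hidden: the fitted trend is anchored to the label origin, so the tapered
pipeline is only approximately invariant under rotation of direction
labels (the raw DFT magnitude, `detrend = FALSE, window = FALSE`, is
exactly invariant and is what the invariance property tests assert); and
the window makes each strong fold carry half its magnitude into its two
neighbors, which matters when judging which folds are "significant".

Null distributions shuffle the direction labels (5000 times at full scale),
recompute the spectrum per shuffle, and take the 95th percentile per fold
(uncorrected) and of the across-fold maximum (FWE). The DC fold is excluded
from the maximum because detrending removes the mean by construction;
including it would only inflate the threshold without changing
exchangeability. Under white noise the FWE exceedance rate sits in the
2.5-7.5% band over 500 replicates.

## Directional amplitude-phase coupling

To test whether a sixfold (entorhinal-like) activity curve is peak-aligned
with a threefold (hippocampal-like) curve over direction, the slow curve's
instantaneous phase is extracted with the circular Hilbert transform (the
signal is periodic in direction, so the analytic signal is formed exactly
in the Fourier domain with no padding), phases are classified into 9 bins
of 40 degrees with one bin *centered at phase 0* (the anchoring implied by
reporting coupling "in the bin centered at phase 0"), and the modulation
index $M_b = |\mathrm{mean}(A e^{i\phi})|$ is computed per bin. Surrogates
circularly offset the amplitude against the phase across all nonzero
spatial lags; coupling strength is $M - M'$.

One modeling choice deserves emphasis: the amplitude $A$ is the fast
curve's directional *activity level itself*, not its Hilbert envelope. The
envelope of a noiseless pure tone is exactly constant, which would make all
bins identical up to sampling artifacts - the phase-0 alignment result
would be undefined. With activity-level weighting, peak-aligned
$\cos(6\theta)$ / $\cos(3\theta)$ signals yield maximal positive coupling
strength in the 0-centered bin on any uniform grid dense enough that phase
samples do not straddle bin edges degenerately (the packaged analyses use
360 samples; a 72-sample grid places phase samples exactly on two bin
edges and is the one density we avoid). The odd bin count is what breaks
the 180-degree symmetry: the anti-phase alignment at 180 degrees falls on
a bin edge and splits. Ninefold and twelvefold amplitude controls produce
strictly weaker coupling everywhere, mirroring the harmonic-relation
control analyses.

Band-pass filtering uses a type-I FIR designed by least squares on a dense
frequency grid (pass band of one fold half-width, one-fold transition
bands, gain normalized at the pass-band center) and is applied forward and
backward via the squared magnitude response on the circular domain - the
zero-phase, edge-free analog of two-way filtering for periodic signals.
Phase locking offers both PLV (resultant of phase differences) and PLI
(sign consistency); the degenerate cases pin the conventions: identical
signals give PLV 1 / PLI 0, a constant nonzero lag gives PLV 1 / PLI 1.

## Circular statistics

Rayleigh test (statistic $\bar R$, $z = n\bar R^2$, standard series
approximation with an optional Monte-Carlo p), pairwise phase consistency
(computed as the literal mean over pairs; the identity
$\mathrm{PPC} = (n\bar R^2 - 1)/(n - 1)$ is asserted in tests, with
uniform-phase surrogates for p), the Jammalamadaka-SenGupta
circular-circular correlation with its asymptotic normal test, and the
fold-phase mapping $\varphi \mapsto k\varphi$ that places fold-specific
phases (entorhinal $[0,60)$, hippocampal $[0,120)$) on a common circle.
No circular-statistics dependency is used; the implementations are small
closed forms validated against Monte-Carlo oracles.

# The synthetic-data generator

`sample_ring_starts()` reproduces the experimental sampling: 24 directions
per 30-degree bin drawn without replacement from a 1.25-degree precision
grid (24 slots per bin, so the default design uses every slot), radius
21 plus or minus 1 cell around the prototype - 288 starts, exactly uniform
across bins. `make_event_design()` distributes them over 8 sessions of 36
direction trials plus 4 lures on a fixed 2 s fixation + 10 s trial grid
(no jitter by default). `simulate_voxel()` applies the forward model
matched to the GLM: per-trial impulse amplitude
$\text{baseline} + a\cos(k(\theta - \varphi^*))$, double-gamma
convolution, TR 2 s, i.i.d. Gaussian noise (AR(1) optional).
`simulate_region()` draws voxel orientations von Mises around
$k\varphi^*$; `simulate_behavior()` plants a periodic performance vector.

What the generator does *not* emulate - realistic fMRI noise spectra,
spatial autocorrelation, motion, physiological confounds, session
nonstationarity - bounds what green tests mean: they validate the
estimators and the statistical machinery, not robustness to real scanner
data.

# Problem sizes and numerical choices

The packaged tests use 2-session designs for GLM unit tests and the full
8-session, 288-trial design where the protocol itself is under test. The
navigation headline runs at its full scale (100 goals x 120 starts, 5000
permutations, about a minute); the orientation profile uses 1-degree
sampling at ring radius 21; white-noise error control uses 500 replicates
of 400 permutations. All stochastic steps take explicit seeds and restore
the caller's RNG state.

Degenerate inputs are handled explicitly: identical trial directions make
the quadrature design rank deficient (flagged, then a hard error at fit
time naming the columns); zero quadrature vectors have undefined
orientation (error); antipodal orientation pairs in folded space yield a
near-zero resultant (flagged low-confidence); empty direction bins and
empty phase bins are flagged and carried as NA.

# Known limitations

* On the square lattice, the navigation model's detour profile is not
  exactly 120-degree periodic: only the 135-degree trough direction lies on
  a lattice mirror axis, so the other two trough mountains are sheared
  mirror images of each other. Together with Hann leakage (half of a strong
  fold-3 magnitude appears at folds 2 and 4), this places folds 1, 2 and 4
  above the label-shuffle threshold in full-scale runs even though fold 3
  is always the argmax and by far the strongest component. The acceptance
  suite asserts the strict "fold 3 only" phenomenology and therefore
  documents this discrepancy as a genuine property of the discretized
  model rather than weakening the test.
* The coupling amplitude convention (activity level, not envelope) is the
  only reading under which noiseless peak-alignment is well defined; with
  noisy data the two conventions converge.
* Orientation estimation assumes the forward and analysis HRFs match; HRF
  mismatch is not modeled.
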