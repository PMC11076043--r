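---
title: "Models and numerical methods in smtirf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in smtirf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`smtirf` analyzes single-molecule TIRF experiments on supported lipid
bilayers: how often a labeled protein lands on the membrane, how long it
stays, how it diffuses while bound, and how fast membrane-bound enzymes turn
substrate lipids into product. This vignette is the package's account of the
underlying models, the numerical choices, and what the built-in simulators
do and do not emulate.

## Dwell times and the survival-curve fit

A molecule tracked over $n$ consecutive frames at frame interval
$\Delta t$ is assigned the recorded dwell $(n-1)\,\Delta t$. The imaging
clock cannot distinguish sub-frame timing, so a molecule bound for time $t$
is observed in $\lfloor t/\Delta t \rfloor + 1$ frames; the minimum record
is two frames (one displacement), matching the usual "tracked $\ge 2$
frames" filter applied after linking. Both the simulator and the analysis
use this convention, so recovery checks are exact about discretization.

Dissociation is modeled as a one- or two-component exponential:
$$S(t) = \alpha e^{-t/\tau_1} + (1-\alpha)e^{-t/\tau_2},
\qquad \tau_1 \le \tau_2,$$
with $\alpha$ the fraction of fast-dissociating molecules. The empirical
survival function $1-\mathrm{CDF}$ is evaluated on the $\Delta t$ grid and
$\log_{10}$-transformed, and the model is fit by unweighted nonlinear least
squares in that space — the same representation in which such curves are
conventionally plotted and fit. Three numerical choices matter:

* **Origin shift.** Times are shifted so the minimum recorded dwell is the
  fit origin. Conditioning an exponential mixture on $T \ge t_0$ yields
  another exponential mixture with the *same* time constants and a
  reweighted $\alpha$, so the shifted fit recovers $\tau_1,\tau_2$ without
  bias from the 2-frame minimum. The reported $\alpha$ estimates the
  *conditional* (detectable-event) weight, which for 52 ms frames and
  sub-second $\tau_1$ sits a few percent below the underlying weight.
* **Tail floor.** Grid points where the empirical survival rests on fewer
  than `min_tail_events` surviving events (default 30) are excluded, along
  with zero-survival points (log undefined). The sampling noise of
  $\log_{10}\hat S$ grows without bound as $\hat S \to 1/n$, and an
  unweighted fit otherwise lets a handful of extreme order statistics —
  flat, single-event "shelves" in log space — dominate the slow component.
  With the floor at 30 events the per-point noise stays below roughly 0.08
  decades and recovery of $\tau_2$ is unbiased to within a few percent at
  the sample sizes this assay produces ($n \sim 10^3$–$10^4$).
* **Multistart.** $\tau_1$ is initialized from the first grid time where
  survival drops below $1/e$ (scaled by 0.5 and 1), $\tau_2$ at 2 and 5
  times that, and $\alpha$ at 0.3 and 0.7; the best residual sum of squares
  wins, ties broken by start order. The parameterization
  $(\mathrm{logit}\,\alpha, \log\tau_1, \log(\tau_2/\tau_1 - 1))$ enforces
  positivity and the canonical ordering $\tau_1 \le \tau_2$.

The least-squares estimates are cross-checked in the test suite against an
independent maximum-likelihood oracle that works on the raw discretized
counts (probability $S(d) - S(d+\Delta t)$ per recorded dwell $d$,
conditioned on detectability); the two agree within sampling uncertainty.
Bootstrap standard errors (resampling durations, seeded) are available via
`n_boot`; note these quantify sampling noise of one sample, not the
between-replicate spread usually reported as $\pm$SD in experimental work.

**Model selection.** `select_dwell_model()` accepts the two-component fit
only if the extra-sum-of-squares F-test (2 extra parameters) is significant
at `p_threshold` (default 0.01) *and* $\alpha \in [0.1, 0.9]$ *and*
$\tau_2/\tau_1 \ge 2$. Neighbouring survival points are strongly
correlated, which makes the F-test alone wildly anti-conservative: under a
true single exponential the two-component fit occasionally locks onto a
correlated wiggle with an essentially-zero p-value. The weight and
separation guards therefore carry the calibration; with the defaults,
simulated single-exponential data at $n = 5000$ is misclassified in under
5% of runs while well-separated mixtures ($\tau_2/\tau_1 \ge 3$, central
$\alpha$) are detected essentially always. Both guards are arguments, so a
user who prefers the bare F-rule can have it.

**Censoring.** Tracks touching the first or last movie frame are removed
rather than treated as censored observations. For movies much longer than
the dwell times (the intended regime) the resulting bias is negligible; no
survival-analysis censoring correction is applied.

## Step sizes and the diffusion-mixture fit

Frame-to-frame displacements $r$ at a single lag $\tau$ (the frame
interval) follow, for 2D Brownian motion with coefficient $D$, the Rayleigh
density
$$f(r) = \frac{r}{2D\tau} e^{-r^2/(4D\tau)},$$
and a two-species population gives the mixture with weight $\alpha$ on the
slow coefficient $D_1$. Displacements are histogrammed from zero in fixed
0.01 µm bins as frequency divided by bin width; the final partial bin is
retained. The fit is unweighted least squares of the binned density against
the model at bin centers, with multistart over
$D \in \{0.1, 0.5, 1.5\} \times \bar{r^2}/(4\tau)$ and
$\alpha \in \{0.3, 0.7\}$, the same positivity/ordering parameterization as
above, and canonical $D_1 \le D_2$. Steps spanning a closed linking gap are
excluded rather than rescaled, because the model assumes a single lag. An
EM oracle on the raw, unbinned displacements serves as the independent
cross-check in the tests.

Localization error is *not* part of the fitted model (measured step sizes
include a $\sim 2\sigma_{xy}^2$ inflation); the simulator can render movies
whose re-tracked steps carry that error, which makes the resulting bias
measurable but deliberately leaves it uncorrected, as is conventional for
these fits.

## Surface densities

Two conversions produce absolute densities. Counting a dilute labeled
subpopulation (e.g. 1:10,000) and dividing the per-area count by the
labeled fraction gives the total density of the mostly-dark species;
per-frame counts are averaged first and a Poisson standard error is
attached. For lipids, a mole fraction $x$ at per-lipid footprint $a$
(0.72 nm² for phosphatidylcholine) gives $x \cdot 10^6 / a$ lipids/µm²,
counting only the solution-facing leaflet — the accessible-substrate
convention under which 2 mol% yields $2.8\times10^4$ lipids/µm². No
correction is made for incomplete dye labeling (fold it into the labeled
fraction) or dye photophysics.

## Biosensor kinetics and per-enzyme rates

A product-lipid biosensor trace is normalized to $[0,1]$ between a baseline
window and a plateau window (means within each), clipped to $[0, 1.05]$
with clipping flagged, and multiplied by the total product density at
completion to give product lipids/µm² over time. Sensor occupancy is
assumed proportional to product density, valid when far below sensor
saturation.

The initial rate is the ordinary least-squares slope over the maximal
prefix of the trace with product below `depletion_cap` (default 0.1) of the
total. Under the first-order depletion model
$$P(t) = S_0\left(1 - e^{-k_{\mathrm{cat}} E\, t / S_0}\right)$$
the tangent at zero is exactly $k_{\mathrm{cat}} E$, and the least-squares
secant over a 10%-depletion window underestimates it by about 5% (the
closed-form bias is asserted in the tests); smaller caps trade bias for
noise. The per-enzyme rate is $k_{\mathrm{cat}} = $ rate $/ E$ with $E$ the
membrane-bound enzyme density, supplied directly or from single-molecule
counting. For the default normalization windows, a catalysis trace is
assumed to start at reaction start (baseline = first sample) and to reach
its plateau (last 10% of samples); traces with a pre-reaction phase need
explicit windows.

Two-phase (ATP-spike) experiments measure enzyme density in the pre-ATP
equilibration phase and rates after ATP addition; the density-normalized
activation fold is
$(\mathrm{rate}_\mathrm{test}/\mathrm{rate}_\mathrm{ref}) /
(E_\mathrm{test}/E_\mathrm{ref})$, i.e. the ratio of per-enzyme rates,
which separates allosteric activation from mere recruitment.

Bulk membrane equilibration traces are fit to the pseudo-first-order form
$I(t) = I_\infty(1 - e^{-k_{\mathrm{obs}} t})$; a warning is raised when the
trace spans less than $3/k_{\mathrm{obs}}$, where the plateau is poorly
constrained.

## The simulators: what they emulate

The synthetic-data module generates every input the analysis consumes, all
deterministically from one integer seed per call (the caller's RNG state is
saved and restored):

* **Dwell samples** — mixture draws discretized to the camera clock, with
  sub-threshold events redrawn (conditioning on detectability, the default)
  or dropped.
* **Track sets** — spatially uniform Poisson arrivals at
  `arrival_rate × area` per second; per-particle dwell and diffusion
  species drawn independently by default (`couple_states` links them for
  sensitivity studies); 2D Brownian steps with per-axis variance
  $2D\Delta t$; optional photobleaching as a competing exponential hazard;
  optional rebinding ("membrane hopping") that re-inserts a dissociating
  particle within a radius with some probability and continues the track —
  a minimal formalization, off by default.
* **Movies** — integrated-Gaussian point-spread functions with Poisson spot
  photons, Poisson background, and Gaussian read noise, stored as a double
  array and quantized to 16-bit only on TIFF export. No EMCCD gain-register
  noise, no astigmatic/3D PSF, no drift.
* **Catalysis and adsorption traces** — the closed forms above with
  multiplicative (catalysis) or additive (adsorption) Gaussian noise.

Passing recovery tests on these simulations demonstrates that the
estimators are consistent and unbiased *under the generating models*. Real
data additionally contain localization error, detection misses and false
positives at low SNR, blinking and bleaching, stage drift, and non-ideal
membranes; of these only bleaching, rebinding, and shot/read noise are in
the forward model, so simulation-based recovery is a necessary but not
sufficient validation for any particular experiment.

## Default parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `frame_interval_s` | 0.052 | s | typical single-molecule acquisition interval; the survival-curve bin width |
| `min_frames` | 2 | frames | minimum detectable track; defines the recorded-dwell floor $\Delta t$ |
| `bin_width_um` | 0.01 | µm | step-size histogram bin |
| `min_tail_events` | 30 | events | survival-fit tail floor (above) |
| `depletion_cap` | 0.1 | fraction | initial-rate window; $\sim$5% secant bias |
| `footprint_nm2` | 0.72 | nm² | phosphatidylcholine per-lipid area |
| edge margin | $3\sigma_{\mathrm{PSF}}$ | px | default border exclusion for track filtering |

Detection and linking gates (LoG `quality_threshold`,
`max_displacement_um`) have no universal defaults — they depend on photon
budget and mobility — and are required arguments; the tracking tests
document working values for the simulated regime (e.g. threshold ~90 at
~300 photons/spot over ~20 background photons/pixel, gate 0.5–0.6 µm at
$D \lesssim 0.2$ µm²/s and 52 ms frames).

## Linking as gated optimal assignment

Full LAP tracking with merge/split handling is unnecessary in the sparse
single-molecule regime this package targets; linking is per-frame-pair
minimum-total-squared-displacement bipartite assignment (Hungarian
algorithm) among candidates within the gate, with birth/death costs at the
gate cost so unmatched spots start or end tracks, and optional gap closing
up to `max_gap_frames` with the gate scaled by the gap length. Ties are
broken deterministically by frame and spot order. Sub-pixel localization is
quadratic interpolation of the Laplacian-of-Gaussian response peak —
adequate for the distributional statistics computed downstream, and cheap
to verify (a noiseless rendered spot localizes to well under 0.1 px).

## Problem sizes and reproducibility

The recovery analyses in the test suite and the acceptance script use the
sample sizes the corresponding experiments produce: $n = 4698$ and
$n = 3421$ dwell events for the two dwell conditions, 20,000 displacements
for the diffusion fits, 1500–2000-point sensor traces at 2% multiplicative
noise for the kinetics, and medians over 20 seeds for every stochastic
quantity. `run_pipeline()` derives per-stage seeds by hashing the stage
name with the global seed, so adding a stage to a config never changes the
randomness — and therefore the numbers — of existing stages.

## Known limitations

* No photobleaching correction of dwell times (fit constants are apparent
  off-rates plus bleaching); no hidden-Markov state assignment within
  tracks.
* No MSD-based anomalous-diffusion analysis and no per-track diffusion
  classification; the two-species fit is a population decomposition at one
  lag.
* No Michaelis–Menten analysis: each kinetics experiment runs at a single
  substrate density.
* Mean dwell times can be reported either as the arithmetic mean of
  recorded dwells (`mean_dwell`) or as the mixture mean
  $\alpha\tau_1 + (1-\alpha)\tau_2$ (`model_mean`); the two differ under
  discretization and truncation, so comparisons between conditions should
  fix one convention — fold changes here use arithmetic means.
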