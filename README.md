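# smtirf

Single-molecule TIRF analysis of membrane binding and lipid kinase kinetics
on supported lipid bilayers.

`smtirf` is an R package for quantifying how peripheral membrane proteins —
lipid kinases in particular — bind, diffuse on, and catalyze reactions at
supported lipid bilayers (SLBs) imaged by single-molecule total internal
reflection fluorescence (TIRF) microscopy. It is aimed at experimentalists
who track single fluorescently labeled molecules (e.g. with TrackMate) and
monitor bulk biosensor fluorescence, and who want a scripted, testable route
from track tables and sensor traces to dwell-time constants, diffusion
coefficients, absolute surface densities, per-enzyme catalytic rates, and
localization-normalized activation folds.

Every analysis stage is paired with a seeded forward simulator, so the whole
pipeline can be validated by parameter recovery: simulate data from known
constants, run the analysis, and check that the constants come back.

## What it computes

**Dwell-time survival analysis.** Membrane residence times are recorded as
(frames tracked − 1) × frame interval (default 52 ms). The empirical
survival function 1 − CDF, binned at the frame interval, is fit in log10
space to a single exponential

    f(x) = exp(-x / tau)

or a two-component exponential mixture

    f(x) = alpha * exp(-x / tau1) + (1 - alpha) * exp(-x / tau2),

where `alpha` is the fraction of fast-dissociating molecules with time
constant `tau1`. An extra-sum-of-squares F-test with weight/separation
guards selects between the two forms.

**Step-size diffusion analysis.** Frame-to-frame displacements r at a single
lag tau are histogrammed (0.01 µm bins) as a probability density and fit to
the 2D Brownian single-species model

    f(r) = r / (2 D tau) * exp(-r^2 / (4 D tau))

or a two-species mixture with weight `alpha` on the slow coefficient `D1`.

**Surface-density calibration.** Absolute molecules/µm² from counting a
dilute labeled subpopulation and dividing by the labeled fraction; absolute
lipids/µm² from a mole fraction and a per-lipid footprint (0.72 nm² for
phosphatidylcholine), counting the solution-facing leaflet.

**Biosensor kinase kinetics.** Product-sensor traces are normalized between
baseline and plateau, converted to product lipids/µm², and the initial rate
is taken as the least-squares slope below a 10% substrate-depletion cap.
Dividing by the membrane-bound enzyme density gives the per-enzyme rate

    kcat = initial_rate / enzyme_density      [lipids/s per enzyme]

and two-phase (ATP-spike) experiments give a density-normalized activation
fold `(rate_test / rate_ref) / (density_test / density_ref)`.

**Tracking.** For rendered or recorded movies: Laplacian-of-Gaussian spot
detection with sub-pixel localization, gated minimum-squared-displacement
(Hungarian) frame-to-frame linking, and TrackMate-style track filters
(remove tracks at movie start/end, ≥ 2 frames, displacement and edge
filters). TrackMate-dialect CSV track tables are read and written directly.

## Worked example

Simulate a dwell-time sample from a two-component mixture at 52 ms frames,
fit the survival curve, and compare with the generating constants:

```r
library(smtirf)

smp <- simulate_dwell_sample(3421, alpha = 0.58, tau1_s = 0.61,
                             tau2_s = 3.09, frame_interval_s = 0.052,
                             min_frames = 2, seed = 42)
fit <- fit_survival(smp, n_components = 2)
#> alpha = 0.552, tau1 = 0.562 s, tau2 = 3.143 s (ssr = 0.0562, 3421 dwells)
mean_dwell(smp)   #> 1.750 s
model_mean(fit)   #> 1.719 s  (= alpha*tau1 + (1-alpha)*tau2)
```

The recovered constants (0.552, 0.562 s, 3.143 s) sit within sampling error
of the generating ones (0.58, 0.61 s, 3.09 s); the recovered weight is
slightly below the generating weight because recording conditions on a
2-frame minimum dwell. Diffusion and kinetics work the same way:

```r
st <- simulate_step_sample(20000, alpha = 0.6, D1_um2_s = 0.23,
                           D2_um2_s = 0.88, lag_s = 0.052, seed = 42)
fit_step_distribution(st, n_species = 2)
#> alpha = 0.572, D1 = 0.223, D2 = 0.828 um^2/s

S0 <- lipid_surface_density(0.02, 0.72)$value   #> 27778 lipids/um^2
k  <- 57 * 0.2 / S0
cfg <- catalysis_sim_config(57, 0.2, S0, seq(0, 6 / k, length.out = 2000),
                            noise_sd_frac = 0.02, seed = 42)
estimate_kcat_from_trace(simulate_catalysis_trace(cfg), S0,
                         enzyme_density = 0.2)
#> initial rate = 10.81 lipids/um^2/s over [0, 256] s
#> kcat = 54.0 lipids/s per enzyme
```

The kcat estimate runs ~5% below the generating 57/s: the least-squares
slope is a secant of the depleting-substrate curve, which under the default
10% depletion cap underestimates the tangent by about 5% (see the methods
vignette).

Whole runs can also be described in a YAML/JSON config and executed with
`run_pipeline()`, which derives per-stage seeds from one global seed and
writes a manifest alongside the outputs.

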