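---
title: "Opponent visuospatial coding: models, generator design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Opponent visuospatial coding: models, generator design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opponentprf)
```

## Scope

`opponentprf` implements a complete, simulation-backed version of the
opponent visuospatial coding analysis: signed-amplitude pRF fitting on
bar-mapping timeseries, rectangular positive-by-negative RDMs, RDM
correlation with independent task sessions, a visuospatial matching
analysis, a label-shuffle bootstrap, and group-level inference. It operates
on voxel timeseries in percent-signal-change units; acquisition-side
processing (multi-echo denoising, motion correction, surface projection,
anatomical ROI delineation) is out of scope, as is any claim about what
the default-mode regions that motivated the method are *for*.

## The forward model and its assumptions

A voxel's population receptive field is an isotropic 2-D Gaussian with
centre $(x, y)$ and width $\sigma$, all in degrees of visual angle. Its
neural drive at TR $t$ is the aperture overlap

$$o_t \;=\; \frac{\sum_{c} m_{t}(c)\, G(c)}{\sum_{c} G(c)},$$

the $G$-weighted mean of the binary stimulus mask over the raster, so
$o_t \in [0, 1]$ with $o_t = 1$ for a full-field stimulus. The predicted
BOLD series is $b + \beta\,(o \circledast h)$, with $\beta$ a *signed*
amplitude in percent-signal-change units: $\beta > 0$ is activation by
stimulation of the receptive field, $\beta < 0$ deactivation. Two pRFs
identical in $(x, y, \sigma)$ with amplitudes $+\beta$ and $-\beta$
therefore predict exactly anticorrelated timeseries ($r = -1$), the
idealised opponent pair; this identity is the package's analytic reference
value and is independent of where the shared field sits.

The HRF is the gamma-variate $h(\tau) = (\tau/pq)^p e^{p - \tau/q}$ with
$p = 8.6$, $q = 0.547$ s (peak at $pq \approx 4.7$ s, analytic peak value
1), sampled at the TR and rescaled so the sampled maximum is exactly 1.
This is the classical single-gamma kernel used by the AFNI family of
fitters; both shape parameters are arguments of `gam_hrf()`. The model
assumes linear summation across the field, a time-invariant HRF, and no
compressive spatial nonlinearity — the standard assumptions of grid-search
pRF mapping. Difference-of-Gaussians and compressive variants are
deliberately not implemented.

Implementation note: the Gaussian is separable, so the overlap of every
centre pair at one $\sigma$ is computed as
$G_x^\top M_t G_y$, which is what makes exhaustive grid fitting cheap. The
naive cell-by-cell sum is kept alive in the test suite as the oracle for
this fast path.

## Stimulus and task designs

The mapping run is a bar aperture traversing a circular field of 12°
diameter: 8 sweeps (4 orientations × 2 directions, in a fixed canonical
order), 18 steps per sweep, one 2-s TR per step, hence 36 s per sweep and
144 TRs per run. Bar centres take evenly spaced positions spanning the full
extent along the motion axis, the bar oriented perpendicular to motion, and
every mask is clipped to the circular aperture. The bar width is not a
quantity the analysis is sensitive to; the default is 2° (one sixth of the
extent), configurable, and diagonal sweeps run along the 45° axes with
spacing measured along the motion axis. Sweeps are contiguous by default;
an inter-sweep blank is available but off.

The recall session is an event-related design: 12 items × 2 repetitions per
run × 6 runs, each trial a 0.5-s cue followed by 9.5 s of covert recall
(modelled as a single 10-s event), inter-trial intervals uniform on
2.5–7 s. The perception session is a slow event-related design: 96 stimuli,
0.5 s each, once per run, 2 runs, ISIs uniform on 3–7 s. Both designs are
seeded and validated property-style (ordering, ITI ranges, label multisets)
across 1000 seeds in the test suite.

## The synthetic-data generator

The generator's purpose is ground-truth recovery: populations of voxels
with known pRFs, a known fraction of negative amplitudes, and task
responses carrying a *tunable* degree of opponent visuospatial structure.

* **Population.** Centres uniform in the aperture (area-uniform), widths
  uniform on 0.5–3°, amplitude magnitudes uniform on 0.5–1.5 percent signal
  change, signs assigned to match the target negative fraction exactly
  (default 125/300 ≈ 41.7%, the canonical worked-example split). These are
  plausible magnitudes for extrastriate cortex at 3 T; they put desk-grid
  mapping fits in the R² ≈ 0.2–0.9 range at the default noise.
* **Mapping runs** follow the forward model exactly, about a baseline of
  100, plus noise.
* **Task runs.** Each event label receives a latent spatial activation
  bump (Gaussian, centre uniform in the aperture, width uniform on
  0.5–2° — the scale of the pRFs themselves), clipped to the aperture. The
  response amplitude of voxel $v$ to event $e$ is
  $$\beta_{v,e} = a_v\left[\kappa\, O_{v,e} + (1-\kappa)\,\eta_{v,e}\right],
  \qquad \eta \sim N(0,1)\ \text{i.i.d.},$$
  with $a_v$ the signed mapping amplitude and $O$ the voxel's overlap with
  the event's bump, *standardised per voxel across the event set* (zero
  mean, unit variance). Standardisation matters for three reasons: it puts
  the two mixture components on a common scale so $\kappa$ interpolates
  meaningfully between pure noise and pure tuning; it removes the shared
  response envelope that raw non-negative overlaps would impose on every
  voxel (which would dominate all pairwise correlations); and it
  decouples responsiveness from receptive-field size. At $\kappa = 1$ with
  zero noise, voxels sharing a receptive field but differing in sign
  respond in exact antiphase — the generator reproduces the idealised
  opponent-pair identity by construction.
* **Noise** is white Gaussian in percent-signal-change units (default SD
  0.3); an AR(1) option (coefficient 0.3, unit marginal variance) probes
  robustness to temporal autocorrelation.

What the generator does *not* emulate: spatially correlated physiological
noise, category selectivity or any non-spatial stimulus content, voxel
interdependence through a shared vasculature, and raw-signal artefacts.
Passing recovery tests therefore show that the *pipeline* detects opponent
structure when it is present and stays calibrated when it is absent — they
do not show that real cortical data contain such structure.

## Fitting: grid search, filtering, classification

Every candidate $(x, y, \sigma)$ on a regular grid is scored by closed-form
least squares (amplitude and baseline free); the candidate maximising
$R^2 = 1 - SS_{res}/SS_{tot}$ wins. Numerical choices:

* Centres span the full screen per axis; $\sigma$ is sampled at $n_\sigma$
  even intervals over $(0, \sigma_{max}]$ with $\sigma_{max}$ = half the
  extent — zero is excluded as degenerate. The full-fidelity preset
  (200 × 200 × 100 = 4,000,000 candidates) exists for parity with the
  reference fitter; the desk preset (40 × 40 × 20) is the default, and all
  simulation results quoted here use it.
* Ties in $R^2$ break to the lowest linear candidate index ($\sigma$
  slowest, then $y$, then $x$), making the fit deterministic.
* Constant or non-finite voxels are flagged invalid, never fitted.
* Candidate regressors with zero variance (e.g. a tiny $\sigma$ far from
  the bar path) score $R^2 = 0$; a pRF whose Gaussian underflows on every
  raster cell is rejected with guidance to refine the raster.
* Raster resolution: predictions from a coarse and a fine raster correlate
  above 0.999 once $\sigma$ is at least ~1.5 raster cells; the default 101
  cells/axis keeps even the smallest searched desk-grid $\sigma$ (0.3°)
  above that bound.

Suprathreshold filtering keeps voxels with $R^2 > 0.08$ (strict) and
$\sigma \le 0.95\,\sigma_{max}$. The size exclusion is interpreted as a
*fraction* of the maximum searched size: read in raw degrees, a 0.95°
cutoff would discard nearly every plausible pRF in a 12° display, so the
fraction reading is the only self-consistent one; it discards fits that
effectively cover the whole display. Classification is by amplitude sign;
an exactly zero amplitude (a measure-zero event) belongs to neither class.

Under the default study conditions — 200 simulated voxels, noise SD 0.25,
desk grid — the fit recovers the amplitude sign in ≥ 95% of voxels and the
median centre error stays within one grid step (≈ 0.31°); these are the
recovery bars the acceptance suite holds the fitter to.

## RDMs, matching, bootstrap

The cross-RDM is $1 - r$ between every +ve and every −ve voxel's
timeseries, so entries live in $[0, 2]$. Constant series are excluded
before construction (Pearson is undefined for them) rather than imputed.
Task RDMs are computed per run and averaged entrywise before the
correlation with the mapping RDM; per-run correlations are also reported as
a test–retest profile. The RDM–RDM association is Pearson over vectorised
entries — the scatter of these quantities is linear in the relevant regime —
with Spearman available as an option; group-level tests use Fisher
$z = \operatorname{atanh}(r)$ with $|r|$ clipped at $1 - 10^{-7}$.

The matching analysis pairs each −ve voxel with (a) the +ve voxel whose
*mapping* series is most anticorrelated (best visuospatial match), (b) the
most positively correlated one (worst match), and (c) random partners of
either sign, 1000 iterations, always excluding the voxel itself —
self-pairing would trivially inflate the random mean toward $r = 1$. The
scheme means are computed on the *task* series, so the comparison is
circularity-free. On fully opponent synthetic data the signature ordering
(matched < random < unmatched) holds in ≈ 99 of 100 seeded replicates.

The bootstrap permutes the +/− labels (class sizes preserved exactly),
rebuilds both RDMs under the shuffled labels, and recomputes $z$, 1000
times. Because RDM entries are pairwise correlations, the implementation
computes each session's full voxel-by-voxel correlation matrix once and
re-indexes it per shuffle — exactly equivalent to rebuilding from raw
series, and verified against the naive path in the tests. Both an
empirical percentile and a $t$ test of the observed value against the null
mean are reported, the percentile being the better-behaved summary.

**A structural caveat.** On data generated by the package's own
signed-amplitude mechanism, the label shuffle is *not* an effective null:
the mapping–task alignment is a property of every voxel pair
($M \approx 1 - c\,\rho_m$, $T \approx 1 - c\,\rho_t$ with $c$ the sign
congruence, for all pairs), so every relabelled pair subset is as aligned
as the true one, and the null distribution sits on top of the observed
value rather than below it. The shuffle separates observed from null only
when the alignment is specific to the true class partition — for instance
when same-sign task correlations are dominated by non-spatial shared
responses, as is plausible in real cortex but deliberately absent from
this generator. The calibration half of the story does hold here: at
$\kappa = 0$ the observed value falls inside the central 95% of its null
in ≈ 93–95% of replicates, and the mean alignment is indistinguishable
from zero. Users applying the bootstrap to real data should interpret a
non-escaping null accordingly.

## Group-level inference

One-sample $t$ tests on Fisher-z values (two-sided by default; a one-sided
option exists for directional hypotheses about positive RDM correlations)
and factorial linear mixed models with a participant random intercept,
fitted by `lmerTest` with Satterthwaite denominator degrees of freedom and
Bonferroni-corrected pairwise contrasts via `emmeans`. This stage is
inferential plumbing, so it delegates to those established implementations;
the tests pin behaviour (power on synthetic effects, the Bonferroni
multiplier, reduction to fixed-effects ANOVA when the random variance
collapses to the boundary) rather than exact $F$ values, because
denominator-df conventions differ across mixed-model implementations. A
constant response is returned as null effects ($F = 0$, $p = 1$) without
fitting, since the model is degenerate there. The Dice coefficient
$2|A \cap B| / (|A| + |B|)$ is provided for ROI-overlap comparison; it is
undefined (an error) for two empty sets.

## Pipeline, seeding, problem sizes

`run_opponency_pipeline()` chains simulate → fit → filter → RDM → match →
bootstrap under one validated config. Each stage draws its own seed,
derived deterministically from the master seed and the stage name, so any
stage can be re-run in isolation; the manifest records the config,
percent-negative, all correlations, matching means, and the null
distribution, and `write_report()` renders them (with the per-stage seeds)
as plain text. Two runs from the same config produce byte-identical
tables.

Simulation sizes in the tests and acceptance suite are chosen to estimate
each property precisely while keeping a full run in the minutes range on a
single core: 100 seeded replicates of 32-voxel populations for the
structure-recovery and calibration rates, 200 voxels for parameter
recovery, 200–1000 iterations for permutation distributions depending on
the quantile being read. The replicate counts match the granularity at
which the recovery rates are stated (per-cent resolution).

## Known limitations

* The grid stage is the estimator; no nonlinear refinement is applied, so
  accuracy is bounded by the grid step (the recovery bar above is stated
  in grid steps for that reason).
* The event-bump model of task responses is an explicit modelling choice,
  not an inference about what recall or perception actually evoke in the
  visual field.
* The label-shuffle bootstrap caveat above: on pair-level synthetic
  opponency it cannot separate observed from null, and results on real
  data should be read with that mechanism in mind.
* Real-data ingestion (NIfTI volumes, ROI masks) is out of scope; the
  package operates on timeseries matrices however obtained.
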