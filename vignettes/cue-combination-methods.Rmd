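---
title: "Methods: simulating and analysing Bayes-like combination of a novel distance cue with vision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing Bayes-like combination of a novel distance cue with vision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuefuse)
```

## The scientific problem

When two noisy estimates of the same quantity are available, the
minimum-variance combination is the precision-weighted average: weight each
estimate by 1/variance. Adults do this with familiar cue pairs. `cuefuse`
implements the full computational machinery for asking whether they also do
it with a *newly learned* cue — an echo-like auditory delay that signals the
distance of a hidden target — paired with a noisy visual cue, in a
five-session training paradigm on a 10–35 m virtual response line.

Two behavioural markers identify reliability-weighted ("Bayes-like")
combination:

1. **Precision gain**: with both cues, response variance falls below the best
   single cue's variance.
2. **Reweighting**: when the visual cue's reliability changes and no feedback
   is available on bimodal trials, the weight given to vision shifts in the
   reliability-tracking direction.

The package provides the stimulus/design generators, a family of simulated
observers that do or do not integrate, the error statistics and paired tests
for marker 1, a hierarchical Bayesian model for marker 2, and simulation
batteries that certify the whole procedure.

## Stimuli and trial design

**Echo-delay cue.** A 5 ms click (sine at 4000 or 2000 Hz, first half-period
scaled to 0.6, exponential decay mask ramping its exponent linearly from 0 at
1.5 periods to −10 at 5 ms) is embedded in ≥1 s of silence with its onset at
50 ms, followed by a sample-exact copy delayed by `2·d/350` s (speed of sound
≈ 350 m/s). For distances ≥ 10 m the delay (≥ 57 ms) always exceeds the click
length, so the two clicks never overlap. `synthesize_click_pair()` extends
the buffer when a delay would run past 1 s (not reachable on the 10–35 m
line) and `write_wav()` emits 24-bit / 96 kHz PCM, matching the lab audio
chain.

**Bubble field.** The visual cue is externally noisy: 256 non-overlapping
spheres (radius 0.15 m) arranged as a mirrored log-normal "violin" whose
half-width at position *x* is proportional to the log-normal density at *x*.
The target is always an actual draw from the displayed distribution, so the
widest cross-section (the density mode, `center·exp(−sd²)`) is the single
best response given vision alone. The packing algorithm is a design choice
(the layout, not the algorithm, is what matters scientifically): the outline
is traced first, starting at the widest point, then the interior is filled by
rejection sampling — positions along the line drawn from the displayed
distribution, cross-section positions uniform in the local disc — with a
bounded attempt budget. The lateral half-width at the mode defaults to 2 m so
that 256 spheres pack comfortably at every spread the design uses; all of
this is deterministic under a seed.

**Matched triplets.** Sessions 3–5 are built in triplets, starting from the
audio-visual specification: visual centres spaced evenly on the log of the
10–35 m line, the true target drawn from
`Normal(ln center, visual_sd_log²)` on the log scale, the audio cue
signalling the target exactly; the audio-only and visual-only members simply
drop the other cue. The visual spread is calibrated per participant:
`visual_sd_log = ratio × audio_sd_log`, with ratio 0.75 or 1.25. We read the
ratio as applying to the SD (the calibration text's wording); a config switch
(`ratio_applies_to = "variance"`) provides the other reading.

Two numerical choices here deserve note:

* **Edge targets are redrawn, not clipped.** A target drawn off the response
  line would break the "actual draw" property if clipped to the limit, so it
  is redrawn (count logged). The cost is that for centres within ~3 SDs of a
  line limit the distribution of `ln(target) − ln(center)` is truncated; over
  the full design the sample SD sits ~3% below nominal. Distributional
  recovery (KS, SD within 2%) therefore holds for interior centres and is
  tested there.
* **Session totals.** Printed session totals (e.g. 298 or 299 trials) cannot
  all be reconciled with a 40-trial warm-up, 10-trial preview and the triplet
  counts; the triplet counts (83/62/83) are authoritative throughout and the
  totals informational.

Counterbalancing follows the design: half of simulated participants start at
4000 Hz and switch to 2000 Hz in Session 4 (half the reverse), and
orthogonally half see ratio 0.75 in Sessions 3–4 then 1.25 in Session 5
(half the reverse). Feedback rules: Session 3 all trials; Session 4 none on
trials with the new sound; Session 5 none on bimodal trials. Warm-up,
preview and forced-choice trials never enter the statistics.

## Simulated observers

`observer_params()` defines the generative model: on the log scale the audio
percept is `ln(target) + N(0, σ_a²)`, the visual percept is the displayed
centre (the cue's noise is external, carried by the displayed spread;
internal visual noise is available and defaults to 0). The policies span the
hypothesis space: `ideal` (precision-weighted, optionally blind to the
Session-5 reliability change), `fixed` (static weight), `switch` (one cue
per trial — the "subjective alternation" alternative), `best_single` (the
sharpest no-integration null), single-cue responders, and `none`
(cue-ignoring, responding uniformly on the log line — the untrained-control
floor, compared against the closed-form centre-of-line baseline
`untrained_baseline_ve()`). A constant log bias and Gaussian motor noise are
added, and responses are clamped to the physical 10–35 m line (clamp counts
reported, since clamping thins the tails; variance oracles in the test suite
use interior designs for exactly this reason).

Defaults are the study conditions: 12 participants, 83/62/83 triplets,
σ_a = 0.12 log units (placing variable errors near the 0.01 scale on which
the analyses operate), motor SD 0.03 and bias −0.024 (the magnitude of bias
the paradigm typically shows). These are fixture choices, stated once here,
not tuning knobs.

## Error statistics

All responses and targets are log-transformed (delays grow harder to
discriminate linearly with distance, and the response line is log-spaced).
Per participant × session × trial type (108 cells in the full design):

* constant error `CE = Σ(ln R − ln T)/n` — the bias component;
* per-trial variable error `VE = (ln R − ln T − CE)²` — the precision
  component. `VE = 0.01` corresponds to a response SD of 10.5% of the target
  distance (1.1 m at 10 m, 3.7 m at 35 m).

The **best single cue** per participant-session is the unimodal condition
with the lower mean VE (ties, which have measure zero but can follow
clamping, go to audio and are logged). Each audio-visual trial's VE is paired
with the VE of the best single cue's trial *from the same triplet*; the pairs
enter a two-tailed Wilcoxon sign-rank test (zero differences dropped; exact
null distribution up to n = 25 without ties, otherwise the tie-corrected,
continuity-corrected normal approximation) and a bootstrap effect size: the
difference between 100% and the ratio of the smaller to the larger mean VE,
with a percentile CI over 10,000 pair resamples.

The **ideal-integrator benchmark** is `(σ_a⁻² + σ_v⁻²)⁻¹` computed from the
two single-cue mean VEs of the cell, paired against each audio-visual trial's
VE — the only construction that reproduces the design's printed pair counts
(2736 omnibus, 996 in Session 3). One honest caveat, worth stating because it
constrains interpretation: against a cell-constant reference the sign-rank
test is *directional*, not calibrated — per-trial VEs are χ²-skewed, so even
an exactly optimal integrator produces a non-null sign-rank statistic. The
calibrated quantities for optimality claims are the effect size (→ 0 for an
ideal integrator as motor noise → 0) and the `optimality_gap()` ratio (→ 1);
the test suite asserts those, and the z value serves as a direction summary,
as in the original analyses.

`visual_reliance()` implements the model-free reweighting check — mean
|ln response − ln visual centre| on bimodal trials, lower = more reliance —
and `alternative_error_metrics()` the robustness variants (total error
without bias correction; per-participant mean VE, 12 pairs).

## The reweighting model

For audio-visual trials of Sessions 3 and 5 (log scale; A = ln target since
the audio cue signals the target exactly — audio perceptual noise is absorbed
into the response precision):

* Lower layer: `Y_ijk ~ Normal(W_ij·V_ijk + (1−W_ij)·A_ijk, precision τ_ij)`.
* Upper layer: `W_i5 = Φ(Φ⁻¹(W_i3) − R_i)` for participants whose visual
  reliability decreased, `Φ(Φ⁻¹(W_i3) + R_i)` for increased;
  `R_i ~ Normal(M, precision T)`.
* Priors: `W_i3 ~ Uniform(0,1)` (independent per participant — no pooling of
  the Session-3 weights), `τ_ij ~ Exponential(rate 0.001)`,
  `M ~ Normal(0, precision 1)`, `T ~ Exponential(rate 0.001)` (prior mean
  1000 — extremely vague). Normal distributions are parameterized by
  precision throughout this module.

A positive M is the Bayesian signature; M = 0 is a static learned weighting.
The model can represent weights arbitrarily close to 0 or 1 (cue selection /
weak interaction) and is free to find an M interval containing zero — the
`label_swap_check()` demonstrates this by flipping half of each direction
group's labels, which must pull the M interval back over zero on
direction-consistent data.

**Sampler.** The model is small, so the fit uses a bespoke
Metropolis-within-Gibbs sampler rather than an external engine; its contract
is distributional correctness, verified against a conjugate reduction (with
weights fixed, the τ full conditional is Gamma(1 + n/2, 0.001 + RSS/2); the
sampled draws match it by KS test). Design choices:

* `W_i3` is sampled on the probit scale (random walk on `Φ⁻¹(W)` with the
  Jacobian giving the implied flat prior) to avoid boundary sticking; a
  `w_scale = "uniform"` flag provides naive uniform-scale sampling for
  cross-checking (the two agree to ~10⁻³ in posterior means).
* `τ_ij`, `M`, `T` have conjugate full conditionals under these priors and
  are drawn exactly inside the sweep; only the weights and `R_i` need
  Metropolis. With sufficient statistics the likelihood is O(1) per block,
  so the default 6 chains × 25,000 retained samples (5,000 burn-in each;
  150,000 used samples) run in about a minute.
* Proposal scales adapt toward 0.44 acceptance during burn-in only, frozen
  before any retained draw; several Metropolis sweeps per iteration
  (`n_inner = 3`) shorten the autocorrelation time of M.
* Diagnostics: split-R̂ per parameter (warning above 1.05) and an effective
  sample size for M (the default settings give ESS(M) well above 1000);
  burn-in is discarded per chain before pooling, no thinning.
* Credible intervals are central percentile intervals (an HPD convention
  would differ only in asymmetric posteriors; the choice is stated rather
  than silent).
* Eq. scale: the model is fitted on log distances, consistent with every
  other analysis in the pipeline; the linear-scale alternative is not
  implemented.

Calibration has a design-size caveat found during validation: at the study
size (12 participants × 83 triplets) the 95% interval for M shows nominal
behaviour under a zero-reweighting truth (0/8 spurious exclusions in our
battery), but for much smaller cohorts (6 × 40) the hierarchical interval is
markedly anticonservative (~25% exclusions). Recovery and calibration claims
are therefore made — and tested — at the study size only.

## Validation simulations

* **Type-I error** (`type1_error_sim()`): null cohorts in which audio-visual
  responses are generated from the best single cue's response process — the
  sharpest null for the pairing procedure, since both members of every pair
  then share a response distribution. Each replicate runs the full analysis
  path. At 3000 replicates the measured level is 4.97% ± 0.4 at α = 0.05
  (and ~1% at α = 0.01): the matched-pair procedure holds its nominal level.
  The default 1000 replicates resolve the level to ±1.4 percentage points.
* **Recovery battery** (`recovery_battery()`): ideal integrators (true
  reweighting known from `ideal_weight()`), fixed-weight grids (zero true
  reweighting), 50/50 switchers and near-zero-weight cue-selection observers.
  Weights are recovered within ±0.1 (RMSE < 0.1) at the study size; the M
  interval excludes zero under true reweighting and keeps coverage under
  zero reweighting; switchers yield no audio-visual benefit over the best
  single cue (discriminant validity).
* **Optimality gap** (`optimality_gap()`): per-cell ratio of audio-visual
  mean VE to the ideal-integrator prediction; 1 within Monte-Carlo error for
  noiseless-motor ideal observers, > 1 with motor noise, invariant to
  additive log bias.

## What the synthetic data do and do not show

The generator reproduces the design's statistical skeleton: matched triplets,
log-normal response noise, external visual noise calibrated to audio
precision, bounded responses, per-session feedback rules. It does not emulate
learning dynamics within or across sessions, perceptual nonlinearity in the
delay-to-distance mapping beyond the log transform, internal visual noise
(available but zero by default), lapses, or serial dependencies. Green tests
certify that the *pipeline* — statistics, pairing, model, sampler — behaves
correctly on data with the assumed structure; they are not evidence about
real observers. Conversely, the observer family is rich enough to show that
the pipeline *discriminates*: integrators, switchers, rote learners and
cue-ignorers produce the distinct signatures described above.

## Problem sizes used in the shipped checks

The test suite simulates cohorts at the study size (12 × 83/62/83) for design
arithmetic and inference checks, 10⁴-triplet single-observer runs for
variance convergence, a 20-replicate recovery battery with 2 × 1,500-sample
chains, and a 1000-replicate type-I simulation; the acceptance script runs
the same type-I simulation at 1000 replicates. The full-default sampler
settings (6 × 25,000) are exercised in documentation examples and
`run_pipeline()` defaults rather than in every test, a deliberate economy
since the small-chain fits are validated against the same oracles.
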