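# cuefuse

Simulation and analysis pipeline for **Bayes-like cue combination with a newly
learned distance cue**. The scientific question: when people are taught a novel
sensory skill — judging distance from an echo-like delay between a click and
its copy — do they *integrate* it with vision the way they integrate familiar
cues, i.e. by reliability-weighted averaging? `cuefuse` is for
psychophysicists and modellers who want to simulate such experiments, analyse
trial data (their own or synthetic), and stress-test the statistical
machinery before touching real participants.

## The model and statistics at the core

On each trial a participant sees a noisy visual cue (a "bubble field" whose
widest point marks the most probable target position, external spread
σ_v) and/or hears an echo-delay cue signalling the target exactly (delay
= 2d/350 s), then marks a distance on a 10–35 m response line. All analysis is
on the natural-log scale.

* **Error decomposition.** Per participant × session × trial type:
  constant error `CE = mean(ln R − ln T)` (bias) and per-trial variable error
  `VE = (ln R − ln T − CE)²` (precision).
* **Integration test.** Each audio-visual trial's VE is paired with the VE of
  the *best single cue's* trial from the same matched triplet (same target,
  participant, session); a two-tailed Wilcoxon sign-rank test and a bootstrap
  effect size (`100·(1 − min/max)` of the two mean VEs) quantify the precision
  gain.
* **Ideal-integrator benchmark.** σ²_opt = (σ_a⁻² + σ_v⁻²)⁻¹, computed from
  the single-cue mean VEs per participant-session.
* **Reweighting model.** A two-layer hierarchical Bayesian model of the
  audio-visual trials of Sessions 3 and 5:
  `Y ~ N(W_ij·V + (1−W_ij)·A, precision τ_ij)` with
  `W_i5 = Φ(Φ⁻¹(W_i3) ∓ R_i)` (sign by the direction of the visual-reliability
  change) and `R_i ~ N(M, precision T)`. Priors: `W_i3 ~ U(0,1)`,
  `τ, T ~ Exponential(0.001)`, `M ~ N(0, precision 1)`. A posterior for M
  excluding zero is the signature of reliability-tracking reweighting. Fitted
  by a built-in Metropolis-within-Gibbs sampler (probit-scale weight updates;
  conjugate draws for τ, M, T), with split-R̂ and ESS diagnostics.

## Worked example

```r
library(cuefuse)

# 12 simulated ideal integrators run the Session 3-5 design
designs <- make_cohort_designs(12, sessions = 3:5, seed = 101)
trials  <- simulate_experiment(
  lapply(1:12, function(i) observer_params(sigma_audio_log = 0.12,
                                           weighting_policy = "ideal",
                                           motor_sd_log = 0.03,
                                           bias_log = -0.024)),
  designs, seed = 102)

pairs <- pair_av_vs_best(trials)
nrow(pairs)
#> [1] 2736
signrank_test(pairs)
#> Sign-rank test (normal approximation): z = 11.318, p = 1.073e-29, n = 2736
ve_change(pairs, n_boot = 10000, seed = 1)$effect_pct
#> [1] 35.53388
```

2736 matched pairs (12 participants × 83+62+83 triplets); the positive z and
the ~36% variable-error reduction say these observers respond more precisely
with both cues than with their best single cue — the first marker of
Bayes-like combination. `cue_contrasts()` produces the full per-session table
with bootstrap CIs, `fit_reweighting()` + `summarize_reweighting()` give the
per-participant weights and the credible interval for the mean reweighting M,
and `run_pipeline(cf_config(...))` runs everything and writes the report
files.

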