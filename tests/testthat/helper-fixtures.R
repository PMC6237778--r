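# Shared fixtures: small simulated cohorts built in code at test time.

# A compact Session 3+5 cohort design (both reliability-change directions).
tiny_designs <- function(np = 4, sessions = c(3, 5), seed = 1) {
  make_cohort_designs(np, sessions = sessions, seed = seed)
}

ideal_cohort <- function(np, motor_sd_log = 0.03, bias_log = 0, ...) {
  lapply(seq_len(np), function(i) {
    observer_params(weighting_policy = "ideal", motor_sd_log = motor_sd_log,
                    bias_log = bias_log, ...)
  })
}

# Full-size cohort trials shared across test files (computed once per run).
full_ideal_trials <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- make_cohort_designs(12, sessions = 3:5, seed = 101)
      cache <<- simulate_experiment(
        ideal_cohort(12, motor_sd_log = 0.03, bias_log = -0.024),
        d, seed = 102)
    }
    cache
  }
})

# A hand-built trial table where responses are exact, for closed-form checks.
exact_trials <- function(np = 2, n_trip = 6, session = 3) {
  rows <- lapply(seq_len(np), function(i) {
    block <- make_triplet_block(n_trip, 0.12, seed = i)
    expand_triplets(block, sprintf("P%02d", i), session)
  })
  out <- dplyr::bind_rows(rows)
  out$response_m <- out$target_m
  out
}

small_mcmc <- function(seed = 1, n_chains = 2, n_samples = 2000,
                       n_burnin = 800) {
  mcmc_config(n_chains = n_chains, n_samples = n_samples,
              n_burnin = n_burnin, seed = seed)
}

# Triplet block with centers away from the line limits, so closed-form
# variance oracles are not distorted by response clamping or target redraws.
interior_block <- function(n, sd_v = 0.09, seed = 1, lo = 16, hi = 22) {
  centers <- exp(seq(log(lo), log(hi), length.out = n))
  targets <- withr::with_seed(seed, exp(rnorm(n, log(centers), sd_v)))
  tibble::tibble(triplet_id = seq_len(n), target_m = targets,
                 visual_center_m = centers, visual_sd_log = sd_v,
                 audio_freq_hz = 4000)
}

expand_triplets <- cuefuse:::expand_triplets
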