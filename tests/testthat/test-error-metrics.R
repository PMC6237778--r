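test_that("constant and variable error follow the log-scale decomposition", {
  t <- c(10, 20, 30)
  expect_equal(constant_error(t, t), 0)
  expect_equal(constant_error(t, t * exp(0.1)), 0.1)
  expect_equal(constant_error(c(10, 10), c(10 * exp(0.2), 10)), 0.1)
  expect_equal(variable_error(c(10, 10), c(10 * exp(0.2), 10), 0.1),
               c(0.01, 0.01))
  expect_equal(variable_error(t, t * exp(0.3), 0.3), rep(0, 3))
  expect_error(constant_error(numeric(0), numeric(0)), "non-empty")
  expect_error(variable_error(t, t, c(0, 0)), "single")
})

test_that("the constant error minimizes mean squared log error over all shifts", {
  set.seed(4)
  targ <- exp(runif(40, log(10), log(35)))
  resp <- pmin(35, pmax(10, targ * exp(rnorm(40, 0.05, 0.15))))
  ce <- constant_error(targ, resp)
  mse <- function(shift) mean(variable_error(targ, resp, shift))
  grid <- seq(-0.5, 0.5, by = 0.001)
  expect_equal(grid[which.min(sapply(grid, mse))], ce, tolerance = 2e-3)
})

test_that("a variable error of 0.01 is a 10.5% spread: 1.1 m at 10 m, 3.7 m at 35 m", {
  expect_equal(ve_to_sd_fraction(0.01), exp(0.1) - 1)
  expect_equal(round(100 * ve_to_sd_fraction(0.01), 1), 10.5)
  expect_equal(round(ve_to_sd_meters(0.01, 10), 1), 1.1)
  expect_equal(round(ve_to_sd_meters(0.01, 35), 1), 3.7)
})

test_that("error summaries cover each cell once and ignore row order", {
  trials <- full_ideal_trials()
  s <- summarize_errors(trials)
  expect_equal(nrow(s), 108) # 12 participants x 3 sessions x 3 types
  expect_equal(nrow(dplyr::distinct(
    s[, c("participant_id", "session", "trial_type")])), 108)
  shuffled <- trials[sample(nrow(trials)), ]
  expect_equal(dplyr::arrange(summarize_errors(shuffled), participant_id,
                              session, trial_type),
               dplyr::arrange(s, participant_id, session, trial_type))
  # exact responders: all zero error
  ex <- summarize_errors(exact_trials())
  expect_true(all(ex$constant_error == 0) && all(ex$mean_ve == 0))
  # warm-up/AFC/preview trials are excluded from the statistics
  d5 <- make_session_design(3, "P01", session_params(), seed = 2)
  t5 <- simulate_experiment(ideal_cohort(1), d5, seed = 3)
  s5 <- summarize_errors(t5)
  expect_equal(sum(s5$n_trials), 3 * 83)
})

test_that("the best single cue is the lower-VE modality, ties to audio", {
  s <- tibble::tibble(
    participant_id = "P01", session = 3,
    trial_type = c("audio", "visual"), n_trials = 10,
    constant_error = 0, mean_ve = c(0.010, 0.020))
  expect_equal(best_single_cue(s, "P01", 3), "audio")
  s$mean_ve <- c(0.020, 0.010)
  expect_equal(best_single_cue(s, "P01", 3), "visual")
  s$mean_ve <- c(0.015, 0.015)
  expect_message(tie <- best_single_cue(s, "P01", 3), "tie")
  expect_equal(tie, "audio")
  expect_error(best_single_cue(s[1, ], "P01", 3), "both")
})

test_that("pairing matches every audio-visual trial to its triplet's reference", {
  trials <- full_ideal_trials()
  pb <- pair_av_vs_best(trials)
  expect_equal(nrow(pb), 2736)
  expect_equal(sum(pb$session == 3), 996)
  expect_equal(sum(pb$session == 4), 744)
  expect_equal(sum(pb$session == 5), 996)
  # single triplet -> exactly one pair
  one <- expand_triplets(make_triplet_block(1, 0.12, seed = 1), "P01", 3)
  one$response_m <- one$target_m * exp(c(0.01, -0.02, 0.005))
  expect_equal(nrow(pair_av_vs_best(one)), 1)
  # a broken triplet is skipped with a warning
  broken <- trials[!(trials$triplet_id %in% 5 & trials$session == 3 &
                       trials$participant_id == "P01" &
                       trials$trial_type %in% c("audio", "visual")), ]
  expect_warning(pbb <- pair_av_vs_best(broken), "skipped")
  expect_equal(nrow(pbb), 2735)
})

test_that("the ideal-integrator reference is below the best single cue in every cell", {
  trials <- full_ideal_trials()
  po <- pair_av_vs_optimal(trials)
  pb <- pair_av_vs_best(trials)
  expect_equal(nrow(po), 2736)
  merged <- dplyr::inner_join(
    po, pb, by = c("participant_id", "session", "triplet_id"),
    suffix = c("_opt", "_best"))
  s <- summarize_errors(trials)
  best_mean <- s |>
    dplyr::filter(trial_type %in% c("audio", "visual")) |>
    dplyr::group_by(participant_id, session) |>
    dplyr::summarise(best = min(mean_ve), .groups = "drop")
  cells <- dplyr::distinct(po[, c("participant_id", "session", "ref_ve")])
  cells <- dplyr::inner_join(cells, best_mean,
                             by = c("participant_id", "session"))
  expect_true(all(cells$ref_ve <= cells$best))
})

test_that("sign-rank test matches exact enumeration and handles ties and zeros", {
  r <- signrank_test(c(1, 2, 3))
  expect_equal(r$p_value, 0.25) # 2 * P(W+ >= 6) = 2/8
  expect_equal(r$method, "exact")
  expect_equal(signrank_test(c(-1, 1))$z, 0)
  expect_warning(r0 <- signrank_test(c(0, 0, 0)), "zero")
  expect_equal(c(r0$p_value, r0$z), c(1, 0))

  # normal approximation tracks the exact tail for moderate n
  set.seed(7)
  for (i in 1:20) {
    d <- rnorm(20, mean = runif(1, -0.5, 0.5))
    exact <- signrank_test(d, exact_max_n = 25)
    approx <- signrank_test(d, exact_max_n = 0)
    expect_equal(exact$method, "exact")
    expect_equal(approx$method, "normal approximation")
    expect_lt(abs(exact$p_value - approx$p_value), 0.02)
  }
  # cross-check against the reference implementation: exact path
  set.seed(8)
  d20 <- rnorm(20)
  expect_equal(signrank_test(d20)$p_value,
               wilcox.test(d20, exact = TRUE)$p.value, tolerance = 1e-12)
  # and the continuity-corrected normal path
  d <- rnorm(40)
  ours <- signrank_test(d)
  ref <- wilcox.test(d, exact = FALSE, correct = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("the VE-change effect size and bootstrap CI behave as designed", {
  pairs <- tibble::tibble(ref_ve = rep(0.012, 50), av_ve = rep(0.010, 50))
  ch <- ve_change(pairs, n_boot = 200, seed = 1)
  expect_equal(ch$effect_pct, 100 * (1 - 0.010 / 0.012))
  expect_equal(unname(ch$ci95), c(ch$effect_pct, ch$effect_pct)) # degenerate
  ch2 <- ve_change(pairs, n_boot = 200, seed = 1)
  expect_identical(ch, ch2) # seeded determinism
  set.seed(2)
  noisy <- tibble::tibble(ref_ve = rchisq(200, 1) * 0.012,
                          av_ve = rchisq(200, 1) * 0.010)
  ch3 <- ve_change(noisy, n_boot = 500, seed = 3)
  expect_true(ch3$effect_pct >= 0 && ch3$effect_pct < 100)
  expect_true(ch3$ci95[1] <= ch3$effect_pct + 1e-9 &&
                ch3$effect_pct <= ch3$ci95[2] + 1e-9)
  expect_error(ve_change(tibble::tibble(ref_ve = 0, av_ve = 0),
                         n_boot = 100), "zero")
})

test_that("contrast table reports both contrasts per grouping with sensible signs", {
  trials <- full_ideal_trials()
  ct <- cue_contrasts(trials, n_boot = 200, seed = 1)
  expect_equal(nrow(ct), 8) # (omnibus + 3 sessions) x 2 contrasts
  best <- ct[ct$contrast == "best_single_vs_av", ]
  # integrating observers beat their best single cue in every grouping
  expect_true(all(best$z > 0))
  expect_true(all(best$p_value < 0.01))
  expect_true(all(best$ve_change_pct > 0))
  expect_true(all(best$ci_low <= best$ve_change_pct &
                    best$ve_change_pct <= best$ci_high))
})

test_that("visual reliance tracks the weight given to vision", {
  trials <- full_ideal_trials()
  rel <- visual_reliance(trials)
  expect_equal(nrow(rel), 36) # 12 participants x 3 sessions
  # reliance statistic is larger (further from the center) when the visual
  # cue is less reliable, pooling over participant-sessions
  lo <- rel$reliance[rel$visual_sd_log == 0.75 * 0.12]
  hi <- rel$reliance[rel$visual_sd_log == 1.25 * 0.12]
  expect_gt(mean(hi), mean(lo))
  # responding at the center exactly gives zero reliance
  ex <- exact_trials()
  av <- ex$trial_type == "audiovisual"
  ex$response_m[av] <- ex$visual_center_m[av]
  expect_equal(unique(visual_reliance(ex)$reliance), 0)
  # a vision-ignoring observer's reliance is the audio percept's distance
  # from the center: E|N(log t - log c, sigma_a)| on the triplet offsets
  d <- expand_triplets(interior_block(5000, 0.09, seed = 21), "P01", 3)
  tr <- simulate_experiment(list(observer_params(0.12, "audio_only")), d,
                            seed = 22)
  avt <- tr[tr$trial_type == "audiovisual", ]
  mu <- log(avt$target_m) - log(avt$visual_center_m)
  oracle <- mean(abs(rnorm(length(mu) * 20, mu, 0.12)))
  expect_equal(visual_reliance(tr)$reliance, oracle, tolerance = 0.02)
})

test_that("manipulation check: visual variance drives visual-only variable error", {
  trials <- full_ideal_trials()
  s <- summarize_errors(trials)
  vi <- s[s$trial_type == "visual", ]
  sds <- visual_reliance(trials)[, c("participant_id", "session",
                                     "visual_sd_log")]
  vi <- dplyr::inner_join(vi, sds, by = c("participant_id", "session"))
  expect_gt(cor(vi$visual_sd_log^2, vi$mean_ve), 0.7)
})

test_that("robustness variants: total error and per-participant aggregation", {
  trials <- full_ideal_trials()
  # unbiased cells: total error equals variable error on average
  d <- expand_triplets(make_triplet_block(2000, 0.12, seed = 23), "P01", 3)
  tr <- simulate_experiment(list(observer_params(0.12, "ideal")), d,
                            seed = 24)
  te <- alternative_error_metrics(tr, "total_error")
  ve <- pair_av_vs_best(tr)
  expect_equal(mean(te$pairs$av_ve), mean(ve$av_ve), tolerance = 0.02)
  # total error >= variable error per cell (bias inflates it)
  trb <- full_ideal_trials()
  tot <- alternative_error_metrics(trb, "total_error")
  expect_gte(mean(tot$pairs$av_ve), mean(pair_av_vs_best(trb)$av_ve) - 1e-12)
  # per-participant aggregation gives one pair per participant
  mv <- alternative_error_metrics(trials, "mean_ve")
  expect_equal(nrow(mv$pairs), 12)
  expect_s3_class(mv$test, "cf_signrank")
  expect_error(alternative_error_metrics(trials, "median"), "arg")
})
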