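# A small direction-balanced cohort and its model data, shared in this file.
rw_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- make_cohort_designs(6, sessions = c(3, 5), seed = 31)
      tr <- simulate_experiment(ideal_cohort(6, motor_sd_log = 0.02), d,
                                seed = 32)
      cache <<- reweighting_data(tr)
    }
    cache
  }
})

test_that("model data carries both sessions and derives directions from the display", {
  rd <- rw_fixture()
  expect_s3_class(rd, "reweighting_data")
  expect_equal(length(rd$directions), 6)
  expect_setequal(unique(rd$directions), c("decreased", "increased"))
  # higher Session-5 spread = decreased reliability
  sds <- rd$trials |>
    dplyr::group_by(participant_id, session) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop")
  expect_true(all(table(sds$participant_id) == 2))
  # a participant missing one session is refused
  d1 <- make_cohort_designs(2, sessions = 3, seed = 1)
  t1 <- simulate_experiment(ideal_cohort(2), d1, seed = 2)
  expect_error(reweighting_data(t1), "both sessions")
})

test_that("the probit link maps reweighting effects onto (0,1) weights", {
  expect_equal(cuefuse:::w5_from(0.5, 0, "increased"), 0.5)
  expect_equal(cuefuse:::w5_from(0.5, 1.6449, "increased"), 0.95,
               tolerance = 1e-4)
  expect_equal(cuefuse:::w5_from(0.5, 1.6449, "decreased"), 0.05,
               tolerance = 1e-4)
  # derived Session-5 draws are a deterministic function of w3, r, direction
  rd <- rw_fixture()
  fit <- suppressWarnings( # short diagnostic chains trip the Rhat gate
    fit_reweighting(rd, small_mcmc(seed = 33, n_samples = 300,
                                   n_burnin = 200)))
  i <- 2
  dir_i <- unname(rd$directions[fit$participants[i]])
  expect_equal(as.vector(fit$draws$w5[, , i]),
               cuefuse:::w5_from(as.vector(fit$draws$w3[, , i]),
                                 as.vector(fit$draws$r[, , i]), dir_i))
})

test_that("log posterior is finite on support, -Inf off it, and matches priors", {
  rd <- rw_fixture()
  np <- length(rd$directions)
  params <- list(w3 = rep(0.5, np), r = rep(0, np), tau3 = rep(50, np),
                 tau5 = rep(50, np), m = 0, t = 1)
  lp <- log_posterior(params, rd)
  expect_true(is.finite(lp))
  bad <- params; bad$w3[1] <- 1.2
  expect_equal(log_posterior(bad, rd), -Inf)
  bad <- params; bad$tau5[2] <- -1
  expect_equal(log_posterior(bad, rd), -Inf)
  bad <- params; bad$t <- 0
  expect_equal(log_posterior(bad, rd), -Inf)
  # moving m against the standard-normal prior changes lp by the prior term
  p2 <- params; p2$m <- 1
  expect_equal(log_posterior(p2, rd) - lp,
               dnorm(1, log = TRUE) - dnorm(0, log = TRUE) +
                 sum(dnorm(rep(0, np), 1, 1, log = TRUE)) -
                 sum(dnorm(rep(0, np), 0, 1, log = TRUE)))
  # finite at a random prior draw
  set.seed(1)
  draw <- list(w3 = runif(np), r = rnorm(np, 0, 1), tau3 = rexp(np, 0.001),
               tau5 = rexp(np, 0.001), m = rnorm(1), t = rexp(1, 0.001))
  expect_true(is.finite(log_posterior(draw, rd)))
})

test_that("sufficient-statistic likelihood agrees with the direct log posterior", {
  rd <- rw_fixture()
  np <- length(rd$directions)
  ss <- cuefuse:::suff_stats(rd)
  set.seed(2)
  base <- list(w3 = runif(np), r = rnorm(np), tau3 = rexp(np, 1 / 50) + 1,
               tau5 = rexp(np, 1 / 50) + 1, m = 0.2, t = 2)
  alt <- base; alt$w3 <- runif(np)
  # difference of direct log posteriors at two weight vectors equals the
  # difference of the sampler's O(1) likelihood (priors on w are flat)
  rss <- function(s, w) s$see - 2 * w * s$seg + w^2 * s$sgg
  ll <- function(w3) {
    w5 <- cuefuse:::w5_from(w3, base$r, rd$directions)
    sum(0.5 * ss$`3`$n * log(base$tau3) - 0.5 * base$tau3 * rss(ss$`3`, w3)) +
      sum(0.5 * ss$`5`$n * log(base$tau5) - 0.5 * base$tau5 * rss(ss$`5`, w5))
  }
  expect_equal(log_posterior(alt, rd) - log_posterior(base, rd),
               ll(alt$w3) - ll(base$w3), tolerance = 1e-8)
})

test_that("with weights fixed, precision draws match the conjugate Gamma posterior", {
  rd <- rw_fixture()
  np <- length(rd$directions)
  truth <- list(w3 = rep(0.6, np), r = rep(0.3, np))
  fit <- fit_reweighting(rd, small_mcmc(seed = 34, n_samples = 4000,
                                        n_burnin = 200), fix = truth)
  ss <- cuefuse:::suff_stats(rd)
  w5 <- cuefuse:::w5_from(truth$w3, truth$r, rd$directions)
  for (i in c(1, 4)) {
    draws <- as.vector(fit$draws$tau3[, , i])
    shape <- 1 + ss$`3`$n[i] / 2
    rate <- 0.001 + (ss$`3`$see[i] - 2 * 0.6 * ss$`3`$seg[i] +
                       0.36 * ss$`3`$sgg[i]) / 2
    ks <- suppressWarnings(ks.test(draws, "pgamma", shape, rate))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("the exponential prior on the effect precision has mean 1000", {
  rate <- cuefuse:::TAU_PRIOR_RATE
  set.seed(5)
  expect_equal(mean(rexp(2e5, rate)), 1000, tolerance = 0.02)
})

test_that("weights and the reweighting mean are recovered from simulated data", {
  # generative: known weights and reweighting on the probit scale
  set.seed(41)
  np <- 6
  pids <- sprintf("P%02d", 1:np)
  dirs <- rep(c("decreased", "increased"), each = 3)
  w3 <- c(0.70, 0.65, 0.72, 0.68, 0.71, 0.66)
  r_true <- 0.5
  w5 <- cuefuse:::w5_from(w3, rep(r_true, np), dirs)
  rows <- list()
  for (i in 1:np) {
    for (s in c(3L, 5L)) {
      n <- 83
      a <- runif(n, log(10), log(35))
      v <- a + rnorm(n, 0, 0.25) # well-separated cues identify w sharply
      w <- if (s == 3L) w3[i] else w5[i]
      y <- w * v + (1 - w) * a + rnorm(n, 0, 1 / sqrt(100))
      rows[[length(rows) + 1]] <- tibble::tibble(
        participant_id = pids[i], session = s, phase = "main",
        trial_type = "audiovisual", n_afc = 0L,
        triplet_id = seq_len(n), target_m = exp(a),
        visual_center_m = exp(v), visual_sd_log = 0.1,
        audio_freq_hz = 4000, feedback = FALSE, response_m = exp(y))
    }
  }
  trials <- dplyr::bind_rows(rows)
  rd <- reweighting_data(trials, directions = tibble::tibble(
    participant_id = pids, direction = dirs))
  fit <- fit_reweighting(rd, small_mcmc(seed = 42, n_samples = 3000,
                                        n_burnin = 1000))
  s <- summarize_reweighting(fit)
  expect_true(all(abs(s$participants$w3_mean - w3) < 0.1))
  expect_true(all(s$participants$w3_lo <= w3 + 0.02 &
                    w3 - 0.02 <= s$participants$w3_hi))
  expect_lt(abs(s$m["mean"] - r_true), 0.3)
  expect_gt(s$m["lo"], 0) # true reweighting: interval excludes zero
  # precision draws concentrate near the generative value 100
  expect_equal(mean(fit$draws$tau3), 100, tolerance = 0.15)
})

test_that("a near-zero-weight cue-selection observer is representable", {
  d <- expand_triplets(make_triplet_block(400, 0.12, 0.75, seed = 43),
                       "P01", 3)
  d5 <- expand_triplets(make_triplet_block(400, 0.12, 1.25, seed = 44),
                        "P01", 5)
  tr <- simulate_experiment(
    list(observer_params(0.12, "fixed", w_visual = 0.02,
                         motor_sd_log = 0.01)),
    dplyr::bind_rows(d, d5), seed = 45)
  rd <- reweighting_data(tr)
  fit <- suppressWarnings(
    fit_reweighting(rd, small_mcmc(seed = 46, n_samples = 2000,
                                   n_burnin = 800)))
  w3 <- mean(fit$draws$w3)
  expect_lt(w3, 0.1)
})

test_that("fits are reproducible and chains agree", {
  rd <- rw_fixture()
  f1 <- suppressWarnings(fit_reweighting(rd, small_mcmc(seed = 47,
                                                        n_samples = 500,
                                                        n_burnin = 300)))
  f2 <- suppressWarnings(fit_reweighting(rd, small_mcmc(seed = 47,
                                                        n_samples = 500,
                                                        n_burnin = 300)))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(fit_reweighting(rd, small_mcmc(seed = 48,
                                                        n_samples = 500,
                                                        n_burnin = 300)))
  expect_false(identical(f1$draws$m, f3$draws$m))
  # degenerate data are refused
  rd_bad <- rd
  rd_bad$trials$y <- 3
  expect_error(fit_reweighting(rd_bad, small_mcmc()), "constant")
})

test_that("posterior intervals widen as draws are thinned away", {
  rd <- rw_fixture()
  fit <- fit_reweighting(rd, small_mcmc(seed = 49, n_samples = 5000,
                                        n_burnin = 500))
  m_all <- as.vector(fit$draws$m)
  width <- function(x) diff(quantile(x, c(0.025, 0.975)))
  # Monte-Carlo error scaling: the interval estimated from 1% of the draws
  # varies around the full-sample interval far more than chunks of half
  set.seed(50)
  w_full <- width(m_all)
  spread_small <- sd(replicate(200, width(sample(m_all, length(m_all) / 100))))
  spread_half <- sd(replicate(200, width(sample(m_all, length(m_all) / 2))))
  expect_gt(spread_small, spread_half)
  expect_lt(abs(width(sample(m_all, length(m_all) / 2)) - w_full),
            0.5 * w_full)
})

test_that("swapping direction labels twice restores the original fit", {
  rd <- rw_fixture()
  ids <- names(rd$directions)[c(1, 4)]
  rd2 <- swap_directions(swap_directions(rd, ids), ids)
  expect_identical(rd, rd2)
  cfg <- small_mcmc(seed = 51, n_samples = 400, n_burnin = 200)
  expect_identical(suppressWarnings(fit_reweighting(rd, cfg)$draws),
                   suppressWarnings(fit_reweighting(rd2, cfg)$draws))
  expect_error(swap_directions(rd, "P99"), "unknown")
  # the swap check needs 6 participants per direction group
  expect_error(label_swap_check(rd, cfg), "at least 6")
})
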