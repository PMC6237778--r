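# Simulation studies that certify the pipeline: type-I error of the matched
# pairing procedure, parameter-recovery batteries, and the end-to-end
# optimality check.

#' Type-I error of the matched-pair variable-error procedure
#'
#' Simulates null cohorts in which the audio-visual trials are generated from
#' the best single cue's response process — the sharpest null for the
#' best-single-vs-audio-visual contrast, since the two members of every pair
#' then come from the same response distribution. Each replicate runs the
#' full analysis path ([summarize_errors()] via [pair_av_vs_best()], then the
#' two-tailed [signrank_test()]) and records the p-value; the report gives
#' the fraction below `alpha`.
#'
#' @param n_replicates Simulated experiments (>= 100; default 1000).
#' @param cohort_size Participants per cohort (default 12; half see the
#'   0.75 visual/audio SD ratio, half 1.25).
#' @param n_triplets Matched triplets per participant (default 83).
#' @param audio_sd_log Audio noise SD, log units.
#' @param motor_sd_log,bias_log Response (motor) noise SD and constant bias of
#'   the simulated observers, log units.
#' @param alpha Nominal significance threshold (default 0.05).
#' @param seed Integer seed; the report is reproducible given it.
#' @return A `simulation_report` list: `scenario`, `n_replicates`,
#'   `p_values`, `z_values`, `fraction_significant`, `alpha`, `seed`.
#' @export
type1_error_sim <- function(n_replicates = 1000, cohort_size = 12,
                            n_triplets = 83, audio_sd_log = 0.12,
                            motor_sd_log = 0.03, bias_log = -0.024,
                            alpha = 0.05, seed = 1) {
  cf_assert(n_replicates >= 100, "`n_replicates` must be >= 100")
  cf_assert(cohort_size >= 2, "`cohort_size` must be >= 2")
  pids <- sprintf("P%02d", seq_len(cohort_size))
  ratios <- rep_len(c(0.75, 1.25), cohort_size)
  cohort <- stats::setNames(lapply(seq_len(cohort_size), function(i) {
    observer_params(sigma_audio_log = audio_sd_log,
                    weighting_policy = "best_single",
                    bias_log = bias_log, motor_sd_log = motor_sd_log)
  }), pids)

  p_values <- z_values <- numeric(n_replicates)
  for (rep_i in seq_len(n_replicates)) {
    rseed <- substream_seed(seed, paste0("type1-", rep_i))
    designs <- dplyr::bind_rows(lapply(seq_len(cohort_size), function(i) {
      block <- make_triplet_block(
        n_triplets, audio_sd_log, sd_ratio = ratios[i],
        seed = substream_seed(rseed, pids[i]))
      expand_triplets(block, pids[i], session = 3L)
    }))
    trials <- simulate_experiment(cohort, designs,
                                  seed = substream_seed(rseed, "responses"))
    tst <- signrank_test(pair_av_vs_best(trials))
    p_values[rep_i] <- tst$p_value
    z_values[rep_i] <- tst$z
  }
  structure(list(scenario = "no-integration null (best single cue)",
                 n_replicates = n_replicates, p_values = p_values,
                 z_values = z_values,
                 fraction_significant = mean(p_values < alpha),
                 alpha = alpha, seed = seed),
            class = "simulation_report")
}

#' @export
print.simulation_report <- function(x, ...) {
  cat(sprintf("<simulation_report> %s: %d replicates\n", x$scenario,
              x$n_replicates))
  if (!is.null(x$fraction_significant)) {
    cat(sprintf("  fraction p < %.3g: %.4f\n", x$alpha,
                x$fraction_significant))
  }
  invisible(x)
}

# One recovery replicate: simulate a Session 3 + Session 5 cohort under a
# scenario, fit the reweighting model, and run the best-single contrast.
recovery_replicate <- function(scenario, cohort_size, n_triplets,
                               audio_sd_log, motor_sd_log, mcmc, seed) {
  pids <- sprintf("P%02d", seq_len(cohort_size))
  ratio_first <- rep_len(c(0.75, 1.25), cohort_size)
  w_grid <- seq(0.1, 0.9, by = 0.1)

  cohort <- stats::setNames(lapply(seq_len(cohort_size), function(i) {
    switch(scenario,
      ideal = observer_params(audio_sd_log, "ideal",
                              motor_sd_log = motor_sd_log),
      fixed_w = observer_params(audio_sd_log, "fixed",
                                w_visual = w_grid[(i - 1) %% 9 + 1],
                                motor_sd_log = motor_sd_log),
      switcher = observer_params(audio_sd_log, "switch", p_visual = 0.5,
                                 motor_sd_log = motor_sd_log),
      cue_selection = observer_params(audio_sd_log, "fixed", w_visual = 0.02,
                                      motor_sd_log = motor_sd_log),
      stop("unknown scenario: ", scenario, call. = FALSE))
  }), pids)

  designs <- dplyr::bind_rows(lapply(seq_len(cohort_size), function(i) {
    dplyr::bind_rows(lapply(c(3L, 5L), function(s) {
      ratio <- if (s == 3L) ratio_first[i] else
        setdiff(c(0.75, 1.25), ratio_first[i])
      block <- make_triplet_block(
        n_triplets, audio_sd_log, sd_ratio = ratio,
        seed = substream_seed(seed, paste0(pids[i], "-s", s)))
      expand_triplets(block, pids[i], session = s)
    }))
  }))
  trials <- simulate_experiment(cohort, designs,
                                seed = substream_seed(seed, "responses"))

  true_w3 <- vapply(seq_len(cohort_size), function(i) {
    switch(scenario,
      ideal = ideal_weight(audio_sd_log^2,
                           (ratio_first[i] * audio_sd_log)^2),
      fixed_w = w_grid[(i - 1) %% 9 + 1],
      cue_selection = 0.02,
      switcher = NA_real_)
  }, numeric(1))

  mcmc$seed <- substream_seed(seed, "mcmc")
  fit <- suppressWarnings(fit_reweighting(reweighting_data(trials), mcmc))
  summ <- summarize_reweighting(fit)
  contrast <- signrank_test(pair_av_vs_best(trials))
  list(summary = summ, true_w3 = true_w3, contrast = contrast)
}

#' Parameter-recovery battery for the reweighting model
#'
#' For each generative scenario — ideal integrators, fixed-weight observers
#' on a 0.1-0.9 weight grid (zero true reweighting), 50/50 cue switchers, and
#' a near-zero-weight cue-selection observer — simulates Session 3 + Session
#' 5 cohorts, fits the reweighting model, and aggregates weight-recovery
#' error (bias, RMSE, interval coverage), the mean-reweighting interval, and
#' the best-single contrast outcome.
#'
#' @param scenarios Character vector from `"ideal"`, `"fixed_w"`,
#'   `"switcher"`, `"cue_selection"`.
#' @param n_replicates Replicates per scenario.
#' @param cohort_size,n_triplets Design size per replicate.
#' @param audio_sd_log,motor_sd_log Observer noise, log units.
#' @param mcmc An [mcmc_config()]; the default here is deliberately small so
#'   a battery finishes in minutes.
#' @param seed Integer seed.
#' @return A `simulation_report` with a per-replicate `results` tibble and a
#'   per-scenario `aggregate` tibble (weight bias/RMSE/coverage, fraction of
#'   M intervals excluding zero, fraction of significant best-single
#'   contrasts).
#' @export
recovery_battery <- function(scenarios = c("ideal", "fixed_w", "switcher"),
                             n_replicates = 5, cohort_size = 12,
                             n_triplets = 83, audio_sd_log = 0.12,
                             motor_sd_log = 0.02,
                             mcmc = mcmc_config(n_chains = 2,
                                                n_samples = 2500,
                                                n_burnin = 1000),
                             seed = 1) {
  cf_assert(n_replicates >= 1, "`n_replicates` must be >= 1")
  rows <- list()
  for (sc in scenarios) {
    for (rep_i in seq_len(n_replicates)) {
      rr <- recovery_replicate(sc, cohort_size, n_triplets, audio_sd_log,
                               motor_sd_log, mcmc,
                               substream_seed(seed,
                                              paste0(sc, "-", rep_i)))
      per <- rr$summary$participants
      w_err <- per$w3_mean - rr$true_w3 # all NA when no generative weight
      cover <- rr$true_w3 >= per$w3_lo & rr$true_w3 <= per$w3_hi
      rows[[length(rows) + 1]] <- tibble::tibble(
        scenario = sc, replicate = rep_i,
        w3_bias = mean(w_err, na.rm = TRUE),
        w3_rmse = sqrt(mean(w_err^2, na.rm = TRUE)),
        w3_coverage = mean(cover, na.rm = TRUE),
        m_mean = rr$summary$m["mean"], m_lo = rr$summary$m["lo"],
        m_hi = rr$summary$m["hi"],
        m_excludes_zero = rr$summary$m["lo"] > 0 | rr$summary$m["hi"] < 0,
        contrast_z = rr$contrast$z, contrast_p = rr$contrast$p_value)
    }
  }
  results <- dplyr::bind_rows(rows)
  aggregate <- results |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(
      w3_bias = mean(.data$w3_bias), w3_rmse = mean(.data$w3_rmse),
      w3_coverage = mean(.data$w3_coverage),
      frac_m_excludes_zero = mean(.data$m_excludes_zero),
      frac_contrast_sig = mean(.data$contrast_p < 0.05),
      .groups = "drop")
  structure(list(scenario = paste(scenarios, collapse = ", "),
                 n_replicates = n_replicates, results = results,
                 aggregate = aggregate, seed = seed),
            class = "simulation_report")
}

#' Ratio of audio-visual variable error to the ideal-integrator prediction
#'
#' For every participant-session with all three trial types, the ratio of the
#' audio-visual mean variable error to [optimal_variance()] of the two
#' single-cue mean variable errors. A ratio of 1 is perfect integration;
#' ratios above 1 quantify how far performance falls short of the ideal
#' integrator. The constant-error correction makes the ratio invariant to
#' additive log-scale bias.
#'
#' @param trials Trial table with responses.
#' @return Tibble with `participant_id`, `session`, `av_ve`, `optimal_ve`,
#'   `ratio`. Incomplete cells are skipped with a message.
#' @export
optimality_gap <- function(trials) {
  summ <- summarize_errors(trials)
  wide <- tidyr::pivot_wider(
    summ[, c("participant_id", "session", "trial_type", "mean_ve")],
    names_from = "trial_type", values_from = "mean_ve")
  needed <- c("audio", "visual", "audiovisual")
  missing_col <- setdiff(needed, names(wide))
  if (length(missing_col) > 0) {
    stop("no trials of type: ", paste(missing_col, collapse = ", "),
         call. = FALSE)
  }
  bad <- !stats::complete.cases(wide[, needed])
  if (any(bad)) {
    message(sum(bad), " participant-session(s) missing a trial type skipped")
    wide <- wide[!bad, ]
  }
  opt <- optimal_variance(wide$audio, wide$visual)
  tibble::tibble(participant_id = wide$participant_id,
                 session = wide$session, av_ve = wide$audiovisual,
                 optimal_ve = opt, ratio = wide$audiovisual / opt)
}
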