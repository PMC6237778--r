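# Log-scale constant/variable error decomposition, best-single-cue pairing,
# sign-rank tests, bootstrap effect sizes, the ideal-integrator benchmark and
# the visual-reliance measure.

#' Constant error of a cell
#'
#' The bias component of performance: the mean signed log error,
#' `mean(log(response) - log(target))`, computed separately for each
#' participant x session x trial-type cell.
#'
#' @param target_m,response_m Paired target and response distances in metres
#'   (non-empty, positive).
#' @return Constant error in log units.
#' @examples
#' constant_error(c(10, 20), c(10, 20) * exp(0.1)) # 0.1
#' @export
constant_error <- function(target_m, response_m) {
  cf_assert(length(target_m) >= 1 && length(target_m) == length(response_m),
            "`target_m` and `response_m` must be non-empty and equal length")
  cf_assert(all(target_m > 0) && all(response_m > 0),
            "distances must be positive")
  mean(log(response_m) - log(target_m))
}

#' Per-trial variable error
#'
#' The precision component: for each trial, the squared log error remaining
#' after the cell's constant error is removed,
#' `(log(response) - log(target) - ce)^2`.
#'
#' @inheritParams constant_error
#' @param ce The cell's constant error (a single number computed from the
#'   same trials with [constant_error()]).
#' @return Vector of squared log units, one per trial.
#' @examples
#' variable_error(c(10, 10), c(10 * exp(0.2), 10), ce = 0.1) # 0.01 0.01
#' @export
variable_error <- function(target_m, response_m, ce) {
  cf_assert(is.numeric(ce) && length(ce) == 1,
            "`ce` must be a single number computed from the same cell")
  cf_assert(length(target_m) == length(response_m),
            "`target_m` and `response_m` must be equal length")
  (log(response_m) - log(target_m) - ce)^2
}

#' Express a variable error as a response spread
#'
#' A variable error `ve` (squared log units) corresponds to a response SD of
#' `sqrt(ve)` log units, i.e. a multiplicative spread of `exp(sqrt(ve))`.
#' `ve_to_sd_fraction()` returns that spread as a fraction of the target
#' distance; `ve_to_sd_meters()` converts it to metres at a given distance.
#'
#' @param ve Variable error in squared log units.
#' @param distance_m Distance at which to express the spread, metres.
#' @return Fraction of the target distance, or metres.
#' @examples
#' ve_to_sd_fraction(0.01)    # ~0.105: SD is 10.5% of the distance
#' ve_to_sd_meters(0.01, 35)  # ~3.7 m
#' @export
ve_to_sd_fraction <- function(ve) {
  cf_assert(all(ve >= 0), "`ve` must be >= 0")
  exp(sqrt(ve)) - 1
}

#' @rdname ve_to_sd_fraction
#' @export
ve_to_sd_meters <- function(ve, distance_m) distance_m * ve_to_sd_fraction(ve)

# Continuous-response main trials that enter the statistics: Sessions 3+,
# main phase, no forced choice. Warm-up, preview and AFC trials are excluded;
# Sessions 1-2 serve only training and audio-SD calibration.
analysis_trials <- function(trials) {
  cf_assert(all(c("participant_id", "session", "phase", "trial_type",
                  "target_m", "response_m") %in% names(trials)),
            "`trials` is missing required columns")
  keep <- trials$phase == "main" & trials$session >= 3 &
    (is.na(trials$n_afc) | trials$n_afc == 0) &
    trials$trial_type %in% c("audio", "visual", "audiovisual")
  trials[keep, ]
}

# Append per-trial log error, cell constant error and variable error.
# `correct_bias = FALSE` gives the total-error variant (no bias removal).
trial_errors <- function(trials, correct_bias = TRUE) {
  at <- analysis_trials(trials)
  le <- log(at$response_m) - log(at$target_m)
  if (correct_bias) {
    key <- interaction(at$participant_id, at$session, at$trial_type,
                       drop = TRUE)
    ce <- stats::ave(le, key)
  } else {
    ce <- 0
  }
  at$log_error <- le
  at$ce <- ce
  at$ve <- (le - ce)^2
  at
}

#' Summarize errors per participant x session x trial type
#'
#' Computes the constant error and mean variable error for every cell of the
#' design (for the full 12-participant, 3-session, 3-trial-type layout that
#' is 108 cells). Only continuous-response main trials of Sessions 3+ enter;
#' cells with fewer than 2 trials are dropped with a warning.
#'
#' @param trials Trial table with responses (see [simulate_experiment()] /
#'   [read_trials()]).
#' @return Tibble with columns `participant_id`, `session`, `trial_type`,
#'   `n_trials`, `constant_error`, `mean_ve`.
#' @export
summarize_errors <- function(trials) {
  te <- trial_errors(trials)
  out <- te |>
    dplyr::group_by(.data$participant_id, .data$session, .data$trial_type) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     constant_error = mean(.data$log_error),
                     mean_ve = mean(.data$ve), .groups = "drop")
  small <- out$n_trials < 2
  if (any(small)) {
    warning(sum(small), " cell(s) with < 2 trials excluded", call. = FALSE)
    out <- out[!small, ]
  }
  out
}

#' Best single cue for a participant-session
#'
#' The unimodal condition (audio-only or visual-only) with the lower mean
#' variable error, averaged over all targets in the cell. Ties go to audio
#' (with a message).
#'
#' @param summaries Output of [summarize_errors()].
#' @param participant,session Cell to look up.
#' @return `"audio"` or `"visual"`.
#' @export
best_single_cue <- function(summaries, participant, session) {
  cell <- summaries[summaries$participant_id == participant &
                      summaries$session == session &
                      summaries$trial_type %in% c("audio", "visual"), ]
  cf_assert(nrow(cell) == 2,
            paste0("both single-cue summaries needed for ", participant,
                   ", session ", session))
  a <- cell$mean_ve[cell$trial_type == "audio"]
  v <- cell$mean_ve[cell$trial_type == "visual"]
  if (a == v) {
    message("single-cue tie for ", participant, " session ", session,
            "; choosing audio")
    return("audio")
  }
  if (a < v) "audio" else "visual"
}

# Best single cue for every participant-session at once.
best_single_table <- function(summaries) {
  singles <- summaries[summaries$trial_type %in% c("audio", "visual"), ]
  wide <- tidyr::pivot_wider(
    singles[, c("participant_id", "session", "trial_type", "mean_ve")],
    names_from = "trial_type", values_from = "mean_ve")
  cf_assert(!any(is.na(wide$audio)) && !any(is.na(wide$visual)),
            "a participant-session is missing a single-cue modality")
  ties <- wide$audio == wide$visual
  if (any(ties)) {
    message(sum(ties), " single-cue tie(s); choosing audio")
  }
  wide$best_type <- ifelse(wide$audio <= wide$visual, "audio", "visual")
  wide
}

#' Pair audio-visual trials with their best-single-cue reference
#'
#' For each audio-visual main trial, the matched pair is the variable error of
#' the best single cue's trial from the same triplet (same target, same
#' participant, same session). The best single cue is fixed per
#' participant-session from the mean single-cue variable errors. Broken
#' triplets (missing counterpart) are skipped with a warning.
#'
#' @param trials Trial table with responses.
#' @param correct_bias Remove each cell's constant error first (default);
#'   `FALSE` gives the total-error variant.
#' @return Pairs tibble with columns `participant_id`, `session`,
#'   `triplet_id`, `target_m`, `av_ve`, `ref_ve`, `ref_type`, and attribute
#'   `label = "best_single_vs_av"`. Sign-rank differences are taken as
#'   `ref_ve - av_ve`, so a positive statistic means the audio-visual trials
#'   were more precise.
#' @export
pair_av_vs_best <- function(trials, correct_bias = TRUE) {
  te <- trial_errors(trials, correct_bias = correct_bias)
  summ <- te |>
    dplyr::group_by(.data$participant_id, .data$session, .data$trial_type) |>
    dplyr::summarise(mean_ve = mean(.data$ve), .groups = "drop")
  best <- best_single_table(summ)[, c("participant_id", "session",
                                      "best_type")]

  av <- te[te$trial_type == "audiovisual" & !is.na(te$triplet_id), ]
  singles <- te[te$trial_type %in% c("audio", "visual") &
                  !is.na(te$triplet_id),
                c("participant_id", "session", "triplet_id", "trial_type",
                  "ve")]
  av <- dplyr::inner_join(av, best, by = c("participant_id", "session"))
  pairs <- dplyr::left_join(
    av, singles,
    by = c("participant_id", "session", "triplet_id",
           "best_type" = "trial_type"),
    suffix = c("", "_ref"))
  broken <- is.na(pairs$ve_ref)
  if (any(broken)) {
    warning(sum(broken), " audio-visual trial(s) without a matching ",
            "single-cue trial skipped", call. = FALSE)
    pairs <- pairs[!broken, ]
  }
  out <- tibble::tibble(
    participant_id = pairs$participant_id, session = pairs$session,
    triplet_id = pairs$triplet_id, target_m = pairs$target_m,
    av_ve = pairs$ve, ref_ve = pairs$ve_ref, ref_type = pairs$best_type)
  attr(out, "label") <- "best_single_vs_av"
  out
}

#' Pair audio-visual trials with the ideal-integrator prediction
#'
#' The reference for each audio-visual trial is the optimal combined variance
#' ([optimal_variance()]) of that participant-session's single-cue mean
#' variable errors — one pair per audio-visual main trial, as in the
#' best-single contrast. Sign-rank differences are `ref_ve - av_ve`, so a
#' negative statistic means performance fell short of the ideal integrator.
#'
#' @inheritParams pair_av_vs_best
#' @return Pairs tibble as in [pair_av_vs_best()] with
#'   `ref_type = "optimal"` and attribute `label = "av_vs_optimal"`.
#' @export
pair_av_vs_optimal <- function(trials, correct_bias = TRUE) {
  te <- trial_errors(trials, correct_bias = correct_bias)
  summ <- te |>
    dplyr::group_by(.data$participant_id, .data$session, .data$trial_type) |>
    dplyr::summarise(mean_ve = mean(.data$ve), .groups = "drop")
  wide <- best_single_table(summ)
  wide$opt_ve <- optimal_variance(wide$audio, wide$visual)

  av <- te[te$trial_type == "audiovisual" & !is.na(te$triplet_id), ]
  pairs <- dplyr::inner_join(
    av, wide[, c("participant_id", "session", "opt_ve")],
    by = c("participant_id", "session"))
  out <- tibble::tibble(
    participant_id = pairs$participant_id, session = pairs$session,
    triplet_id = pairs$triplet_id, target_m = pairs$target_m,
    av_ve = pairs$ve, ref_ve = pairs$opt_ve, ref_type = "optimal")
  attr(out, "label") <- "av_vs_optimal"
  out
}

#' Two-tailed Wilcoxon signed-rank test on matched pairs
#'
#' Tests whether the paired differences (`ref_ve - av_ve` for a pairs table,
#' or a numeric vector of differences) are symmetric about zero. Zero
#' differences are dropped. For `n <= exact_max_n` untied differences the
#' p-value comes from the exact null distribution of the signed-rank
#' statistic; otherwise from the normal approximation with the tie
#' correction. The z statistic is always reported (positive z: `ref` larger,
#' i.e. the audio-visual trials more precise).
#'
#' @param pairs Pairs tibble from [pair_av_vs_best()] /
#'   [pair_av_vs_optimal()], or a numeric vector of differences.
#' @param exact_max_n Largest n for which the exact distribution is used
#'   (default 25).
#' @return A `cf_signrank` list: `statistic` (W+, sum of positive ranks),
#'   `z`, `p_value`, `n` (non-zero pairs), `method`.
#' @examples
#' signrank_test(c(1, 2, 3))$p_value # exact: 0.25
#' @export
signrank_test <- function(pairs, exact_max_n = 25) {
  d <- if (is.data.frame(pairs)) pairs$ref_ve - pairs$av_ve else pairs
  cf_assert(is.numeric(d) && length(d) >= 1, "need at least one pair")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero", call. = FALSE)
    return(structure(list(statistic = 0, z = 0, p_value = 1, n = 0,
                          method = "degenerate"), class = "cf_signrank"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tie_counts <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_counts^3 - tie_counts) / 48
  # continuity-corrected normal deviate (correction vanishes at w = mu)
  z <- if (sig2 > 0) (w - mu - 0.5 * sign(w - mu)) / sqrt(sig2) else 0

  has_ties <- any(tie_counts > 1)
  if (n <= exact_max_n && !has_ties) {
    p <- 2 * min(stats::psignrank(w, n),
                 stats::psignrank(w - 1, n, lower.tail = FALSE))
    p <- min(1, p)
    method <- "exact"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  structure(list(statistic = w, z = z, p_value = p, n = n, method = method),
            class = "cf_signrank")
}

#' @export
print.cf_signrank <- function(x, ...) {
  cat(sprintf("Sign-rank test (%s): z = %.3f, p = %.4g, n = %d\n",
              x$method, x$z, x$p_value, x$n))
  invisible(x)
}

#' Variable-error change effect size with bootstrap CI
#'
#' The effect size reported alongside each contrast: the difference between
#' 100% and the ratio of the smaller mean variable error over the larger one,
#' `100 * (1 - min(m_ref, m_av) / max(m_ref, m_av))`. The 95% confidence
#' interval is a percentile bootstrap over the pairs (default 10,000
#' resamples).
#'
#' @param pairs Pairs tibble with `ref_ve` and `av_ve` columns.
#' @param n_boot Bootstrap resamples (>= 100; default 10,000).
#' @param seed Integer seed for the bootstrap.
#' @return List with `effect_pct`, `ci95` (length-2 vector), `n_boot`.
#' @export
ve_change <- function(pairs, n_boot = 10000, seed = 1) {
  cf_assert(is.data.frame(pairs) && nrow(pairs) >= 1, "need at least one pair")
  cf_assert(n_boot >= 100, "`n_boot` must be >= 100")
  eff <- function(ref, av) {
    m1 <- mean(ref); m2 <- mean(av)
    if (m1 == 0 || m2 == 0) {
      stop("a mean variable error is zero; the ratio effect is undefined",
           call. = FALSE)
    }
    100 * (1 - min(m1, m2) / max(m1, m2))
  }
  point <- eff(pairs$ref_ve, pairs$av_ve)
  n <- nrow(pairs)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    eff(pairs$ref_ve[idx], pairs$av_ve[idx])
  }, numeric(1)))
  list(effect_pct = point,
       ci95 = unname(stats::quantile(boots, c(0.025, 0.975))),
       n_boot = n_boot)
}

#' All paired contrasts, omnibus and per session
#'
#' Runs both paired contrasts (audio-visual vs best single cue; audio-visual
#' vs the ideal-integrator prediction) on the omnibus pair set and separately
#' per session, each with the two-tailed sign-rank test and the bootstrap
#' variable-error-change effect size.
#'
#' @param trials Trial table with responses.
#' @param n_boot Bootstrap resamples for the effect-size CI.
#' @param seed Integer seed for the bootstraps.
#' @return Tibble with one row per grouping x contrast: `grouping`,
#'   `contrast`, `n_pairs`, `z`, `p_value`, `mean_ref_ve`, `mean_av_ve`,
#'   `ve_change_pct`, `ci_low`, `ci_high`.
#' @export
cue_contrasts <- function(trials, n_boot = 10000, seed = 1) {
  all_pairs <- list(best_single_vs_av = pair_av_vs_best(trials),
                    av_vs_optimal = pair_av_vs_optimal(trials))
  sessions <- sort(unique(all_pairs[[1]]$session))
  groupings <- c(list(omnibus = sessions),
                 stats::setNames(as.list(sessions),
                                 paste0("session", sessions)))
  if (length(sessions) == 1) groupings <- groupings[1]

  rows <- list()
  for (gname in names(groupings)) {
    for (cname in names(all_pairs)) {
      p <- all_pairs[[cname]]
      p <- p[p$session %in% groupings[[gname]], ]
      if (nrow(p) == 0) next
      tst <- signrank_test(p)
      chg <- ve_change(p, n_boot = n_boot,
                       seed = substream_seed(seed, paste0(gname, cname)))
      rows[[length(rows) + 1]] <- tibble::tibble(
        grouping = gname, contrast = cname, n_pairs = nrow(p),
        z = tst$z, p_value = tst$p_value,
        mean_ref_ve = mean(p$ref_ve), mean_av_ve = mean(p$av_ve),
        ve_change_pct = chg$effect_pct,
        ci_low = chg$ci95[1], ci_high = chg$ci95[2])
    }
  }
  dplyr::bind_rows(rows)
}

#' Reliance on the visual cue
#'
#' How close responses fall to the centre of the visual cue on audio-visual
#' trials: the per participant-session mean of
#' `|log(response) - log(visual_center)|`. Lower values indicate stronger
#' reliance on vision; comparing the statistic across visual-reliability
#' conditions (e.g. with [signrank_test()]) probes cue re-weighting without
#' any model fitting.
#'
#' @param trials Trial table with responses.
#' @return Tibble with `participant_id`, `session`, `visual_sd_log`,
#'   `n_trials`, `reliance` (log units).
#' @export
visual_reliance <- function(trials) {
  at <- analysis_trials(trials)
  av <- at[at$trial_type == "audiovisual", ]
  cf_assert(nrow(av) >= 1, "no audio-visual main trials")
  av |>
    dplyr::group_by(.data$participant_id, .data$session) |>
    dplyr::summarise(
      visual_sd_log = mean(.data$visual_sd_log),
      n_trials = dplyr::n(),
      reliance = mean(abs(log(.data$response_m) -
                            log(.data$visual_center_m))),
      .groups = "drop")
}

#' Robustness variants of the error analysis
#'
#' Two alternative inputs to the paired contrasts: `"total_error"` skips the
#' constant-error correction (per-trial squared log error, bias included);
#' `"mean_ve"` aggregates the variable errors to one pair per participant
#' before testing (12 pairs for the full design).
#'
#' @param trials Trial table with responses.
#' @param mode `"total_error"` or `"mean_ve"`.
#' @param contrast Which reference to pair against.
#' @return List with `pairs` (the pairs entering the test) and `test`
#'   (the [signrank_test()] result).
#' @export
alternative_error_metrics <- function(trials,
                                      mode = c("total_error", "mean_ve"),
                                      contrast = c("best_single", "optimal")) {
  mode <- match.arg(mode)
  contrast <- match.arg(contrast)
  pair_fun <- if (contrast == "best_single") pair_av_vs_best else
    pair_av_vs_optimal
  pairs <- switch(mode,
    total_error = pair_fun(trials, correct_bias = FALSE),
    mean_ve = {
      p <- pair_fun(trials)
      p |>
        dplyr::group_by(.data$participant_id) |>
        dplyr::summarise(ref_ve = mean(.data$ref_ve),
                         av_ve = mean(.data$av_ve), .groups = "drop")
    })
  list(pairs = pairs, test = signrank_test(pairs))
}

#' Per-participant mean variable errors, best single cue vs audio-visual
#'
#' The scatter underlying the per-session comparison plots: one point per
#' participant-session, its best-single-cue mean variable error against its
#' audio-visual mean variable error. Points below the identity line indicate
#' a precision gain from having both cues.
#'
#' @param trials Trial table with responses.
#' @return Tibble with `participant_id`, `session`, `best_ve`, `av_ve`,
#'   `best_type`.
#' @export
ve_scatter <- function(trials) {
  summ <- summarize_errors(trials)
  best <- best_single_table(summ)
  av <- summ[summ$trial_type == "audiovisual",
             c("participant_id", "session", "mean_ve")]
  out <- dplyr::inner_join(best, av, by = c("participant_id", "session"))
  tibble::tibble(participant_id = out$participant_id, session = out$session,
                 best_ve = pmin(out$audio, out$visual), av_ve = out$mean_ve,
                 best_type = out$best_type)
}
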