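# Synthetic observers: generative models of participants that respond to
# session designs, producing trial tables with the statistical structure the
# analysis assumes.

#' Ideal (precision-weighted) weight on the visual cue
#'
#' With two independent Gaussian estimates, the minimum-variance combination
#' weights each by its precision (1/variance); the weight on vision is
#' `sigma_audio_sq / (sigma_audio_sq + sigma_visual_sq)`.
#'
#' @param sigma_audio_sq,sigma_visual_sq Cue variances (> 0), in squared log
#'   units. Vectorized.
#' @return Weight on the visual cue, in (0, 1).
#' @examples
#' ideal_weight(1, 1) # 0.5
#' ideal_weight(1, 3) # 0.25
#' @export
ideal_weight <- function(sigma_audio_sq, sigma_visual_sq) {
  cf_assert(all(sigma_audio_sq > 0) && all(sigma_visual_sq > 0),
            "variances must be > 0")
  sigma_audio_sq / (sigma_audio_sq + sigma_visual_sq)
}

#' Ideal-integrator response variance
#'
#' The variance of the optimal (precision-weighted) combination of two
#' independent Gaussian cues: the harmonic combination
#' `1 / (1/sigma_audio_sq + 1/sigma_visual_sq)`. Always at most the smaller
#' of the two single-cue variances; the benchmark that audio-visual variable
#' error is compared against.
#'
#' @inheritParams ideal_weight
#' @return Combined-estimate variance (same units as the inputs). Vectorized.
#' @examples
#' optimal_variance(1, 1) # 0.5
#' optimal_variance(1, 4) # 0.8
#' @export
optimal_variance <- function(sigma_audio_sq, sigma_visual_sq) {
  cf_assert(all(sigma_audio_sq > 0) && all(sigma_visual_sq > 0),
            "variances must be > 0")
  1 / (1 / sigma_audio_sq + 1 / sigma_visual_sq)
}

#' Define a simulated observer
#'
#' The generative model of one participant. On each trial the observer forms
#' a noisy audio percept of the target (Gaussian on the natural-log scale),
#' takes the visual percept to be the displayed distribution centre (external
#' noise only, plus optional internal visual noise), combines them according
#' to its weighting policy, adds a constant log-scale bias and Gaussian motor
#' noise, and responds on the bounded line (responses clamped to 10-35 m).
#'
#' Policies:
#' * `"ideal"` — precision-weighted average with weights from
#'   [ideal_weight()]; tracks each session's true visual spread when
#'   `reliability_known = TRUE`, otherwise keeps using
#'   `assumed_visual_sd_log` (a rote learner).
#' * `"fixed"` — constant weight `w_visual` on vision.
#' * `"switch"` — uses exactly one cue per trial, vision with probability
#'   `p_visual` (the "subjective alternation" null).
#' * `"best_single"` — uses only whichever cue has the lower true variance
#'   that trial (no integration benefit; the type-I-error null).
#' * `"audio_only"`, `"visual_only"` — single-cue responders.
#' * `"none"` — ignores all cues, responding uniformly on the log response
#'   line (models the untrained control at its least informed).
#'
#' @param sigma_audio_log SD of internal audio noise, log units (> 0).
#' @param weighting_policy One of the policies above.
#' @param w_visual Fixed weight on vision for `"fixed"` (in \[0, 1\]).
#' @param p_visual Per-trial probability of using vision for `"switch"`.
#' @param bias_log Additive constant error on the log scale.
#' @param motor_sd_log SD of extra response noise, log units (>= 0).
#' @param sigma_visual_internal_log SD of internal visual noise (default 0:
#'   the visual cue's noise is external, carried by the displayed spread).
#' @param reliability_known Should ideal weights track the session's true
#'   visual SD?
#' @param assumed_visual_sd_log Visual SD assumed when
#'   `reliability_known = FALSE`.
#' @return An `observer_params` object.
#' @examples
#' observer_params(0.12, "ideal")
#' @export
observer_params <- function(sigma_audio_log = 0.12,
                            weighting_policy = c("ideal", "fixed", "switch",
                                                 "best_single", "audio_only",
                                                 "visual_only", "none"),
                            w_visual = NULL, p_visual = NULL,
                            bias_log = 0, motor_sd_log = 0,
                            sigma_visual_internal_log = 0,
                            reliability_known = TRUE,
                            assumed_visual_sd_log = NULL) {
  weighting_policy <- match.arg(weighting_policy)
  cf_assert(is.numeric(sigma_audio_log) && sigma_audio_log > 0,
            "`sigma_audio_log` must be > 0")
  cf_assert(motor_sd_log >= 0, "`motor_sd_log` must be >= 0")
  if (weighting_policy == "fixed") {
    cf_assert(!is.null(w_visual) && w_visual >= 0 && w_visual <= 1,
              "`fixed` policy needs `w_visual` in [0, 1]")
  }
  if (weighting_policy == "switch") {
    cf_assert(!is.null(p_visual) && p_visual >= 0 && p_visual <= 1,
              "`switch` policy needs `p_visual` in [0, 1]")
  }
  if (!reliability_known) {
    cf_assert(is.numeric(assumed_visual_sd_log) && assumed_visual_sd_log > 0,
              "`reliability_known = FALSE` needs `assumed_visual_sd_log` > 0")
  }
  structure(list(sigma_audio_log = sigma_audio_log,
                 weighting_policy = weighting_policy,
                 w_visual = w_visual, p_visual = p_visual,
                 bias_log = bias_log, motor_sd_log = motor_sd_log,
                 sigma_visual_internal_log = sigma_visual_internal_log,
                 reliability_known = reliability_known,
                 assumed_visual_sd_log = assumed_visual_sd_log),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf("<observer_params> policy %s, sigma_audio %g, bias %g, motor %g\n",
              x$weighting_policy, x$sigma_audio_log, x$bias_log,
              x$motor_sd_log))
  invisible(x)
}

# Vectorized response generation for one observer over a block of trials.
# Assumes the RNG state is already set by the caller.
simulate_block <- function(obs, trials) {
  n <- nrow(trials)
  lt <- log(trials$target_m)
  a_hat <- lt + stats::rnorm(n, 0, obs$sigma_audio_log)
  lc <- log(trials$visual_center_m)
  v_hat <- lc + if (obs$sigma_visual_internal_log > 0) {
    stats::rnorm(n, 0, obs$sigma_visual_internal_log)
  } else 0

  est <- numeric(n)
  is_afc <- trials$n_afc > 0
  type <- trials$trial_type

  # Forced-choice trials: pick the alternative nearest the audio percept.
  if (any(is_afc)) {
    est[is_afc] <- vapply(which(is_afc), function(i) {
      alts <- log(log_spaced_targets(trials$n_afc[i]))
      alts[which.min(abs(alts - a_hat[i]))]
    }, numeric(1))
  }

  cont <- !is_afc
  au <- cont & type == "audio"
  vi <- cont & type == "visual"
  av <- cont & type == "audiovisual"
  if (any((vi | av) & is.na(lc))) {
    stop("policy requires a visual cue but some trials lack visual fields",
         call. = FALSE)
  }
  est[au] <- a_hat[au]
  est[vi] <- v_hat[vi] # ideal single-cue strategy: respond at the densest point

  if (any(av)) {
    pol <- obs$weighting_policy
    sa2 <- obs$sigma_audio_log^2
    sv2 <- (if (obs$reliability_known) trials$visual_sd_log[av] else
              obs$assumed_visual_sd_log)^2 + obs$sigma_visual_internal_log^2
    w <- switch(pol,
      ideal = ideal_weight(sa2, sv2),
      fixed = obs$w_visual,
      switch = as.numeric(stats::runif(sum(av)) < obs$p_visual),
      best_single = as.numeric(sv2 < sa2),
      audio_only = 0,
      visual_only = 1,
      none = NA_real_)
    est[av] <- if (pol == "none") NA_real_ else
      w * v_hat[av] + (1 - w) * a_hat[av]
  }

  if (obs$weighting_policy == "none") {
    est[cont] <- stats::runif(sum(cont), log(.LINE_LO), log(.LINE_HI))
  }

  resp <- est + obs$bias_log +
    if (obs$motor_sd_log > 0) stats::rnorm(n, 0, obs$motor_sd_log) else 0
  clamp(exp(resp))
}

resolve_observer <- function(cohort, pid, session) {
  o <- cohort[[pid]]
  if (is.null(o)) stop("no observer for participant ", pid, call. = FALSE)
  if (inherits(o, "observer_params")) return(o)
  out <- o[[as.character(session)]] %||% o$default
  if (is.null(out)) {
    stop("no observer for participant ", pid, ", session ", session,
         call. = FALSE)
  }
  out
}

#' Simulate a cohort responding to trial designs
#'
#' @param cohort A list of [observer_params()], one per participant (recycled
#'   if length 1, matched to participants by name if named, by order
#'   otherwise). An element may itself be a list keyed by session number
#'   (with optional `default`) to let policies change across sessions.
#' @param designs Trial design tibble from [make_cohort_designs()] /
#'   [make_session_design()].
#' @param seed Integer seed; the full table is reproducible given it.
#' @return The design tibble with a `response_m` column (metres, clamped to
#'   the response line). The number of responses clamped at the line limits is
#'   reported in the `clamped` attribute (clamping distorts tails).
#' @examples
#' d <- make_session_design(3, "P01", session_params(), seed = 1)
#' t <- simulate_experiment(list(observer_params()), d, seed = 1)
#' head(t$response_m)
#' @export
simulate_experiment <- function(cohort, designs, seed = 1) {
  cf_assert(is.list(cohort) && length(cohort) >= 1,
            "`cohort` must be a non-empty list")
  pids <- unique(designs$participant_id)
  if (inherits(cohort, "observer_params")) cohort <- list(cohort)
  if (is.null(names(cohort))) {
    cf_assert(length(cohort) %in% c(1L, length(pids)),
              "`cohort` must have one observer, or one per participant")
    cohort <- stats::setNames(rep_len(cohort, length(pids)), pids)
  } else {
    missing <- setdiff(pids, names(cohort))
    cf_assert(length(missing) == 0,
              paste0("no observer for participant(s): ",
                     paste(missing, collapse = ", ")))
  }

  designs <- designs[order(designs$participant_id, designs$session), ]
  key <- paste(designs$participant_id, designs$session)
  groups <- split(seq_len(nrow(designs)), factor(key, levels = unique(key)))
  responses <- numeric(nrow(designs))
  for (g in groups) {
    pid <- designs$participant_id[g[1]]
    sess <- designs$session[g[1]]
    obs <- resolve_observer(cohort, pid, sess)
    gseed <- substream_seed(seed, paste0("sim-", pid, "-s", sess))
    responses[g] <- with_seed(gseed, simulate_block(obs, designs[g, ]))
  }
  out <- designs
  out$response_m <- responses
  attr(out, "clamped") <- sum(responses <= .LINE_LO | responses >= .LINE_HI)
  out
}

#' Variable error of the center-of-line responder
#'
#' The baseline used to interpret the untrained control: a responder who
#' ignores all cues and always answers the log-midpoint of the response line,
#' `sqrt(10 * 35)` m. Returns the mean variable error (squared log units) of
#' that strategy over the given targets, after removing its constant error.
#'
#' @param targets Target distances in metres (non-empty, positive).
#' @return Mean variable error in squared log units.
#' @examples
#' untrained_baseline_ve(c(10, 35)) # (log(sqrt(3.5)))^2
#' @export
untrained_baseline_ve <- function(targets) {
  cf_assert(is.numeric(targets) && length(targets) >= 1,
            "`targets` must be a non-empty numeric vector")
  cf_assert(all(is.finite(targets)) && all(targets > 0),
            "`targets` must be positive and finite")
  resp <- log(sqrt(.LINE_LO * .LINE_HI))
  err <- resp - log(targets)
  mean((err - mean(err))^2)
}
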