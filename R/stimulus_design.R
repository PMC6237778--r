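# Stimulus and trial-design generation: echo-delay click pairs, mirrored
# log-normal bubble fields, log-spaced target grids, matched triplet blocks,
# and full session schedules.

#' Echo delay for a target distance
#'
#' The novel audio cue signals distance through the time between an emitted
#' click and its returning copy: the sound travels to the target and back at
#' the speed of sound in air (approximated at 350 m/s), so the delay is
#' `2 * distance / 350` seconds.
#'
#' @param distance_m Target distance(s) in metres; must be positive and finite.
#' @return Delay(s) in seconds.
#' @examples
#' echo_delay(10)   # ~0.057 s
#' echo_delay(17.5) # 0.1 s
#' @export
echo_delay <- function(distance_m) {
  cf_assert(is.numeric(distance_m) && length(distance_m) >= 1,
            "`distance_m` must be numeric")
  cf_assert(all(is.finite(distance_m)) && all(distance_m > 0),
            "`distance_m` must be positive and finite")
  2 * distance_m / .SPEED_OF_SOUND
}

# 5 ms click: unit-amplitude sine at `frequency`, first half-period scaled by
# 0.6, then an exponential decay mask whose exponent ramps linearly from 0 at
# 1.5 periods to -10 at 5 ms.
make_click <- function(frequency, sample_rate) {
  n <- round(0.005 * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  w <- sin(2 * pi * frequency * t)
  w[t < 1 / (2 * frequency)] <- 0.6 * w[t < 1 / (2 * frequency)]
  t0 <- 1.5 / frequency
  decay <- t >= t0
  w[decay] <- w[decay] * exp(-10 * (t[decay] - t0) / (0.005 - t0))
  w
}

#' Synthesize an echo-delay click pair
#'
#' Builds the emission click (5 ms amplitude-shaped sine) and adds an exact
#' copy delayed by [echo_delay()] of the target distance, embedded in at least
#' one second of silence with the emission starting at 50 ms. For the
#' experiment's distances (>= 10 m) the two clicks never overlap.
#'
#' @param distance_m Target distance in metres (> 0).
#' @param frequency Click carrier frequency in Hz; 4000 and 2000 are the
#'   trained emissions, other values are allowed with a warning.
#' @param sample_rate Samples per second (default 96000); must be at least
#'   twice `frequency`.
#' @return A `click_pair` object: list with `samples` (amplitudes in
#'   \[-1, 1\]), `sample_rate`, `frequency`, `delay_s`, `distance_m`, and the
#'   0-based sample offsets `emission_onset` and `echo_onset`.
#' @examples
#' cp <- synthesize_click_pair(10)
#' cp$echo_onset - cp$emission_onset # delay in samples
#' @export
synthesize_click_pair <- function(distance_m, frequency = 4000,
                                  sample_rate = 96000) {
  cf_assert(is.numeric(distance_m) && length(distance_m) == 1 &&
              is.finite(distance_m) && distance_m > 0,
            "`distance_m` must be a single positive finite number")
  if (!frequency %in% c(2000, 4000)) {
    warning("frequency ", frequency, " Hz is outside the trained emissions ",
            "(2000/4000 Hz)", call. = FALSE)
  }
  cf_assert(sample_rate >= 2 * frequency,
            "`sample_rate` must be at least twice `frequency`")

  click <- make_click(frequency, sample_rate)
  delay_s <- echo_delay(distance_m)
  lead <- round(0.050 * sample_rate)
  delay_samples <- round(delay_s * sample_rate)
  needed <- lead + delay_samples + length(click)
  n_total <- max(sample_rate, needed) # 1 s buffer, extended for long delays
  if (needed > sample_rate) {
    message("echo extends past the 1 s buffer; extended to ",
            n_total, " samples")
  }

  samples <- numeric(n_total)
  idx <- lead + seq_along(click)
  samples[idx] <- samples[idx] + click
  idx <- lead + delay_samples + seq_along(click)
  samples[idx] <- samples[idx] + click
  peak <- max(abs(samples))
  if (peak > 1) { # only possible when the clicks overlap (< ~0.9 m)
    samples <- samples / peak
    warning("overlapping clicks rescaled to unit peak", call. = FALSE)
  }

  structure(
    list(samples = samples, sample_rate = sample_rate, frequency = frequency,
         delay_s = delay_s, distance_m = distance_m,
         emission_onset = lead, echo_onset = lead + delay_samples),
    class = "click_pair"
  )
}

#' @export
print.click_pair <- function(x, ...) {
  cat(sprintf(
    "<click_pair> %g m, %g Hz @ %g Hz: delay %.4f s (%d samples), %d samples total\n",
    x$distance_m, x$frequency, x$sample_rate, x$delay_s,
    x$echo_onset - x$emission_onset, length(x$samples)))
  invisible(x)
}

#' Targets spaced evenly on a log scale
#'
#' @param n Number of targets (>= 2).
#' @param lo,hi Range endpoints in metres, `0 < lo < hi`; defaults are the
#'   response line limits 10 and 35 m.
#' @return Numeric vector of `n` distances whose logs form an arithmetic
#'   progression from `log(lo)` to `log(hi)`.
#' @examples
#' log_spaced_targets(3) # 10, sqrt(350), 35
#' @export
log_spaced_targets <- function(n, lo = .LINE_LO, hi = .LINE_HI) {
  cf_assert(is.numeric(n) && length(n) == 1 && n >= 2 && n == round(n),
            "`n` must be an integer >= 2")
  cf_assert(is.numeric(lo) && is.numeric(hi) && lo > 0 && hi > lo,
            "need 0 < lo < hi")
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Generate a mirrored log-normal bubble field
#'
#' The visual cue is a 3D cloud of translucent spheres ("bubbles") whose
#' outline, seen from the side, is a violin: the half-width of the cloud at
#' along-line position `x` is proportional to the log-normal density at `x`.
#' The target is drawn from the displayed distribution, so the widest
#' cross-section (the density mode) is the single best place to respond when
#' only the visual cue is available.
#'
#' Bubbles are placed deterministically under `seed` by first lining the
#' outline (starting at the widest point) and then rejection-filling the
#' interior so that no two bubbles touch.
#'
#' @param center_m Median of the displayed distribution, in metres, within the
#'   response line \[10, 35\].
#' @param sd_log Standard deviation of the distribution in natural-log
#'   distance units (> 0).
#' @param n_bubbles Number of bubbles (default 256).
#' @param radius_m Bubble radius in metres (default 0.15).
#' @param seed Integer seed; the field is deterministic given all arguments.
#' @param max_halfwidth_m Lateral/vertical half-width of the violin at its
#'   widest point, metres.
#' @param max_attempts Rejection-sampling budget for the interior fill.
#' @return A `bubble_field`: tibble of bubble centres with columns `along_m`
#'   (position on the response line), `lateral_m`, `vertical_m`, plus
#'   attributes `center_m`, `sd_log`, `radius_m`.
#' @examples
#' bf <- make_bubble_field(20, 0.1, n_bubbles = 64, seed = 7)
#' nrow(bf)
#' @export
make_bubble_field <- function(center_m, sd_log, n_bubbles = 256,
                              radius_m = 0.15, seed = 1,
                              max_halfwidth_m = 2, max_attempts = 1e5) {
  cf_assert(is.numeric(center_m) && length(center_m) == 1 &&
              center_m >= .LINE_LO && center_m <= .LINE_HI,
            "`center_m` must lie on the response line [10, 35]")
  cf_assert(is.numeric(sd_log) && sd_log > 0, "`sd_log` must be > 0")
  cf_assert(n_bubbles >= 1, "`n_bubbles` must be >= 1")

  mu <- log(center_m)
  mode_x <- exp(mu - sd_log^2)
  dmax <- stats::dlnorm(mode_x, mu, sd_log)
  halfwidth <- function(x) max_halfwidth_m * stats::dlnorm(x, mu, sd_log) / dmax

  pts <- matrix(numeric(0), ncol = 3)
  colnames(pts) <- c("along_m", "lateral_m", "vertical_m")
  add <- function(p) rbind(pts, matrix(p, ncol = 3))
  min_sep <- 2 * radius_m

  if (n_bubbles == 1) {
    pts <- add(c(mode_x, 0, 0))
  } else {
    pts <- with_seed(seed, {
      clear_of_all <- function(p) {
        nrow(pts) == 0 ||
          min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 +
                (pts[, 3] - p[3])^2) > min_sep^2
      }
      # Edge ring: trace the outline outward from the widest point on both
      # sides, top and bottom, stepping so consecutive bubbles just clear;
      # mirrored placements are dropped where the tails pinch together.
      pts <- add(c(mode_x, halfwidth(mode_x), 0))
      pts <- add(c(mode_x, -halfwidth(mode_x), 0))
      for (dir in c(-1, 1)) {
        x <- mode_x
        repeat {
          hw <- halfwidth(x)
          slope <- (halfwidth(x + dir * 1e-4) - hw) / 1e-4
          dx <- 1.05 * min_sep / sqrt(1 + slope^2)
          x <- x + dir * dx
          if (x < .LINE_LO || x > .LINE_HI || halfwidth(x) < radius_m / 2 ||
              nrow(pts) >= n_bubbles) {
            break
          }
          for (side in c(1, -1)) {
            p <- c(x, side * halfwidth(x), 0)
            if (nrow(pts) < n_bubbles && clear_of_all(p)) pts <- add(p)
          }
        }
      }
      # Interior fill: along-line position from the displayed distribution
      # (truncated to the line), cross-section position uniform in the disc of
      # radius halfwidth(x); reject anything touching an earlier bubble.
      attempts <- 0
      while (nrow(pts) < n_bubbles && attempts < max_attempts) {
        attempts <- attempts + 1
        x <- stats::rlnorm(1, mu, sd_log)
        if (x < .LINE_LO || x > .LINE_HI) next
        hw <- halfwidth(x)
        u <- stats::runif(1, -hw, hw)
        v <- stats::runif(1, -hw, hw)
        if (u^2 + v^2 > hw^2) next
        d2 <- (pts[, 1] - x)^2 + (pts[, 2] - u)^2 + (pts[, 3] - v)^2
        if (min(d2) > min_sep^2) pts <- add(c(x, u, v))
      }
      if (nrow(pts) < n_bubbles) {
        stop("bubble packing failed: placed ", nrow(pts), " of ", n_bubbles,
             " bubbles within ", max_attempts, " attempts", call. = FALSE)
      }
      pts
    })
  }

  out <- tibble::as_tibble(pts)
  attr(out, "center_m") <- center_m
  attr(out, "sd_log") <- sd_log
  attr(out, "radius_m") <- radius_m
  class(out) <- c("bubble_field", class(out))
  out
}

#' Generate a block of matched stimulus triplets
#'
#' Each triplet specifies one audio-visual trial from which a matching
#' audio-only and visual-only trial are derived. Visual-cue centres are spaced
#' evenly on a log scale over the response line; the true target is an actual
#' draw from the displayed distribution, `Normal(log(center), visual_sd_log^2)`
#' on the log scale. Draws falling off the response line are redrawn
#' (rejection), preserving the "actual draw" property; the redraw count is
#' recorded in the `redraws` attribute.
#'
#' The visual spread is calibrated to each participant's audio precision:
#' `visual_sd_log = sd_ratio * audio_sd_log` (the ratio applies to the SD by
#' default; set `ratio_applies_to = "variance"` to apply it to the variance).
#'
#' @param n_triplets Number of triplets (> 0).
#' @param audio_sd_log Participant's audio-only response SD in log units (> 0).
#' @param sd_ratio Visual/audio reliability ratio; 0.75 and 1.25 are the
#'   experiment's two levels (others allowed with a warning).
#' @param freq Audio carrier frequency in Hz for the block.
#' @param seed Integer seed (target draws are deterministic given it).
#' @param ratio_applies_to `"sd"` (default) or `"variance"`.
#' @return Tibble with columns `triplet_id`, `target_m`, `visual_center_m`,
#'   `visual_sd_log`, `audio_freq_hz`; attribute `redraws` counts rejected
#'   off-line target draws.
#' @examples
#' make_triplet_block(5, audio_sd_log = 0.12, seed = 1)
#' @export
make_triplet_block <- function(n_triplets, audio_sd_log, sd_ratio = 0.75,
                               freq = 4000, seed = 1,
                               ratio_applies_to = c("sd", "variance")) {
  cf_assert(is.numeric(n_triplets) && length(n_triplets) == 1 && n_triplets > 0,
            "`n_triplets` must be a positive count")
  cf_assert(is.numeric(audio_sd_log) && audio_sd_log > 0,
            "`audio_sd_log` must be > 0")
  ratio_applies_to <- match.arg(ratio_applies_to)
  if (!sd_ratio %in% c(0.75, 1.25)) {
    warning("sd_ratio ", sd_ratio, " is outside the experiment's levels ",
            "(0.75 / 1.25)", call. = FALSE)
  }
  sd_v <- switch(ratio_applies_to,
                 sd = sd_ratio * audio_sd_log,
                 variance = sqrt(sd_ratio) * audio_sd_log)

  centers <- if (n_triplets == 1) sqrt(.LINE_LO * .LINE_HI) else
    log_spaced_targets(n_triplets)
  lo <- log(.LINE_LO); hi <- log(.LINE_HI)
  drawn <- with_seed(seed, {
    redraws <- 0L
    lt <- stats::rnorm(n_triplets, log(centers), sd_v)
    bad <- which(lt < lo | lt > hi)
    while (length(bad) > 0) {
      redraws <- redraws + length(bad)
      lt[bad] <- stats::rnorm(length(bad), log(centers)[bad], sd_v)
      bad <- bad[lt[bad] < lo | lt[bad] > hi]
    }
    list(targets = exp(lt), redraws = redraws)
  })
  targets <- drawn$targets
  redraws <- drawn$redraws

  out <- tibble::tibble(
    triplet_id = seq_len(n_triplets),
    target_m = targets,
    visual_center_m = centers,
    visual_sd_log = sd_v,
    audio_freq_hz = freq
  )
  attr(out, "redraws") <- redraws
  out
}

# Expand a triplet block into the three trial rows it defines. Audio-only
# trials carry no visual fields; visual-only trials carry no audio frequency.
expand_triplets <- function(block, participant_id, session,
                            feedback = c(audio = TRUE, visual = TRUE,
                                         audiovisual = TRUE)) {
  types <- c("audio", "visual", "audiovisual")
  out <- tidyr::expand_grid(block, trial_type = types)
  out <- dplyr::mutate(
    out,
    participant_id = participant_id,
    session = as.integer(session),
    phase = "main",
    n_afc = 0L,
    feedback = unname(feedback[.data$trial_type]),
    visual_center_m = ifelse(.data$trial_type == "audio", NA_real_,
                             .data$visual_center_m),
    visual_sd_log = ifelse(.data$trial_type == "audio", NA_real_,
                           .data$visual_sd_log),
    audio_freq_hz = ifelse(.data$trial_type == "visual", NA_real_,
                           .data$audio_freq_hz)
  )
  dplyr::select(out, "participant_id", "session", "phase", "trial_type",
                "n_afc", "triplet_id", "target_m", "visual_center_m",
                "visual_sd_log", "audio_freq_hz", "feedback")
}

#' Session-level design parameters
#'
#' Bundles the counts and assignment rules that define the five-session
#' design: Session 1 trains the audio cue with forced-choice trials (50 2AFC,
#' 100 3AFC, 150 5AFC, all with feedback); Session 2 moves to 250 continuous
#' audio-only trials with feedback; Sessions 3-5 present matched triplets
#' (83/62/83 by default). Session 4 switches the audio frequency and removes
#' feedback from trials with the new sound; Session 5 changes the visual
#' reliability and removes feedback from the audio-visual trials.
#'
#' @param audio_sd_log Audio-only response SD (log units) used to calibrate
#'   the visual spread, nominally measured in Session 2.
#' @param freq_first Carrier frequency (Hz) in Sessions 1-3 and 5.
#' @param freq_new Carrier frequency introduced in Session 4.
#' @param sd_ratio_first Visual/audio SD ratio in Sessions 3-4 (0.75 or 1.25).
#' @param sd_ratio_s5 Ratio in Session 5; defaults to the other level.
#' @param afc_counts Named counts of 2/3/5-alternative trials in Session 1.
#' @param n_continuous_s2 Continuous audio trials in Session 2.
#' @param n_warmup Warm-up forced-choice trials opening Sessions 2-5.
#' @param n_preview Preview trials closing Sessions 2-4.
#' @param n_triplets Named triplet counts for Sessions 3-5.
#' @param ratio_applies_to Whether `sd_ratio` scales the SD or the variance.
#' @return A list of class `session_params`.
#' @export
session_params <- function(audio_sd_log = 0.12,
                           freq_first = 4000, freq_new = 2000,
                           sd_ratio_first = 0.75, sd_ratio_s5 = NULL,
                           afc_counts = c(`2` = 50, `3` = 100, `5` = 150),
                           n_continuous_s2 = 250, n_warmup = 40,
                           n_preview = 10,
                           n_triplets = c(`3` = 83, `4` = 62, `5` = 83),
                           ratio_applies_to = "sd") {
  if (is.null(sd_ratio_s5)) {
    sd_ratio_s5 <- if (sd_ratio_first == 0.75) 1.25 else 0.75
  }
  structure(list(audio_sd_log = audio_sd_log, freq_first = freq_first,
                 freq_new = freq_new, sd_ratio_first = sd_ratio_first,
                 sd_ratio_s5 = sd_ratio_s5, afc_counts = afc_counts,
                 n_continuous_s2 = n_continuous_s2, n_warmup = n_warmup,
                 n_preview = n_preview, n_triplets = n_triplets,
                 ratio_applies_to = ratio_applies_to),
            class = "session_params")
}

afc_trials <- function(participant_id, session, phase, counts, freq) {
  rows <- lapply(names(counts), function(k) {
    n_afc <- as.integer(k)
    alts <- log_spaced_targets(n_afc)
    n <- counts[[k]]
    # correct targets as evenly distributed over the alternatives as possible
    targets <- alts[rep_len(seq_len(n_afc), n)]
    tibble::tibble(
      participant_id = participant_id, session = as.integer(session),
      phase = phase, trial_type = "audio", n_afc = n_afc,
      triplet_id = NA_integer_, target_m = targets,
      visual_center_m = NA_real_, visual_sd_log = NA_real_,
      audio_freq_hz = freq, feedback = TRUE
    )
  })
  dplyr::bind_rows(rows)
}

#' Generate one participant-session trial schedule
#'
#' @param session_id Session number, 1-5.
#' @param participant_id Participant identifier.
#' @param params A [session_params()] object.
#' @param seed Integer seed; target draws and main-trial order are
#'   deterministic given it.
#' @return Tibble of trials, one row each, with columns `participant_id`,
#'   `session`, `phase` (`warmup`/`main`/`preview`), `trial_type`, `n_afc`
#'   (0 for continuous-response trials), `triplet_id`, `target_m`,
#'   `visual_center_m`, `visual_sd_log`, `audio_freq_hz`, `feedback`.
#' @examples
#' d <- make_session_design(3, "P01", session_params(), seed = 1)
#' table(d$phase, d$trial_type)
#' @export
make_session_design <- function(session_id, participant_id,
                                params = session_params(), seed = 1) {
  cf_assert(session_id %in% 1:5, "`session_id` must be in 1..5")
  cf_assert(inherits(params, "session_params"),
            "`params` must come from session_params()")
  sd_warm <- substream_seed(seed, paste0(participant_id, "-s", session_id, "-warm"))
  sd_main <- substream_seed(seed, paste0(participant_id, "-s", session_id, "-main"))

  warmup <- function() {
    n <- params$n_warmup
    counts <- round(n * params$afc_counts / sum(params$afc_counts))
    counts[length(counts)] <- n - sum(counts[-length(counts)])
    afc_trials(participant_id, session_id, "warmup", counts,
               params$freq_first)
  }

  if (session_id == 1) {
    return(afc_trials(participant_id, 1, "main", params$afc_counts,
                      params$freq_first))
  }

  if (session_id == 2) {
    main <- tibble::tibble(
      participant_id = participant_id, session = 2L, phase = "main",
      trial_type = "audio", n_afc = 0L, triplet_id = NA_integer_,
      target_m = with_seed(sd_main,
                           sample(log_spaced_targets(params$n_continuous_s2))),
      visual_center_m = NA_real_, visual_sd_log = NA_real_,
      audio_freq_hz = params$freq_first, feedback = TRUE
    )
    preview <- tibble::tibble( # introduces the visual cue of Session 3
      participant_id = participant_id, session = 2L, phase = "preview",
      trial_type = "visual", n_afc = 0L, triplet_id = NA_integer_,
      target_m = log_spaced_targets(params$n_preview),
      visual_center_m = log_spaced_targets(params$n_preview),
      visual_sd_log = params$sd_ratio_first * params$audio_sd_log,
      audio_freq_hz = NA_real_, feedback = TRUE
    )
    return(dplyr::bind_rows(warmup(), main, preview))
  }

  # Sessions 3-5: warm-up + matched triplets (+ preview for 3 and 4).
  freq <- if (session_id == 4) params$freq_new else params$freq_first
  ratio <- if (session_id == 5) params$sd_ratio_s5 else params$sd_ratio_first
  feedback <- switch(as.character(session_id),
    `3` = c(audio = TRUE, visual = TRUE, audiovisual = TRUE),
    # new-frequency trials (audio and audio-visual) get no feedback in S4
    `4` = c(audio = FALSE, visual = TRUE, audiovisual = FALSE),
    # bimodal trials get no feedback in S5, single-cue trials keep it
    `5` = c(audio = TRUE, visual = TRUE, audiovisual = FALSE))

  block <- make_triplet_block(
    params$n_triplets[[as.character(session_id)]], params$audio_sd_log,
    sd_ratio = ratio, freq = freq, seed = sd_main,
    ratio_applies_to = params$ratio_applies_to)
  main <- expand_triplets(block, participant_id, session_id, feedback)
  main <- with_seed(sd_main + 1L, main[sample(nrow(main)), ])

  preview <- NULL
  if (session_id %in% 3:4) {
    next_freq <- if (session_id == 3) params$freq_new else params$freq_first
    next_ratio <- if (session_id == 4) params$sd_ratio_s5 else ratio
    preview <- tibble::tibble(
      participant_id = participant_id, session = as.integer(session_id),
      phase = "preview",
      trial_type = if (session_id == 3) "audio" else "visual",
      n_afc = 0L, triplet_id = NA_integer_,
      target_m = log_spaced_targets(params$n_preview),
      visual_center_m = if (session_id == 3) NA_real_ else
        log_spaced_targets(params$n_preview),
      visual_sd_log = if (session_id == 3) NA_real_ else
        next_ratio * params$audio_sd_log,
      audio_freq_hz = if (session_id == 3) next_freq else NA_real_,
      feedback = FALSE
    )
  }
  dplyr::bind_rows(warmup(), main, preview)
}

#' Generate trial schedules for a whole cohort
#'
#' Applies the counterbalancing of the experiment: half of the participants
#' start with the 4000 Hz emission (switching to 2000 Hz in Session 4), half
#' the reverse; orthogonally, half see the more reliable visual cue
#' (SD ratio 0.75) in Sessions 3-4 and the less reliable one (1.25) in
#' Session 5, half the reverse.
#'
#' @param n_participants Cohort size (default 12).
#' @param sessions Which sessions to generate (default 1:5).
#' @param audio_sd_log Audio-only SD in log units; scalar or one per
#'   participant.
#' @param seed Integer run seed.
#' @param params Base [session_params()]; per-participant frequency and ratio
#'   assignments override its `freq_first`/`sd_ratio_first`.
#' @return Tibble of trials for all participants and sessions.
#' @examples
#' d <- make_cohort_designs(2, sessions = 3, seed = 1)
#' nrow(d)
#' @export
make_cohort_designs <- function(n_participants = 12, sessions = 1:5,
                                audio_sd_log = 0.12, seed = 1,
                                params = session_params()) {
  cf_assert(n_participants >= 1, "`n_participants` must be >= 1")
  sds <- rep_len(audio_sd_log, n_participants)
  pids <- sprintf("P%02d", seq_len(n_participants))
  freq_first <- ifelse(seq_len(n_participants) %% 2 == 1, 4000, 2000)
  ratio_first <- ifelse(((seq_len(n_participants) + 1) %/% 2) %% 2 == 1,
                        0.75, 1.25)
  out <- lapply(seq_len(n_participants), function(i) {
    p <- params
    p$audio_sd_log <- sds[i]
    p$freq_first <- freq_first[i]
    p$freq_new <- if (freq_first[i] == 4000) 2000 else 4000
    p$sd_ratio_first <- ratio_first[i]
    p$sd_ratio_s5 <- if (ratio_first[i] == 0.75) 1.25 else 0.75
    dplyr::bind_rows(lapply(sessions, function(s) {
      make_session_design(s, pids[i], p, seed = substream_seed(seed, pids[i]))
    }))
  })
  dplyr::bind_rows(out)
}
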