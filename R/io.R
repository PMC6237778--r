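# Trial-table reading/writing with validation, run configuration, and the
# end-to-end pipeline.

TRIAL_COLUMNS <- c("participant_id", "session", "phase", "trial_type",
                   "n_afc", "triplet_id", "target_m", "visual_center_m",
                   "visual_sd_log", "audio_freq_hz", "feedback")

#' Write a trial table to CSV
#'
#' @param trials Trial table (with or without responses).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  cf_assert(all(TRIAL_COLUMNS %in% names(trials)),
            "`trials` is missing required columns")
  readr::write_csv(trials, path)
  invisible(path)
}

#' Read and validate a trial table
#'
#' Reads the CSV dialect written by [write_trials()] and validates it:
#' required columns present; targets (and responses, if present) within the
#' response line \[10, 35\]; visual fields present exactly on visual and
#' audio-visual trials; triplets complete (three members). Violations are
#' reported with row numbers.
#'
#' @param path CSV file.
#' @return A validated tibble of trials.
#' @export
read_trials <- function(path) {
  cf_assert(file.exists(path), paste0("no such file: ", path))
  trials <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(TRIAL_COLUMNS, names(trials))
  cf_assert(length(missing) == 0,
            paste0("missing column(s): ", paste(missing, collapse = ", ")))

  problems <- character(0)
  offend <- function(bad, what) {
    if (any(bad)) {
      rows <- utils::head(which(bad), 5)
      problems <<- c(problems, paste0(
        what, " (", sum(bad), " row(s), e.g. ",
        paste(rows, collapse = ", "), ")"))
    }
  }
  offend(!is.finite(trials$target_m) | trials$target_m < .LINE_LO |
           trials$target_m > .LINE_HI,
         "target_m outside the response line [10, 35]")
  if ("response_m" %in% names(trials)) {
    offend(!is.na(trials$response_m) &
             (trials$response_m < .LINE_LO | trials$response_m > .LINE_HI),
           "response_m outside the response line [10, 35]")
  }
  needs_visual <- trials$trial_type %in% c("visual", "audiovisual")
  offend(needs_visual & (is.na(trials$visual_center_m) |
                           is.na(trials$visual_sd_log)),
         "visual/audio-visual trial without visual fields")
  offend(!needs_visual & !is.na(trials$visual_center_m),
         "audio trial with visual fields")

  trip <- trials[!is.na(trials$triplet_id) & trials$phase == "main", ]
  if (nrow(trip) > 0) {
    sizes <- trip |>
      dplyr::count(.data$participant_id, .data$session, .data$triplet_id)
    if (any(sizes$n != 3)) {
      bad <- sizes[sizes$n != 3, ]
      problems <- c(problems, paste0(
        "incomplete triplet(s): ",
        paste(utils::head(paste0(bad$participant_id, "/s", bad$session, "/t",
                                 bad$triplet_id), 5), collapse = ", "),
        " (", nrow(bad), " total)"))
    }
  }
  if (length(problems) > 0) {
    stop("invalid trial table:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  trials
}

#' Pipeline run configuration
#'
#' @param seed Run seed; every stochastic stage derives a named substream
#'   from it.
#' @param participants Cohort size.
#' @param sessions Sessions to generate and analyse.
#' @param audio_sd_log Audio noise SD (log units), scalar or per participant.
#' @param observer Arguments passed to [observer_params()] for the simulated
#'   cohort.
#' @param n_boot Bootstrap resamples for effect-size CIs.
#' @param mcmc An [mcmc_config()] for the reweighting fit.
#' @param validation_replicates Replicates for the type-I-error simulation
#'   stage; 0 (default) skips it, otherwise at least 100.
#' @param ratio_applies_to Whether the visual/audio reliability ratio scales
#'   the SD (default) or the variance.
#' @param out_dir Output directory; `NULL` keeps everything in memory.
#' @return A list of class `cf_config`.
#' @export
cf_config <- function(seed = 1, participants = 12, sessions = 3:5,
                      audio_sd_log = 0.12,
                      observer = list(weighting_policy = "ideal",
                                      motor_sd_log = 0.03,
                                      bias_log = -0.024),
                      n_boot = 10000, mcmc = mcmc_config(),
                      validation_replicates = 0,
                      ratio_applies_to = "sd", out_dir = NULL) {
  structure(list(seed = seed, participants = participants,
                 sessions = sessions, audio_sd_log = audio_sd_log,
                 observer = observer, n_boot = n_boot, mcmc = mcmc,
                 validation_replicates = validation_replicates,
                 ratio_applies_to = ratio_applies_to, out_dir = out_dir),
            class = "cf_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys map to [cf_config()] arguments; an `mcmc` mapping maps to
#' [mcmc_config()] arguments.
#'
#' @param path YAML file.
#' @return A `cf_config` list.
#' @export
cf_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$mcmc)) raw$mcmc <- do.call(mcmc_config, raw$mcmc)
  do.call(cf_config, raw)
}

#' Run the full pipeline
#'
#' Simulates (or loads) a cohort, summarizes errors, runs both paired
#' contrasts omnibus and per session, computes the visual-reliance measure,
#' fits the reweighting model, and optionally runs the type-I-error
#' validation. All tables, a JSON reweighting summary, a config snapshot and
#' a run log are written to `config$out_dir` when set.
#'
#' If the cohort cannot support the reweighting fit (it needs both
#' reliability-change directions), that stage is skipped and the refusal is
#' recorded in the log; the contrasts are still produced.
#'
#' @param config A [cf_config()].
#' @param trials Optional pre-existing trial table (e.g. from
#'   [read_trials()]); when `NULL` a cohort is simulated.
#' @return Invisibly, a list with `trials`, `summaries`, `contrasts`,
#'   `reliance`, `optimality`, `reweighting` (summary or `NULL`),
#'   `validation` (report or `NULL`), and `log` (character).
#' @export
run_pipeline <- function(config = cf_config(), trials = NULL) {
  cf_assert(inherits(config, "cf_config"),
            "`config` must come from cf_config()")
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  if (is.null(trials)) {
    say("[simulate] ", config$participants, " participants, sessions ",
        paste(config$sessions, collapse = ","))
    params <- session_params(audio_sd_log = config$audio_sd_log[1],
                             ratio_applies_to = config$ratio_applies_to)
    designs <- make_cohort_designs(
      config$participants, sessions = config$sessions,
      audio_sd_log = config$audio_sd_log,
      seed = substream_seed(config$seed, "design"), params = params)
    cohort <- lapply(rep_len(config$audio_sd_log, config$participants),
                     function(sd) {
      do.call(observer_params, c(list(sigma_audio_log = sd),
                                 config$observer))
    })
    trials <- simulate_experiment(cohort, designs,
                                  seed = substream_seed(config$seed,
                                                        "responses"))
    say("[simulate] ", nrow(trials), " trials, ",
        attr(trials, "clamped"), " response(s) clamped at the line limits")
  } else {
    say("[load] using supplied trials (", nrow(trials), " rows)")
  }

  say("[errors] constant/variable error per cell")
  summaries <- summarize_errors(trials)
  say("[errors] ", nrow(summaries), " cells")

  say("[contrasts] paired sign-rank tests + bootstrap effect sizes")
  contrasts <- cue_contrasts(trials, n_boot = config$n_boot,
                             seed = substream_seed(config$seed, "bootstrap"))
  reliance <- visual_reliance(trials)
  optimality <- optimality_gap(trials)

  reweighting <- NULL
  rw_error <- tryCatch({
    rd <- reweighting_data(trials)
    cf_assert(length(unique(rd$directions)) == 2,
              "reweighting fit needs both reliability-change directions")
    say("[reweight] fitting ", config$mcmc$n_chains, " chains x ",
        config$mcmc$n_samples, " samples")
    mc <- config$mcmc
    mc$seed <- substream_seed(config$seed, "mcmc")
    reweighting <- summarize_reweighting(fit_reweighting(rd, mc))
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(rw_error)) say("[reweight] skipped: ", rw_error)

  validation <- NULL
  if (config$validation_replicates >= 100) {
    say("[validate] type-I simulation, ", config$validation_replicates,
        " replicates")
    validation <- type1_error_sim(
      n_replicates = config$validation_replicates,
      cohort_size = config$participants,
      audio_sd_log = config$audio_sd_log[1],
      seed = substream_seed(config$seed, "type1"))
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$out_dir, f)
    write_trials(trials, out("trials.csv"))
    readr::write_csv(summaries, out("summaries.csv"))
    readr::write_csv(contrasts, out("contrasts.csv"))
    readr::write_csv(reliance, out("reliance.csv"))
    readr::write_csv(optimality, out("optimality.csv"))
    if (!is.null(reweighting)) {
      jsonlite::write_json(
        list(participants = reweighting$participants,
             m = as.list(reweighting$m), t = as.list(reweighting$t),
             n_direction_consistent = reweighting$n_direction_consistent,
             rhat_max = reweighting$rhat_max, ess_m = reweighting$ess_m),
        out("reweighting.json"), auto_unbox = TRUE, digits = NA)
    }
    if (!is.null(validation)) {
      jsonlite::write_json(
        list(scenario = validation$scenario,
             n_replicates = validation$n_replicates,
             fraction_significant = validation$fraction_significant,
             alpha = validation$alpha),
        out("validation.json"), auto_unbox = TRUE, digits = NA)
    }
    cfg <- config
    cfg$mcmc <- unclass(cfg$mcmc)
    yaml::write_yaml(unclass(cfg), out("config.yaml"))
    writeLines(log_lines, out("log.txt"))
    say("[done] outputs in ", config$out_dir)
  }

  invisible(list(trials = trials, summaries = summaries,
                 contrasts = contrasts, reliance = reliance,
                 optimality = optimality, reweighting = reweighting,
                 validation = validation, log = log_lines))
}
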