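# Internal helpers shared across modules.

# Response line limits in metres: nearest and furthest possible positions.
.LINE_LO <- 10
.LINE_HI <- 35

# Speed of sound in air used for the echo-delay cue, m/s.
.SPEED_OF_SOUND <- 350

cf_assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

clamp <- function(x, lo = .LINE_LO, hi = .LINE_HI) pmin(pmax(x, lo), hi)

#' Derive a reproducible sub-seed from a run seed and a stage label
#'
#' Every stochastic stage of the pipeline draws its RNG stream from a single
#' run seed through a named substream, so that changing one stage (say, the
#' bootstrap) never perturbs another (say, the simulated responses).
#'
#' @param seed Integer run seed.
#' @param label Character stage label, e.g. `"type1-rep-12"`.
#' @return An integer seed in `[0, 2^31)`.
#' @examples
#' substream_seed(1, "design")
#' @export
substream_seed <- function(seed, label) {
  cf_assert(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
            "`seed` must be a single finite number")
  cf_assert(is.character(label) && length(label) == 1,
            "`label` must be a single string")
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% 1000003
  as.integer((abs(seed) %% 2146000000 + h) %% 2147483647)
}

# Evaluate `code` under `set.seed(seed)`, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
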