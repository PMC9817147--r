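# Transformed up-down adaptive staircases, threshold estimation, validity
# rules, pure-tone averages and the binaural masking level difference.

#' Configure an adaptive staircase
#'
#' @param rule `"one_up_one_down"` (converges to 50% correct) or
#'   `"one_up_three_down"` (converges to 0.5^(1/3) = 79.4% correct).
#' @param initial_level Starting level in dB.
#' @param step_schedule Data frame with columns `after_reversal` and
#'   `step_db`: each step size applies to movements after that many
#'   completed reversals.
#' @param total_reversals Reversals collected before the track ends.
#' @param average_last Number of trailing reversals averaged into the
#'   threshold.
#' @param level_cap,level_floor Optional hard level limits in dB.
#' @param max_cap_hits Track is invalidated once the cap has been hit on
#'   this many trials.
#' @param max_trials Track is invalidated after this many trials without
#'   completing its reversals.
#' @return A `staircase_config` object.
#' @export
staircase_config <- function(rule = c("one_up_one_down", "one_up_three_down"),
                             initial_level,
                             step_schedule,
                             total_reversals,
                             average_last,
                             level_cap = NULL,
                             level_floor = NULL,
                             max_cap_hits = 6,
                             max_trials = 200) {
  rule <- match.arg(rule)
  check_param(all(c("after_reversal", "step_db") %in% names(step_schedule)),
              "step_schedule needs columns after_reversal and step_db")
  step_schedule <- step_schedule[order(step_schedule$after_reversal), ]
  check_param(all(diff(step_schedule$step_db) <= 0),
              "step sizes must be non-increasing over a track")
  check_param(average_last <= total_reversals,
              "average_last cannot exceed total_reversals")
  structure(list(rule = rule, initial_level = initial_level,
                 step_schedule = step_schedule,
                 total_reversals = as.integer(total_reversals),
                 average_last = as.integer(average_last),
                 level_cap = level_cap, level_floor = level_floor,
                 max_cap_hits = as.integer(max_cap_hits),
                 max_trials = as.integer(max_trials)),
            class = "staircase_config")
}

#' Audiometry staircase preset
#'
#' One-up one-down; steps 20 dB, then 10 dB after the second reversal, then
#' 5 dB after the fourth; eight reversals, threshold from the last four.
#'
#' @param initial_level Starting level in dB HL.
#' @return A `staircase_config`.
#' @export
audiometry_config <- function(initial_level = 40) {
  staircase_config("one_up_one_down", initial_level,
                   data.frame(after_reversal = c(0, 2, 4),
                              step_db = c(20, 10, 5)),
                   total_reversals = 8, average_last = 4)
}

#' Tone-in-noise staircase preset
#'
#' One-up three-down; step 4 dB up to the second reversal, 2 dB thereafter;
#' ten reversals, threshold from the last eight; tone level capped at
#' 80 dB SPL.
#'
#' @param initial_level Starting tone level in dB SPL (65 for N0S0, 50 for
#'   N0Spi in the protocol).
#' @return A `staircase_config`.
#' @export
tin_config <- function(initial_level) {
  staircase_config("one_up_three_down", initial_level,
                   data.frame(after_reversal = c(0, 2),
                              step_db = c(4, 2)),
                   total_reversals = 10, average_last = 8,
                   level_cap = protocol_constants$tin_cap_db_spl)
}

#' Initialise the state of a staircase track
#' @param cfg A `staircase_config`.
#' @return A `track_state` object.
#' @export
new_track <- function(cfg) {
  structure(list(current_level = cfg$initial_level,
                 consecutive_correct = 0L,
                 reversal_levels = numeric(0),
                 reversal_trials = integer(0),
                 direction = "none",
                 trial_count = 0L,
                 cap_hits = 0L,
                 complete = FALSE,
                 invalid = FALSE,
                 levels = numeric(0),
                 responses = logical(0)),
            class = "track_state")
}

#' Current step size given the number of completed reversals
#' @noRd
current_step <- function(cfg, n_reversals) {
  sched <- cfg$step_schedule
  sched$step_db[max(which(sched$after_reversal <= n_reversals))]
}

#' Advance a staircase by one response
#'
#' Implements the transformed up-down rules: under one-up three-down the
#' level decreases only after three consecutive correct responses (the
#' counter then resets) and increases after any error; under one-up
#' one-down every response moves the level. A reversal is recorded at the
#' extremal level whenever the movement direction changes, and the step
#' size follows the schedule keyed on completed reversals (a new step
#' applies to movements following the completion of the keying reversal).
#' A would-be increase beyond the level cap clamps to the cap and counts
#' one cap hit.
#'
#' @param state A `track_state` (not yet complete).
#' @param correct Logical response on the trial presented at
#'   `state$current_level`.
#' @param cfg The `staircase_config`.
#' @return The updated `track_state`.
#' @export
staircase_update <- function(state, correct, cfg) {
  if (isTRUE(state$complete)) stop("track is already complete", call. = FALSE)
  state$trial_count <- state$trial_count + 1L
  state$levels <- c(state$levels, state$current_level)
  state$responses <- c(state$responses, isTRUE(correct))

  move <- NULL
  if (cfg$rule == "one_up_three_down") {
    if (isTRUE(correct)) {
      state$consecutive_correct <- state$consecutive_correct + 1L
      if (state$consecutive_correct == 3L) {
        move <- "down"
        state$consecutive_correct <- 0L
      }
    } else {
      state$consecutive_correct <- 0L
      move <- "up"
    }
  } else {
    move <- if (isTRUE(correct)) "down" else "up"
  }

  if (!is.null(move)) {
    if (state$direction != "none" && move != state$direction) {
      state$reversal_levels <- c(state$reversal_levels, state$current_level)
      state$reversal_trials <- c(state$reversal_trials, state$trial_count)
      if (length(state$reversal_levels) >= cfg$total_reversals) {
        state$complete <- TRUE
        state$direction <- move
        return(state)
      }
    }
    state$direction <- move
    step <- current_step(cfg, length(state$reversal_levels))
    new_level <- state$current_level + if (move == "up") step else -step
    if (!is.null(cfg$level_cap) && new_level > cfg$level_cap) {
      new_level <- cfg$level_cap
      state$cap_hits <- state$cap_hits + 1L
    }
    if (!is.null(cfg$level_floor) && new_level < cfg$level_floor) {
      new_level <- cfg$level_floor
    }
    state$current_level <- new_level
  }

  if (state$cap_hits >= cfg$max_cap_hits || state$trial_count >= cfg$max_trials) {
    state$complete <- TRUE
    state$invalid <- TRUE
  }
  state
}

#' Run a complete staircase track against a responder
#'
#' @param listener_respond Function of the presented level returning `TRUE`
#'   (correct/detected) or `FALSE`; it may use the RNG.
#' @param cfg A `staircase_config`.
#' @param rng_seed Integer seed for the responder's randomness.
#' @return A `track_result`: list with `threshold` (dB, `NA` when invalid),
#'   `valid`, `reversal_levels`, and a `trial_log` data frame
#'   (`trial_index`, `level_db`, `response_correct`, `reversal_flag`).
#' @export
run_track <- function(listener_respond, cfg, rng_seed) {
  state <- with_seed(rng_seed, {
    st <- new_track(cfg)
    while (!st$complete) {
      st <- staircase_update(st, listener_respond(st$current_level), cfg)
    }
    st
  })
  track_result(state, cfg)
}

#' Assemble a track result from a finished state
#' @noRd
track_result <- function(state, cfg) {
  valid <- !state$invalid &&
    length(state$reversal_levels) >= cfg$total_reversals
  threshold <- if (valid)
    mean(utils::tail(state$reversal_levels, cfg$average_last))
  else NA_real_
  log <- data.frame(trial_index = seq_along(state$levels),
                    level_db = state$levels,
                    response_correct = state$responses,
                    reversal_flag = mark_reversal_trials(state))
  structure(list(threshold = threshold, valid = valid,
                 reversal_levels = state$reversal_levels,
                 cap_hits = state$cap_hits,
                 trial_log = log),
            class = "track_result")
}

#' Flag the trials that triggered a reversal
#' @noRd
mark_reversal_trials <- function(state) {
  flags <- logical(length(state$levels))
  flags[state$reversal_trials] <- TRUE
  flags
}

#' Export a track log as CSV
#' @param result A `track_result`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_track_log <- function(result, path) {
  utils::write.csv(result$trial_log, path, row.names = FALSE)
  invisible(path)
}

#' Binaural masking level difference
#'
#' BMLD = threshold(N0S0) minus the better (lower) of the two valid N0Spi
#' thresholds. Missing when the N0S0 track is invalid (reason
#' `"no_convergence_all"`) or when both N0Spi tracks are invalid (reason
#' `"no_convergence_dichotic"`).
#'
#' @param n0s0 A `track_result` for the N0S0 condition.
#' @param nspi_runs List of two `track_result`s for the N0Spi condition.
#' @return List with `bmld` (dB or `NA`) and `reason` (`NA` or the
#'   missingness reason).
#' @export
compute_bmld <- function(n0s0, nspi_runs) {
  nspi_thr <- vapply(nspi_runs,
                     function(r) if (r$valid) r$threshold else NA_real_,
                     numeric(1))
  if (!n0s0$valid) {
    return(list(bmld = NA_real_, reason = "no_convergence_all"))
  }
  if (all(is.na(nspi_thr))) {
    return(list(bmld = NA_real_, reason = "no_convergence_dichotic"))
  }
  list(bmld = n0s0$threshold - min(nspi_thr, na.rm = TRUE), reason = NA_character_)
}

#' Pure-tone average over 500, 1000 and 3000 Hz
#'
#' Computes per-ear PTA3, their average and absolute asymmetry, and an
#' exclusion flag set when either ear's PTA3 exceeds 40 dB HL (strict
#' inequality).
#'
#' @param thresholds Data frame with columns `ear` (`"L"`/`"R"`),
#'   `freq_hz` and `threshold_db_hl`, one row per (ear, frequency).
#' @return An `audiometry_summary`: per-ear thresholds, `pta3_left`,
#'   `pta3_right`, `pta3`, `pta3_asym`, `excluded`, `complete`.
#' @export
compute_pta3 <- function(thresholds) {
  freqs <- protocol_constants$audiometry_freqs
  need <- expand.grid(ear = c("L", "R"), freq_hz = freqs,
                      stringsAsFactors = FALSE)
  got <- merge(need, thresholds, all.x = TRUE, sort = FALSE)
  complete <- !any(is.na(got$threshold_db_hl))
  pta <- function(e) mean(got$threshold_db_hl[got$ear == e])
  pl <- pta("L"); pr <- pta("R")
  structure(list(thresholds = got,
                 pta3_left = pl, pta3_right = pr,
                 pta3 = (pl + pr) / 2,
                 pta3_asym = abs(pl - pr),
                 excluded = isTRUE(pl > 40) || isTRUE(pr > 40),
                 complete = complete),
            class = "audiometry_summary")
}
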