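# Parametric virtual listeners: a psychometric detection model for the
# tone-in-noise task, a cue-to-key response model for the lateralization
# task, and cohort simulation reproducing the qualitative response
# archetypes seen in lesion patients (side-oriented/categorical responding,
# shifted auditory space, high trial-to-trial variability, flattened ITD
# sensitivity).

#' Detection listener parameters
#'
#' Psychometric model of a 3-interval forced-choice tone-in-noise listener:
#' `P(correct) = guess + (1 - guess - lapse) * Phi((L - mu_c) / sigma)`,
#' where the N0Spi midpoint is the N0S0 midpoint minus the binaural
#' advantage.
#'
#' @param mu_n0s0 Psychometric midpoint for N0S0 in dB SPL.
#' @param binaural_advantage Midpoint improvement for N0Spi in dB (>= 0).
#' @param sigma_psy Psychometric slope parameter in dB.
#' @param lapse Lapse rate (0..0.1).
#' @param guess Guess rate (1/3 for the 3-interval task).
#' @param audiogram Data frame (`ear`, `freq_hz`, `threshold_db_hl`) of true
#'   audiometric thresholds used to simulate the audiometry staircases.
#' @param sigma_audio Slope of the audiometric psychometric function in dB.
#' @return A `detection_listener_params` object.
#' @export
detection_listener_params <- function(mu_n0s0 = 64,
                                      binaural_advantage = 13,
                                      sigma_psy = 3,
                                      lapse = 0.02,
                                      guess = 1 / 3,
                                      audiogram = flat_audiogram(10),
                                      sigma_audio = 2) {
  check_param(lapse >= 0 && lapse <= 0.1, "lapse must be in [0, 0.1]")
  check_param(sigma_psy > 0, "sigma_psy must be positive")
  check_param(binaural_advantage >= 0, "binaural_advantage must be >= 0")
  structure(list(mu_n0s0 = mu_n0s0, binaural_advantage = binaural_advantage,
                 sigma_psy = sigma_psy, lapse = lapse, guess = guess,
                 audiogram = audiogram, sigma_audio = sigma_audio),
            class = "detection_listener_params")
}

#' Flat audiogram at a single threshold
#' @param threshold_db_hl Threshold applied to every ear and frequency.
#' @return Audiogram data frame.
#' @export
flat_audiogram <- function(threshold_db_hl) {
  expand.grid(ear = c("L", "R"),
              freq_hz = protocol_constants$audiometry_freqs,
              stringsAsFactors = FALSE) |>
    transform(threshold_db_hl = threshold_db_hl)
}

#' Probability of a correct tone-in-noise response
#'
#' @param params A `detection_listener_params`.
#' @param tone_level Tone level in dB SPL.
#' @param condition `"N0S0"` or `"N0Spi"`.
#' @return Probability of a correct response.
#' @export
detection_prob <- function(params, tone_level, condition = c("N0S0", "N0Spi")) {
  condition <- match.arg(condition)
  mu <- params$mu_n0s0 -
    if (condition == "N0Spi") params$binaural_advantage else 0
  params$guess + (1 - params$guess - params$lapse) *
    stats::pnorm((tone_level - mu) / params$sigma_psy)
}

#' Tone level tracked by a 79.4%-converging staircase for this listener
#'
#' Solves `P(correct) = p_target` for the level; with the default guess of
#' 1/3 and no lapse this is `mu_c + qnorm((p - 1/3) / (2/3)) * sigma`.
#'
#' @param params A `detection_listener_params`.
#' @param condition `"N0S0"` or `"N0Spi"`.
#' @param p_target Tracked probability (0.5^(1/3) for one-up three-down).
#' @return Level in dB SPL.
#' @export
tracked_level <- function(params, condition = "N0S0", p_target = 0.5^(1 / 3)) {
  mu <- params$mu_n0s0 -
    if (condition == "N0Spi") params$binaural_advantage else 0
  q <- (p_target - params$guess) / (1 - params$guess - params$lapse)
  check_param(q > 0 && q < 1, "p_target outside the attainable range")
  mu + stats::qnorm(q) * params$sigma_psy
}

#' Lateralization listener parameters
#'
#' The listener maps a cue to an internal position
#' `x = bias + g_side * s(cue) + noise` on a [-1, 1] scale (-1 = left ear,
#' +1 = right ear), where `s(itd) = itd / 600 us` and `s(ild) = ild / 12 dB`
#' (clipped), with side-specific gains. Monaural stimuli map to
#' `bias +/- mon_extent`. ITDs of +/-1500 us are ambiguous: with probability
#' `ambiguity_weight` they are heard on their fine-structure alias side
#' (a 1500-us lead aliases to a 500-us lag for a 500-Hz carrier with its
#' 2000-us period), otherwise on the leading side, in both cases at the
#' 500-us extent. The internal position is clipped and affinely mapped to
#' the response keys: `key = round(5 + 4 * x)`, snapped to the nearest
#' allowed key (ties to the lower key); with probability `confusion_prob`
#' the mirrored key `10 - key` is reported instead.
#'
#' @param bias Constant internal-position offset (-1..1; 0 = centred).
#' @param gain_itd_left,gain_itd_right,gain_ild_left,gain_ild_right
#'   Dimensionless slopes per normalised cue for each cue type and side.
#' @param noise_sd SD of the internal-position noise.
#' @param allowed_keys Non-empty subset of 1..9 the listener uses.
#' @param confusion_prob Probability of reporting the mirrored key.
#' @param ambiguity_weight Probability that a supra-physiological ITD is
#'   heard on its alias side.
#' @param mon_extent Internal-position magnitude of monaural stimuli.
#' @return A `lateralization_listener_params` object.
#' @export
lateralization_listener_params <- function(bias = 0,
                                           gain_itd_left = 0.7,
                                           gain_itd_right = 0.7,
                                           gain_ild_left = 0.45,
                                           gain_ild_right = 0.45,
                                           noise_sd = 0.25,
                                           allowed_keys = 1:9,
                                           confusion_prob = 0.01,
                                           ambiguity_weight = 0.5,
                                           mon_extent = 0.9) {
  check_param(length(allowed_keys) > 0 && all(allowed_keys %in% 1:9),
              "allowed_keys must be a non-empty subset of 1..9")
  structure(list(bias = bias,
                 gain_itd_left = gain_itd_left,
                 gain_itd_right = gain_itd_right,
                 gain_ild_left = gain_ild_left,
                 gain_ild_right = gain_ild_right,
                 noise_sd = noise_sd,
                 allowed_keys = sort(unique(as.integer(allowed_keys))),
                 confusion_prob = confusion_prob,
                 ambiguity_weight = ambiguity_weight,
                 mon_extent = mon_extent),
            class = "lateralization_listener_params")
}

#' Snap to the nearest allowed key, ties resolved to the lower key
#' @noRd
snap_key <- function(key, allowed) {
  allowed[which.min(abs(allowed - key))]
}

#' Simulate one lateralization response
#'
#' Draws one 9-key response for a cue under the listener model of
#' [lateralization_listener_params()]. Uses the current RNG stream.
#'
#' @param params A `lateralization_listener_params`.
#' @param cue A `lat_cue` on the protocol grid.
#' @return Integer response key in 1..9.
#' @export
respond_lateralization <- function(params, cue) {
  p <- protocol_constants
  if (cue$kind == "itd" && abs(cue$value) %in% abs(p$itd_extreme_us)) {
    # period at 500 Hz is 2000 us: a 1500-us lead aliases to a 500-us lag
    alias_val <- -sign(cue$value) * 500
    lead_val <- sign(cue$value) * 500
    v <- if (stats::runif(1) < params$ambiguity_weight) alias_val else lead_val
    s <- clip(v / 600)
  } else {
    s <- switch(cue$kind,
                itd = clip(cue$value / 600),
                ild = clip(cue$value / 12),
                diotic = 0,
                mon_left = NA_real_, mon_right = NA_real_)
  }
  if (cue$kind %in% c("mon_left", "mon_right")) {
    x <- params$bias +
      if (cue$kind == "mon_right") params$mon_extent else -params$mon_extent
  } else {
    gain <- 0
    if (s != 0) {
      gain <- switch(cue$kind,
                     itd = if (s < 0) params$gain_itd_left else params$gain_itd_right,
                     ild = if (s < 0) params$gain_ild_left else params$gain_ild_right)
    }
    x <- params$bias + gain * s
  }
  x <- x + stats::rnorm(1, 0, params$noise_sd)
  key <- round(5 + 4 * clip(x))
  key <- snap_key(key, params$allowed_keys)
  if (stats::runif(1) < params$confusion_prob) {
    key <- snap_key(10 - key, params$allowed_keys)
  }
  as.integer(key)
}

#' Listener archetype presets
#'
#' Named parameter presets reproducing qualitative response patterns
#' observed after lesions at different sites: `"control"` (the normative
#' listener), `"categorical"` (responses restricted to left/centre/right
#' keys), `"side_oriented"` (left/right keys only, no centred percepts),
#' `"shifted"` (auditory space displaced toward one side),
#' `"high_variability"` (doubled internal noise), `"flattened_itd"`
#' (near-zero ITD sensitivity with preserved ILD lateralization),
#' `"lr_confusion"` (frequent left-right confusions),
#' `"no_binaural_benefit"` (near-zero binaural advantage in detection), and
#' `"task_failure"` (near-chance tone-in-noise performance, so the
#' staircase runs into the level cap and the tracks never converge).
#'
#' @param name Archetype name.
#' @return List with elements `det` (`detection_listener_params`) and
#'   `lat` (`lateralization_listener_params`).
#' @export
archetype_params <- function(name = c("control", "categorical",
                                      "side_oriented", "shifted",
                                      "high_variability", "flattened_itd",
                                      "lr_confusion", "no_binaural_benefit",
                                      "task_failure")) {
  name <- match.arg(name)
  det <- detection_listener_params()
  lat <- lateralization_listener_params()
  switch(name,
    control = NULL,
    categorical = { lat$allowed_keys <- c(1L, 5L, 9L) },
    side_oriented = { lat$allowed_keys <- c(1L, 2L, 8L, 9L) },
    shifted = { lat$bias <- 0.25 },
    high_variability = { lat$noise_sd <- 0.5 },
    flattened_itd = { lat$gain_itd_left <- lat$gain_itd_right <- 0.05 },
    lr_confusion = { lat$confusion_prob <- 0.3 },
    no_binaural_benefit = { det$binaural_advantage <- 2 },
    task_failure = { det$mu_n0s0 <- 150; det$binaural_advantage <- 0 }
  )
  list(det = det, lat = lat)
}

#' Draw individual listener parameters from the population model
#'
#' Starts from the archetype preset and adds between-subject variability to
#' the control-population parameters (bias, gains, internal noise, monaural
#' extent, detection midpoint, binaural advantage, audiogram). The defining
#' parameter of a non-control archetype is then re-imposed so the archetype
#' pattern survives the jitter. Uses the current RNG stream.
#'
#' @param archetype Archetype name, see [archetype_params()].
#' @return List with `det` and `lat` parameter objects.
#' @export
sample_listener_params <- function(archetype = "control") {
  a <- archetype_params(archetype)
  lat <- a$lat
  det <- a$det

  lat$bias <- stats::rnorm(1, lat$bias, 0.05)
  lat$gain_itd_left <- stats::rnorm(1, lat$gain_itd_left, 0.06)
  lat$gain_itd_right <- stats::rnorm(1, lat$gain_itd_right, 0.06)
  lat$gain_ild_left <- stats::rnorm(1, lat$gain_ild_left, 0.05)
  lat$gain_ild_right <- stats::rnorm(1, lat$gain_ild_right, 0.05)
  lat$noise_sd <- lat$noise_sd * exp(stats::rnorm(1, 0, 0.2))
  lat$mon_extent <- clip(stats::rnorm(1, lat$mon_extent, 0.04), 0, 1)

  det$mu_n0s0 <- stats::rnorm(1, det$mu_n0s0, 2)
  det$binaural_advantage <- max(0, stats::rnorm(1, det$binaural_advantage, 3.5))
  base <- pmax(0, stats::rnorm(1, 12, 6))
  asym <- stats::rnorm(1, 0, 3)
  ag <- expand.grid(ear = c("L", "R"),
                    freq_hz = protocol_constants$audiometry_freqs,
                    stringsAsFactors = FALSE)
  ag$threshold_db_hl <- base +
    ifelse(ag$freq_hz == 3000, 8, 0) +
    ifelse(ag$ear == "L", asym / 2, -asym / 2) +
    stats::rnorm(nrow(ag), 0, 2)
  det$audiogram <- ag

  # re-impose the archetype-defining parameter after jitter
  proto <- archetype_params(archetype)
  switch(archetype,
    shifted = { lat$bias <- proto$lat$bias + abs(stats::rnorm(1, 0, 0.05)) },
    high_variability = { lat$noise_sd <- proto$lat$noise_sd * exp(abs(stats::rnorm(1, 0, 0.1))) },
    flattened_itd = {
      lat$gain_itd_left <- lat$gain_itd_right <- proto$lat$gain_itd_left
    },
    categorical = ,
    side_oriented = { lat$allowed_keys <- proto$lat$allowed_keys },
    lr_confusion = { lat$confusion_prob <- proto$lat$confusion_prob },
    no_binaural_benefit = { det$binaural_advantage <- proto$det$binaural_advantage },
    task_failure = {
      det$mu_n0s0 <- proto$det$mu_n0s0
      det$binaural_advantage <- proto$det$binaural_advantage
    },
    NULL
  )
  list(det = det, lat = lat)
}

#' Internal: run a staircase against a responder using the current RNG
#' @noRd
run_track_rng <- function(listener_respond, cfg) {
  st <- new_track(cfg)
  while (!st$complete) {
    st <- staircase_update(st, listener_respond(st$current_level), cfg)
  }
  track_result(st, cfg)
}

#' The full shuffled lateralization trial sequence
#'
#' Sixteen non-diotic stimuli (6 physiological ITDs, 2 supra-physiological
#' ITDs, 6 ILDs, 2 monaural) presented 6 times each plus 8 diotic trials:
#' 104 trials, ITD and ILD trials interleaved in one shuffled sequence.
#' Uses the current RNG stream for the shuffle.
#'
#' @return Data frame with `stimulus_type`, `stimulus_value`.
#' @export
lat_trial_sequence <- function() {
  p <- protocol_constants
  stim <- rbind(
    data.frame(stimulus_type = "itd",
               stimulus_value = c(p$itd_grid_us, p$itd_extreme_us)),
    data.frame(stimulus_type = "ild", stimulus_value = p$ild_grid_db),
    data.frame(stimulus_type = c("mon_left", "mon_right"),
               stimulus_value = NA_real_)
  )
  seq_df <- rbind(
    stim[rep(seq_len(nrow(stim)), each = p$n_per_stimulus), ],
    data.frame(stimulus_type = "diotic",
               stimulus_value = rep(0, p$n_diotic))
  )
  seq_df[sample.int(nrow(seq_df)), , drop = FALSE]
}

#' Simulate one complete measurement session
#'
#' Runs the full protocol for one virtual listener: six audiometry
#' staircases (both ears at 500, 1000 and 3000 Hz), the tone-in-noise task
#' (two N0Spi runs followed by one N0S0 run, with BMLD), and the
#' lateralization task (104 interleaved trials, see
#' [lat_trial_sequence()]). Reproducible from the seed.
#'
#' @param det A `detection_listener_params`.
#' @param lat A `lateralization_listener_params`.
#' @param seed Integer seed.
#' @param participant_id Identifier stored in the outputs.
#' @param group Group label (e.g. `"control"` or a lesion-group label).
#' @param tasks Subset of `c("audiometry", "tin", "lateralization")` to run.
#' @return A `session_data` list: `participant_id`, `group`, `audiometry`
#'   (an `audiometry_summary`), `tin` (track results, `bmld`, `reason`),
#'   `lateralization` (a trial-log data frame), `covariates`, `seed`.
#' @export
simulate_session <- function(det, lat, seed, participant_id = "P1",
                             group = "control",
                             tasks = c("audiometry", "tin", "lateralization")) {
  p <- protocol_constants
  with_seed(seed, {
    audiometry <- NULL
    if ("audiometry" %in% tasks) {
      rows <- list()
      for (ear in c("L", "R")) for (f in p$audiometry_freqs) {
        thr <- det$audiogram$threshold_db_hl[det$audiogram$ear == ear &
                                               det$audiogram$freq_hz == f]
        res <- run_track_rng(function(level) {
          stats::runif(1) < stats::pnorm((level - thr) / det$sigma_audio)
        }, audiometry_config())
        rows[[length(rows) + 1]] <- data.frame(
          ear = ear, freq_hz = f, threshold_db_hl = res$threshold)
      }
      audiometry <- compute_pta3(do.call(rbind, rows))
    }

    tin <- NULL
    if ("tin" %in% tasks) {
      responder <- function(condition) {
        function(level) stats::runif(1) < detection_prob(det, level, condition)
      }
      nspi <- list(run_track_rng(responder("N0Spi"), tin_config(50)),
                   run_track_rng(responder("N0Spi"), tin_config(50)))
      n0s0 <- run_track_rng(responder("N0S0"), tin_config(65))
      bm <- compute_bmld(n0s0, nspi)
      tin <- list(n0s0 = n0s0, nspi = nspi, bmld = bm$bmld, reason = bm$reason)
    }

    lateralization <- NULL
    if ("lateralization" %in% tasks) {
      seq_df <- lat_trial_sequence()
      keys <- integer(nrow(seq_df))
      for (i in seq_len(nrow(seq_df))) {
        cue <- lat_cue(seq_df$stimulus_type[i],
                       if (is.na(seq_df$stimulus_value[i])) NA_real_
                       else seq_df$stimulus_value[i])
        keys[i] <- respond_lateralization(lat, cue)
      }
      lateralization <- data.frame(
        participant_id = participant_id,
        task = "lateralization",
        trial_index = seq_len(nrow(seq_df)),
        stimulus_type = seq_df$stimulus_type,
        stimulus_value = seq_df$stimulus_value,
        response_key = keys,
        row.names = NULL)
    }

    structure(list(participant_id = participant_id, group = group,
                   audiometry = audiometry, tin = tin,
                   lateralization = lateralization,
                   covariates = list(), seed = seed),
              class = "session_data")
  })
}

#' Specify a simulated cohort
#'
#' @param n_controls Number of control listeners (>= 2).
#' @param roster Patient roster: list of entries
#'   `list(archetype =, group =, n =)`; `n` defaults to 1. An empty roster
#'   gives a controls-only cohort.
#' @param master_seed Master seed; per-participant seeds are derived from
#'   it deterministically.
#' @param tasks Tasks simulated for every participant.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_controls = 12, roster = list(), master_seed = 1,
                        tasks = c("audiometry", "tin", "lateralization")) {
  check_param(n_controls >= 2, "need at least 2 controls")
  structure(list(n_controls = as.integer(n_controls), roster = roster,
                 master_seed = master_seed, tasks = tasks),
            class = "cohort_spec")
}

#' Read a cohort specification from a YAML file
#' @param path YAML file with keys `n_controls`, `master_seed`, `tasks`,
#'   `roster` (list of archetype/group/n entries).
#' @return A `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  y <- yaml::read_yaml(path)
  roster <- lapply(y$roster %||% list(), function(e) {
    # YAML 1.1 parses a bare `n:` key as the boolean FALSE; accept it
    names(e)[names(e) %in% c("FALSE", "no")] <- "n"
    e
  })
  cohort_spec(n_controls = y$n_controls %||% 12,
              roster = roster,
              master_seed = y$master_seed %||% 1,
              tasks = y$tasks %||% c("audiometry", "tin", "lateralization"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a full cohort
#'
#' Controls are drawn from the control population model; each roster entry
#' adds patients of the given archetype with their lesion-group label.
#' Per-participant seeds, listener parameters and non-auditory covariates
#' (age, cognitive screen, depression and vocabulary scores, stroke-scale
#' score for patients) are derived deterministically from the master seed.
#'
#' @param spec A `cohort_spec`.
#' @return A `cohort_data` list: `sessions` (named list of `session_data`),
#'   `params` (per-participant listener parameters), `covariates` (data
#'   frame), `spec`.
#' @export
simulate_cohort <- function(spec) {
  roster <- lapply(spec$roster, function(e) {
    list(archetype = e$archetype, group = e$group, n = e$n %||% 1L)
  })
  plan <- data.frame(
    participant_id = character(0), group = character(0),
    archetype = character(0), stringsAsFactors = FALSE)
  for (i in seq_len(spec$n_controls)) {
    plan <- rbind(plan, data.frame(participant_id = sprintf("C%d", i),
                                   group = "control", archetype = "control"))
  }
  k <- 0
  for (e in roster) for (j in seq_len(e$n)) {
    k <- k + 1
    plan <- rbind(plan, data.frame(participant_id = sprintf("S%d", k),
                                   group = e$group, archetype = e$archetype))
  }
  seeds <- derive_seeds(spec$master_seed, 2 * nrow(plan))
  param_seeds <- seeds[seq_len(nrow(plan))]
  session_seeds <- seeds[nrow(plan) + seq_len(nrow(plan))]

  sessions <- list()
  params <- list()
  cov_rows <- list()
  for (i in seq_len(nrow(plan))) {
    id <- plan$participant_id[i]
    pp <- with_seed(param_seeds[i], {
      lp <- sample_listener_params(plan$archetype[i])
      is_control <- plan$group[i] == "control"
      cov <- list(
        age = round(clip(stats::rnorm(1, if (is_control) 61 else 63, 14),
                         35, 90)),
        moca = round(clip(stats::rnorm(1, if (is_control) 28.4 else 23.9,
                                       if (is_control) 1.6 else 4.7), 18, 30)),
        mwtb = round(clip(stats::rnorm(1, if (is_control) 31.4 else 29.7,
                                       4.1), 10, 37)),
        bdi = round(clip(stats::rnorm(1, if (is_control) 6.3 else 7.6,
                                      if (is_control) 3.2 else 5.0), 0, 30)),
        nihss = if (is_control) NA_real_
                else round(clip(stats::rexp(1, 1 / 1.5), 0, 20)))
      list(lp = lp, cov = cov)
    })
    params[[id]] <- pp$lp
    s <- simulate_session(pp$lp$det, pp$lp$lat, session_seeds[i],
                          participant_id = id, group = plan$group[i],
                          tasks = spec$tasks)
    s$covariates <- pp$cov
    sessions[[id]] <- s
    cov_rows[[i]] <- data.frame(
      participant_id = id, group = plan$group[i],
      archetype = plan$archetype[i],
      age = pp$cov$age, moca = pp$cov$moca, mwtb = pp$cov$mwtb,
      bdi = pp$cov$bdi, nihss = pp$cov$nihss,
      pta3 = if (!is.null(s$audiometry)) s$audiometry$pta3 else NA_real_,
      pta3_asym = if (!is.null(s$audiometry)) s$audiometry$pta3_asym
                  else NA_real_)
  }
  structure(list(sessions = sessions, params = params,
                 covariates = do.call(rbind, cov_rows), spec = spec),
            class = "cohort_data")
}
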