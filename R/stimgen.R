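# Stimulus synthesis: octave-band noise, gating, interaural time and level
# differences, and assembled lateralization and tone-in-noise trials.
#
# Sign convention (used throughout the package): a positive ITD or ILD
# favours the RIGHT ear — right channel leading in time, or right channel
# louder. Mirror negation maps a cue onto its left-favouring twin. The 9-key
# response scale (1 = left ear ... 9 = right ear) therefore increases with
# the cue value.

#' Construct a lateralization cue
#'
#' @param kind One of `"itd"`, `"ild"`, `"diotic"`, `"mon_left"`,
#'   `"mon_right"`.
#' @param value Cue value: microseconds for ITD (protocol grid
#'   +/-200, 400, 600, 1500), dB for ILD (+/-4, 8, 12), 0 for diotic,
#'   `NA` for monaural cues.
#' @return A `lat_cue` object.
#' @export
lat_cue <- function(kind, value = NA_real_) {
  kind <- match.arg(kind, c("itd", "ild", "diotic", "mon_left", "mon_right"))
  if (kind == "itd") {
    grid <- c(protocol_constants$itd_grid_us, protocol_constants$itd_extreme_us)
    check_param(isTRUE(value %in% grid),
                "ITD value must lie on the protocol grid (+/-200,400,600,1500 us)")
  } else if (kind == "ild") {
    check_param(isTRUE(value %in% protocol_constants$ild_grid_db),
                "ILD value must lie on the protocol grid (+/-4,8,12 dB)")
  } else if (kind == "diotic") {
    value <- 0
  } else {
    value <- NA_real_
  }
  structure(list(kind = kind, value = value), class = "lat_cue")
}

#' Mirror a cue onto its left/right twin
#' @param cue A `lat_cue`.
#' @return The mirrored `lat_cue`.
#' @export
mirror_cue <- function(cue) {
  if (cue$kind %in% c("itd", "ild")) cue$value <- -cue$value
  if (cue$kind == "mon_left") cue$kind <- "mon_right"
  else if (cue$kind == "mon_right") cue$kind <- "mon_left"
  cue
}

#' Synthesise octave-band noise
#'
#' Gaussian white noise band-limited by an FFT brick-wall filter with
#' raised-cosine spectral edges of 5 Hz width. The band is octave wide with
#' arithmetic centre `center_hz`: lower edge `2*center/3`, upper edge
#' `4*center/3` (for 500 Hz: 333.3-666.7 Hz, bandwidth 333 Hz).
#'
#' @param center_hz Arithmetic band centre in Hz.
#' @param duration_s Duration in seconds.
#' @param fs Sample rate in Hz.
#' @param seed Integer seed; identical seeds give bit-identical buffers.
#' @return A 1-channel `audio_buffer` with unit RMS.
#' @export
synth_octave_noise <- function(center_hz, duration_s, fs = 48000, seed) {
  check_param(is.numeric(center_hz) && center_hz > 0,
              "center_hz must be positive")
  check_param(is.numeric(duration_s) && duration_s > 0,
              "duration_s must be positive")
  n <- round(duration_s * fs)
  x <- with_seed(seed, stats::rnorm(n))
  f_lo <- 2 * center_hz / 3
  f_hi <- 4 * center_hz / 3
  y <- band_limit(x, fs, f_lo, f_hi, edge_hz = 5)
  y <- y / sqrt(mean(y^2))
  audio_buffer(y, fs = fs)
}

#' Brick-wall band-pass in the frequency domain with raised-cosine edges
#' @noRd
band_limit <- function(x, fs, f_lo, f_hi, edge_hz = 5) {
  n <- length(x)
  f <- seq(0, n - 1) * fs / n
  f <- ifelse(f > fs / 2, fs - f, f)   # folded (absolute) frequency
  h <- numeric(n)
  h[f >= f_lo & f <= f_hi] <- 1
  lo_edge <- f > f_lo - edge_hz & f < f_lo
  h[lo_edge] <- 0.5 * (1 - cos(pi * (f[lo_edge] - (f_lo - edge_hz)) / edge_hz))
  hi_edge <- f > f_hi & f < f_hi + edge_hz
  h[hi_edge] <- 0.5 * (1 + cos(pi * (f[hi_edge] - f_hi) / edge_hz))
  Re(stats::fft(stats::fft(x) * h, inverse = TRUE)) / n
}

#' Apply onset/offset gating ramps
#'
#' Shapes the first and last `ramp_ms` of every channel with a
#' raised-cosine (Hann-flank) or cosine (quarter-sine) window; the interior
#' is untouched. Both window shapes start at exactly zero.
#'
#' @param buf An `audio_buffer`.
#' @param ramp_ms Ramp duration in milliseconds; 0 returns the input.
#' @param shape `"raised_cosine"` or `"cosine"`.
#' @return The gated `audio_buffer`.
#' @export
apply_gate <- function(buf, ramp_ms, shape = c("raised_cosine", "cosine")) {
  shape <- match.arg(shape)
  check_param(is.numeric(ramp_ms) && ramp_ms >= 0, "ramp_ms must be >= 0")
  if (ramp_ms == 0) return(buf)
  nr <- round(ramp_ms / 1000 * buf$fs)
  check_param(2 * nr <= n_samples(buf),
              "gating ramps must not exceed half the buffer duration")
  t <- seq(0, 1, length.out = nr + 1)[seq_len(nr)]  # starts at 0, ends < 1
  w <- switch(shape,
              raised_cosine = 0.5 * (1 - cos(pi * t)),
              cosine        = sin(pi / 2 * t))
  n <- n_samples(buf)
  buf$samples[seq_len(nr), ] <- buf$samples[seq_len(nr), , drop = FALSE] * w
  buf$samples[n - seq_len(nr) + 1, ] <-
    buf$samples[n - seq_len(nr) + 1, , drop = FALSE] * w
  buf
}

#' Fractional delay via a frequency-domain phase ramp with an edge guard
#' @noRd
fractional_delay <- function(x, delay_samples) {
  pad <- ceiling(abs(delay_samples)) + 64
  n <- length(x)
  xp <- c(numeric(pad), x, numeric(pad))
  m <- length(xp)
  k <- seq(0, m - 1)
  k <- ifelse(k > m / 2, k - m, k)      # signed frequency index
  phase <- exp(-2i * pi * k * delay_samples / m)
  if (m %% 2 == 0) phase[m / 2 + 1] <- Re(phase[m / 2 + 1])
  yp <- Re(stats::fft(stats::fft(xp) * phase, inverse = TRUE)) / m
  yp[pad + seq_len(n)]
}

#' Impose an interaural time difference
#'
#' Duplicates a mono buffer into two channels and delays the whole waveform
#' of each channel by half the ITD in opposite directions (symmetric-split
#' fractional delay realised as a frequency-domain phase ramp). Positive
#' `itd_us` makes the right channel lead. Because the delay acts on the
#' already-gated waveform, envelope and fine structure both carry the ITD.
#'
#' @param buf A 1-channel `audio_buffer`.
#' @param itd_us ITD in microseconds (positive = right leading).
#' @return A 2-channel `audio_buffer`.
#' @export
apply_itd <- function(buf, itd_us) {
  check_param(n_channels(buf) == 1, "apply_itd expects a 1-channel buffer")
  d <- itd_us * 1e-6 * buf$fs   # total interchannel lag in samples
  check_param(abs(d) < n_samples(buf), "ITD exceeds the buffer duration")
  x <- buf$samples[, 1]
  if (itd_us == 0) {
    buf$samples <- cbind(x, x, deparse.level = 0)
    return(buf)
  }
  left  <- fractional_delay(x, +d / 2)
  right <- fractional_delay(x, -d / 2)
  buf$samples <- cbind(left, right, deparse.level = 0)
  buf
}

#' Energy-preserving interaural level difference gains
#'
#' @param ild_db ILD in dB (positive = right louder).
#' @return Named vector `c(g_l, g_r)` with `g_l^2 + g_r^2 = 2`, so the
#'   two-channel energy equals that of the diotic presentation.
#' @export
ild_gains <- function(ild_db) {
  check_param(is.finite(ild_db), "ild_db must be finite")
  g_l <- sqrt(2 / (1 + 10^(ild_db / 10)))
  g_r <- g_l * 10^(ild_db / 20)
  c(g_l = g_l, g_r = g_r)
}

#' Impose an interaural level difference without changing overall energy
#'
#' Duplicates a mono buffer into two channels scaled by the constant-power
#' gain split of [ild_gains()]; a 2-channel input has its channels scaled in
#' place.
#'
#' @param buf A 1- or 2-channel `audio_buffer`.
#' @param ild_db ILD in dB (positive = right louder).
#' @return A 2-channel `audio_buffer`.
#' @export
apply_ild <- function(buf, ild_db) {
  g <- ild_gains(ild_db)
  if (n_channels(buf) == 1) {
    x <- buf$samples[, 1]
    buf$samples <- cbind(x * g[["g_l"]], x * g[["g_r"]], deparse.level = 0)
  } else {
    buf$samples[, 1] <- buf$samples[, 1] * g[["g_l"]]
    buf$samples[, 2] <- buf$samples[, 2] * g[["g_r"]]
  }
  buf
}

#' Build a lateralization trial stimulus
#'
#' One second of octave-band noise centred at 500 Hz, gated with 10-ms
#' cosine ramps, carrying the requested interaural cue and calibrated to
#' 70 dB SPL. Monaural cues place the calibrated signal in one ear and
#' silence in the other.
#'
#' @param cue A `lat_cue` on the protocol grid.
#' @param seed Integer seed for the noise token.
#' @param gate_after_itd If `TRUE`, gate after imposing the ITD instead of
#'   before (the default gates first, so the envelope carries the ITD).
#' @return A 2-channel `audio_buffer`.
#' @export
build_lat_stimulus <- function(cue, seed, gate_after_itd = FALSE) {
  check_param(inherits(cue, "lat_cue"), "cue must be a lat_cue")
  p <- protocol_constants
  noise <- synth_octave_noise(p$center_hz, p$lat_dur_s, p$fs, seed)
  gate <- function(b) apply_gate(b, p$lat_ramp_ms, "cosine")
  lvl <- p$lat_level_db_spl
  if (cue$kind == "itd") {
    if (gate_after_itd) {
      out <- gate(apply_itd(set_spl(noise, lvl), cue$value))
    } else {
      out <- apply_itd(set_spl(gate(noise), lvl), cue$value)
    }
  } else if (cue$kind == "ild") {
    out <- apply_ild(set_spl(gate(noise), lvl), cue$value)
  } else if (cue$kind == "diotic") {
    x <- set_spl(gate(noise), lvl)
    x$samples <- cbind(x$samples[, 1], x$samples[, 1], deparse.level = 0)
    out <- x
  } else {  # monaural
    x <- set_spl(gate(noise), lvl)
    z <- numeric(n_samples(x))
    out <- x
    out$samples <- if (cue$kind == "mon_left")
      cbind(x$samples[, 1], z, deparse.level = 0)
    else
      cbind(z, x$samples[, 1], deparse.level = 0)
  }
  out
}

#' Specify a tone-in-noise trial
#'
#' @param condition `"N0S0"` (tone interaurally in phase) or `"N0Spi"`
#'   (tone with interaural phase difference pi).
#' @param tone_level Tone level in dB SPL; `-Inf` omits the tone.
#' @param noise_level Noise level in dB SPL (60 in the protocol).
#' @param target_interval Which of the three intervals carries the tone.
#' @return A `tin_trial_spec` object.
#' @export
tin_trial_spec <- function(condition = c("N0S0", "N0Spi"), tone_level,
                           noise_level = 60, target_interval = 1) {
  condition <- match.arg(condition)
  check_param(target_interval %in% 1:3, "target_interval must be 1, 2 or 3")
  structure(list(condition = condition, tone_level = tone_level,
                 noise_level = noise_level,
                 target_interval = as.integer(target_interval)),
            class = "tin_trial_spec")
}

#' Build a three-interval tone-in-noise trial
#'
#' Three 500-ms bursts of diotic octave-band noise (fresh random tokens per
#' interval, 20-ms raised-cosine ramps, 60 dB SPL), separated by 300-ms
#' gaps. Exactly one interval additionally carries a 420-ms 500-Hz tone,
#' temporally centred (onset 40 ms after the noise onset), with the same
#' ramps. In N0Spi the left-channel tone is sign-inverted (interaural phase
#' difference pi); the noise is always interaurally in phase.
#'
#' @param spec A `tin_trial_spec`.
#' @param seed Integer seed for the three noise tokens.
#' @return A list with elements `intervals` (list of three 2-channel
#'   `audio_buffer`s), `target` (index of the tone interval) and `gap_ms`.
#' @export
build_tin_trial <- function(spec, seed) {
  check_param(inherits(spec, "tin_trial_spec"), "spec must be a tin_trial_spec")
  p <- protocol_constants
  seeds <- derive_seeds(seed, 3)
  n_noise <- round(p$tin_noise_dur_s * p$fs)
  n_tone <- round(p$tin_tone_dur_s * p$fs)
  onset <- round(p$tin_tone_onset_s * p$fs)

  tone <- numeric(0)
  if (is.finite(spec$tone_level)) {
    amp <- spl_to_sine_amp(spec$tone_level)
    tone <- amp * sin(2 * pi * p$center_hz * seq(0, n_tone - 1) / p$fs)
    tone_buf <- apply_gate(audio_buffer(tone, fs = p$fs), p$tin_ramp_ms,
                           "raised_cosine")
    tone <- tone_buf$samples[, 1]
  }

  intervals <- lapply(1:3, function(i) {
    nb <- synth_octave_noise(p$center_hz, p$tin_noise_dur_s, p$fs, seeds[i])
    nb <- apply_gate(set_spl(nb, spec$noise_level), p$tin_ramp_ms,
                     "raised_cosine")
    left <- right <- nb$samples[, 1]
    if (i == spec$target_interval && length(tone)) {
      idx <- onset + seq_len(n_tone)
      right[idx] <- right[idx] + tone
      left[idx] <- left[idx] + if (spec$condition == "N0Spi") -tone else tone
    }
    audio_buffer(cbind(left, right, deparse.level = 0), fs = p$fs,
                 level_ref = nb$level_ref)
  })
  list(intervals = intervals, target = spec$target_interval,
       gap_ms = p$tin_gap_ms)
}
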