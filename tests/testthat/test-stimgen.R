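# Stimulus synthesis: band limits, gating, interaural cues, calibration,
# and assembled trials.

test_that("octave-band noise is deterministic, unit-RMS, and band-limited", {
  b1 <- synth_octave_noise(500, 1, seed = 11)
  b2 <- synth_octave_noise(500, 1, seed = 11)
  expect_identical(b1$samples, b2$samples)
  b3 <- synth_octave_noise(500, 1, seed = 12)
  expect_false(identical(b1$samples, b3$samples))
  expect_equal(sqrt(mean(b1$samples^2)), 1, tolerance = 1e-12)

  # spectral integration oracle: power outside [0.9 f_lo, 1.1 f_hi] at
  # least 40 dB below in-band power for a 1-s token
  x <- b1$samples[, 1]
  n <- length(x)
  pw <- abs(stats::fft(x))^2
  f <- seq(0, n - 1) * b1$fs / n
  half <- f <= b1$fs / 2
  f <- f[half]; pw <- pw[half]
  f_lo <- 2 * 500 / 3; f_hi <- 4 * 500 / 3
  in_band <- sum(pw[f >= f_lo & f <= f_hi])
  out_band <- sum(pw[f < 0.9 * f_lo | f > 1.1 * f_hi])
  expect_gt(10 * log10(in_band / out_band), 40)

  expect_error(synth_octave_noise(500, -1, seed = 1), "positive")
  expect_error(synth_octave_noise(0, 1, seed = 1), "positive")
})

test_that("octave band spans 2/3 to 4/3 of the centre (333 Hz bandwidth)", {
  b <- synth_octave_noise(500, 2, seed = 21)
  x <- b$samples[, 1]
  n <- length(x)
  pw <- abs(stats::fft(x))^2
  f <- seq(0, n - 1) * b$fs / n
  half <- f <= b$fs / 2
  f <- f[half]; pw <- pw[half]
  cdf <- cumsum(pw) / sum(pw)
  lo_edge <- f[which(cdf >= 0.001)[1]]
  hi_edge <- f[which(cdf >= 0.999)[1]]
  expect_equal(lo_edge, 1000 / 3, tolerance = 0.02)
  expect_equal(hi_edge, 2000 / 3, tolerance = 0.02)
  expect_equal(hi_edge - lo_edge, 1000 / 3, tolerance = 0.05)
})

test_that("gating ramps shape only the edges and remove the analytic energy", {
  b <- synth_octave_noise(500, 0.5, seed = 31)
  expect_identical(apply_gate(b, 0)$samples, b$samples)

  g <- apply_gate(b, 20, "raised_cosine")
  expect_identical(g$samples[1, 1], 0)                      # window starts at 0
  nr <- round(0.020 * b$fs)
  interior <- (nr + 1):(n_samples(b) - nr)
  expect_identical(g$samples[interior, 1], b$samples[interior, 1])

  # closed-form window energy: mean of w^2 over a raised-cosine ramp is 3/8
  n <- n_samples(b)
  expected_ratio <- ((n - 2 * nr) + 2 * nr * 3 / 8) / n
  got_ratio <- sum(g$samples^2) / sum(b$samples^2)
  expect_lt(got_ratio, 1)
  # a single noise token fluctuates; the mean ratio over tokens matches the
  # closed form within 1%
  ratios <- vapply(1:8, function(s) {
    tok <- synth_octave_noise(500, 0.5, seed = 300 + s)
    gt <- apply_gate(tok, 20, "raised_cosine")
    sum(gt$samples^2) / sum(tok$samples^2)
  }, numeric(1))
  expect_equal(mean(ratios), expected_ratio, tolerance = 0.01)

  gc <- apply_gate(b, 10, "cosine")
  expect_identical(gc$samples[1, 1], 0)
  expect_error(apply_gate(b, 300), "half the buffer")
})

test_that("ITD is a symmetric fractional delay with the right lag and phase", {
  b <- apply_gate(synth_octave_noise(500, 1, seed = 41), 10, "cosine")

  z <- apply_itd(b, 0)
  expect_identical(z$samples[, 1], z$samples[, 2])

  # cross-correlation oracle with parabolic interpolation: +200 us at
  # 48 kHz must give an interchannel lag of 9.6 samples
  s <- apply_itd(b, 200)
  l <- s$samples[, 1]; r <- s$samples[, 2]
  lags <- -15:15
  cc <- vapply(lags, function(k) {
    if (k >= 0) sum(l[(1 + k):length(l)] * r[1:(length(r) - k)])
    else sum(l[1:(length(l) + k)] * r[(1 - k):length(r)])
  }, numeric(1))
  i <- which.max(cc)
  # parabolic interpolation around the peak
  num <- cc[i - 1] - cc[i + 1]
  den <- cc[i - 1] - 2 * cc[i] + cc[i + 1]
  lag <- lags[i] + 0.5 * num / den
  expect_equal(lag, 9.6, tolerance = 0.05)

  # FFT-phase oracle: interaural phase of the 500-Hz component equals
  # 2*pi*f*ITD, within 1 degree for 400 us
  s4 <- apply_itd(b, 400)
  bin <- 500 + 1  # 1-s token at integer frequencies
  ph <- function(ch) Arg(stats::fft(s4$samples[, ch])[bin])
  # right leads, so the right-channel phase leads the left by 2*pi*f*ITD
  dphi <- (ph(2) - ph(1)) %% (2 * pi)
  expect_equal(dphi * 180 / pi, 2 * pi * 500 * 400e-6 * 180 / pi,
               tolerance = 1)

  # channel-swap symmetry: swap o apply_itd(+x) = apply_itd(-x)
  plus <- apply_itd(b, 600)
  minus <- apply_itd(b, -600)
  expect_identical(swap_channels(plus)$samples, minus$samples)

  expect_error(apply_itd(b, 2e6), "exceeds")
})

test_that("ILD gains preserve two-channel energy and set the level ratio", {
  for (ild in c(-12, -8, -4, 0, 4, 8, 12)) {
    g <- ild_gains(ild)
    expect_equal(sum(g^2), 2, tolerance = 1e-12)
    expect_equal(20 * log10(g[["g_r"]] / g[["g_l"]]), ild, tolerance = 1e-9)
  }
  expect_identical(ild_gains(0), c(g_l = 1, g_r = 1))

  b <- apply_gate(synth_octave_noise(500, 1, seed = 51), 10, "cosine")
  s0 <- apply_ild(b, 0)
  expect_identical(s0$samples[, 1], s0$samples[, 2])
  s12 <- apply_ild(b, 12)
  rms <- function(x) sqrt(mean(x^2))
  expect_equal(rms(s12$samples[, 2]) / rms(s12$samples[, 1]), 10^(12 / 20),
               tolerance = 1e-6)
  # energy equals the diotic presentation
  expect_equal(sum(s12$samples^2), sum(s0$samples^2), tolerance = 1e-9)
  expect_error(ild_gains(Inf), "finite")
})

test_that("calibration round-trips within 0.01 dB", {
  b <- synth_octave_noise(500, 1, seed = 61)
  for (lvl in c(40, 60, 70, 80)) {
    expect_equal(buffer_spl(set_spl(b, lvl)), lvl, tolerance = 0.01)
  }
  # full-scale sine measures 100 dB SPL under the default calibration
  sine <- audio_buffer(sin(2 * pi * 500 * seq(0, 47999) / 48000))
  expect_equal(buffer_spl(sine), 100, tolerance = 0.01)
})

test_that("lateralization stimuli respect the cue, level and mirror rules", {
  d <- build_lat_stimulus(lat_cue("diotic"), seed = 71)
  expect_identical(d$samples[, 1], d$samples[, 2])
  expect_equal(buffer_spl(d), 70, tolerance = 0.01)
  expect_equal(n_samples(d), 48000)

  ml <- build_lat_stimulus(lat_cue("mon_left"), seed = 71)
  expect_true(all(ml$samples[, 2] == 0))
  expect_true(any(ml$samples[, 1] != 0))

  # mirrored ITD stimulus equals the channel-swapped opposite stimulus
  sp <- build_lat_stimulus(lat_cue("itd", 600), seed = 72)
  sm <- build_lat_stimulus(lat_cue("itd", -600), seed = 72)
  expect_identical(swap_channels(sp)$samples, sm$samples)

  expect_error(lat_cue("itd", 300), "grid")
  expect_error(lat_cue("ild", 5), "grid")
})

test_that("tone-in-noise trials place an antiphasic tone 40 ms into one interval", {
  spec <- tin_trial_spec("N0Spi", tone_level = 70, target_interval = 2)
  trial <- build_tin_trial(spec, seed = 81)
  expect_length(trial$intervals, 3)
  expect_identical(trial$target, 2L)

  # subtract the noise-only reconstruction built from the same seed
  noise_only <- build_tin_trial(tin_trial_spec("N0Spi", -Inf, target_interval = 2),
                                seed = 81)
  for (i in c(1, 3)) {
    expect_identical(trial$intervals[[i]]$samples,
                     noise_only$intervals[[i]]$samples)
  }
  diff2 <- trial$intervals[[2]]$samples - noise_only$intervals[[2]]$samples
  onset <- round(0.040 * 48000)
  expect_true(all(diff2[seq_len(onset), ] == 0))
  expect_gt(max(abs(diff2)), 0)
  expect_identical(which(diff2[, 2] != 0)[1] > onset, TRUE)
  # N0Spi: left tone component is the sign-inverted right component
  expect_equal(diff2[, 1], -diff2[, 2], tolerance = 1e-12)

  # N0S0 keeps the tone interaurally in phase
  t0 <- build_tin_trial(tin_trial_spec("N0S0", 70, target_interval = 1),
                        seed = 82)
  n0 <- build_tin_trial(tin_trial_spec("N0S0", -Inf, target_interval = 1),
                        seed = 82)
  d0 <- t0$intervals[[1]]$samples - n0$intervals[[1]]$samples
  expect_equal(d0[, 1], d0[, 2], tolerance = 1e-12)

  # fresh noise tokens per interval
  expect_false(identical(trial$intervals[[1]]$samples,
                         trial$intervals[[3]]$samples))
  # noise presented at 60 dB SPL
  expect_equal(buffer_spl(noise_only$intervals[[1]]), 60, tolerance = 0.1)
})
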