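# Virtual listeners: psychometric detection model, cue-to-key response
# model, archetypes, and session/cohort simulation.

test_that("detection probability has the right floor, midpoint and root", {
  p <- detection_listener_params(mu_n0s0 = 60, sigma_psy = 4, lapse = 0)
  expect_equal(detection_prob(p, -1e6, "N0S0"), 1 / 3, tolerance = 1e-12)
  expect_equal(detection_prob(p, 60, "N0S0"), 1 / 3 + (2 / 3) * 0.5,
               tolerance = 1e-12)
  # independent numeric root of P = 0.794 vs the closed form
  root <- stats::uniroot(function(l)
    detection_prob(p, l, "N0S0") - 0.5^(1 / 3), c(40, 90), tol = 1e-10)$root
  expect_equal(tracked_level(p, "N0S0"), root, tolerance = 1e-6)
  # binaural advantage shifts the N0Spi midpoint down
  p2 <- detection_listener_params(mu_n0s0 = 60, binaural_advantage = 13,
                                  sigma_psy = 4, lapse = 0)
  expect_equal(tracked_level(p2, "N0Spi"), tracked_level(p2, "N0S0") - 13)
  expect_error(detection_listener_params(lapse = 0.5), "lapse")
})

test_that("the cue-to-key mapping saturates, shifts and respects key sets", {
  quiet <- lateralization_listener_params(noise_sd = 0, confusion_prob = 0,
                                          gain_itd_left = 1, gain_itd_right = 1,
                                          gain_ild_left = 1, gain_ild_right = 1)
  expect_identical(respond_lateralization(quiet, lat_cue("ild", 12)), 9L)
  expect_identical(respond_lateralization(quiet, lat_cue("ild", -12)), 1L)
  expect_identical(respond_lateralization(quiet, lat_cue("diotic")), 5L)

  shifted <- lateralization_listener_params(bias = 0.25, noise_sd = 0,
                                            confusion_prob = 0)
  expect_identical(respond_lateralization(shifted, lat_cue("diotic")), 6L)

  # restricted key sets: responses stay within the allowed keys
  lr_only <- lateralization_listener_params(allowed_keys = c(1, 9))
  set.seed(5)
  keys <- replicate(50, respond_lateralization(lr_only, lat_cue("ild", 4)))
  expect_true(all(keys %in% c(1L, 9L)))

  # monaural extent
  mon <- lateralization_listener_params(noise_sd = 0, confusion_prob = 0,
                                        mon_extent = 0.9)
  expect_identical(respond_lateralization(mon, lat_cue("mon_right")), 9L)
  expect_identical(respond_lateralization(mon, lat_cue("mon_left")), 1L)

  expect_error(lateralization_listener_params(allowed_keys = integer(0)),
               "allowed_keys")
})

test_that("supra-physiological ITDs are heard at the 500-us extent on either side", {
  # ambiguity 0: always the leading side, at the aliased 500-us extent
  lead <- lateralization_listener_params(noise_sd = 0, confusion_prob = 0,
                                         ambiguity_weight = 0)
  k_lead <- respond_lateralization(lead, lat_cue("itd", 1500))
  expect_identical(k_lead,
                   as.integer(round(5 + 4 * 0.7 * 500 / 600)))
  # ambiguity 1: always the alias side
  alias <- lateralization_listener_params(noise_sd = 0, confusion_prob = 0,
                                          ambiguity_weight = 1)
  k_alias <- respond_lateralization(alias, lat_cue("itd", 1500))
  expect_identical(k_alias,
                   as.integer(round(5 - 4 * 0.7 * 500 / 600)))
})

test_that("a noise-free linear listener returns the configured gain exactly", {
  # gain 0.75 makes 5 + 4*g*s land on integer keys at every grid step
  g <- 0.75
  quiet <- lateralization_listener_params(noise_sd = 0, confusion_prob = 0,
                                          gain_itd_left = g, gain_itd_right = g,
                                          gain_ild_left = g, gain_ild_right = g)
  tbl <- make_full_table(function(type, value, r) {
    cue <- lat_cue(type, if (is.na(value)) NA_real_ else value)
    respond_lateralization(quiet, cue)
  })
  m <- compute_metrics(tbl)
  # slope in keys/step is 4*g/3; recover g from each fitted slope
  for (v in c("itd_l_slope", "itd_r_slope", "ild_l_slope", "ild_r_slope")) {
    expect_equal(3 * m[[v]] / 4, g, tolerance = 1e-12)
  }
})

test_that("mirrored listener parameters produce the mirrored responses", {
  set.seed(11)
  base <- lateralization_listener_params(
    bias = 0.18, gain_itd_left = 0.62, gain_itd_right = 0.81,
    gain_ild_left = 0.5, gain_ild_right = 0.38, noise_sd = 0,
    confusion_prob = 0, mon_extent = 0.85)
  mirrored <- base
  mirrored$bias <- -base$bias
  mirrored$gain_itd_left <- base$gain_itd_right
  mirrored$gain_itd_right <- base$gain_itd_left
  mirrored$gain_ild_left <- base$gain_ild_right
  mirrored$gain_ild_right <- base$gain_ild_left
  cues <- c(lapply(c(-600, -400, -200, 200, 400, 600),
                   function(v) lat_cue("itd", v)),
            lapply(c(-12, -8, -4, 4, 8, 12), function(v) lat_cue("ild", v)),
            list(lat_cue("diotic"), lat_cue("mon_left"), lat_cue("mon_right")))
  for (cue in cues) {
    k1 <- respond_lateralization(base, cue)
    k2 <- respond_lateralization(mirrored, mirror_cue(cue))
    expect_identical(k2, 10L - k1)
  }
})

test_that("a session runs the full protocol deterministically", {
  det <- detection_listener_params()
  lat <- lateralization_listener_params()
  s1 <- simulate_session(det, lat, seed = 99)
  s2 <- simulate_session(det, lat, seed = 99)
  expect_identical(s1$lateralization, s2$lateralization)
  expect_identical(s1$tin$bmld, s2$tin$bmld)
  expect_identical(s1$audiometry$pta3, s2$audiometry$pta3)

  # protocol arithmetic: 16 six-trial stimuli + 8 diotic = 104 trials
  lt <- s1$lateralization
  expect_equal(nrow(lt), 104)
  counts <- table(paste(lt$stimulus_type, lt$stimulus_value))
  expect_equal(unname(counts[["diotic 0"]]), 8)
  expect_true(all(counts[names(counts) != "diotic 0"] == 6))
  expect_equal(sum(lt$stimulus_type == "itd"), 8 * 6)
  expect_equal(sum(lt$stimulus_type == "ild"), 6 * 6)

  # ITD and ILD trials are interleaved in one shuffled sequence
  first_half_types <- unique(lt$stimulus_type[1:30])
  expect_true(all(c("itd", "ild") %in% first_half_types))

  # audiometry thresholds near the configured audiogram
  expect_lte(abs(s1$audiometry$pta3 - 10), 6)
})

test_that("a control-archetype session lands near the expected ITD mean", {
  # sampling-theory bound: ITD mean within 1.5 SE of the centre key 5
  m <- lapply(1:20, function(s) {
    ses <- simulate_session(detection_listener_params(),
                            lateralization_listener_params(), seed = 1000 + s,
                            tasks = "lateralization")
    compute_metrics(prepare_trials(ses$lateralization))
  })
  im <- vapply(m, `[[`, numeric(1), "itd_mean")
  se <- stats::sd(im) / sqrt(length(im))
  expect_lte(abs(mean(im) - 5), 3 * se + 0.1)
})

test_that("cohorts honour the roster and are reproducible", {
  spec <- cohort_spec(n_controls = 3,
                      roster = list(list(archetype = "shifted",
                                         group = "thal_l", n = 2)),
                      master_seed = 5, tasks = "lateralization")
  co <- simulate_cohort(spec)
  expect_length(co$sessions, 5)
  expect_equal(sum(co$covariates$group == "control"), 3)
  expect_equal(sum(co$covariates$group == "thal_l"), 2)

  co2 <- simulate_cohort(spec)
  expect_identical(co$sessions[["S1"]]$lateralization,
                   co2$sessions[["S1"]]$lateralization)

  # shifted archetype responds right of centre on diotic trials
  lt <- co$sessions[["S1"]]$lateralization
  expect_gt(mean(lt$response_key[lt$stimulus_type == "diotic"]), 5)

  # empty roster: controls only
  co0 <- simulate_cohort(cohort_spec(n_controls = 2, master_seed = 1,
                                     tasks = "lateralization"))
  expect_length(co0$sessions, 2)
  expect_true(all(co0$covariates$group == "control"))
  expect_error(cohort_spec(n_controls = 1), "at least 2")
})
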