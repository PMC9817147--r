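# Shared fixtures built in code: trial tables and an independent
# brute-force recomputation of the lateralization battery.

# Full-protocol trial table with one response row per (stimulus, repeat).
# `keyfun(type, value, rep)` supplies the response key.
make_full_table <- function(keyfun, id = "P1") {
  p <- binlat::protocol_constants
  stim <- rbind(
    data.frame(stimulus_type = "itd",
               stimulus_value = c(p$itd_grid_us, p$itd_extreme_us), n = 6),
    data.frame(stimulus_type = "ild", stimulus_value = p$ild_grid_db, n = 6),
    data.frame(stimulus_type = "mon_left", stimulus_value = NA_real_, n = 6),
    data.frame(stimulus_type = "mon_right", stimulus_value = NA_real_, n = 6),
    data.frame(stimulus_type = "diotic", stimulus_value = 0, n = 8))
  rows <- list()
  idx <- 0
  for (i in seq_len(nrow(stim))) {
    for (r in seq_len(stim$n[i])) {
      idx <- idx + 1
      rows[[idx]] <- data.frame(
        participant_id = id, task = "lateralization", trial_index = idx,
        stimulus_type = stim$stimulus_type[i],
        stimulus_value = stim$stimulus_value[i],
        response_key = keyfun(stim$stimulus_type[i], stim$stimulus_value[i], r))
    }
  }
  do.call(rbind, rows)
}

# Random full-protocol table (keys uniform on 1..9)
random_table <- function(seed, id = "P1") {
  set.seed(seed)
  make_full_table(function(type, value, r) sample(1:9, 1), id = id)
}

# A deterministic saturating linear listener: key = round(5 + 4 * g * s)
linear_keyfun <- function(gain_itd = 0.7, gain_ild = 0.45, bias = 0) {
  function(type, value, r) {
    s <- switch(type,
                itd = max(-1, min(1, value / 600)),
                ild = max(-1, min(1, value / 12)),
                diotic = 0, mon_left = -0.9, mon_right = 0.9)
    g <- switch(type, itd = gain_itd, ild = gain_ild, 1)
    x <- max(-1, min(1, bias + g * s))
    as.integer(round(5 + 4 * x))
  }
}

# Independent brute-force recomputation of the battery using plain loops
# and textbook formulas (kept deliberately separate from the package path).
naive_battery <- function(tbl) {
  nm <- function(x) if (length(x) == 0) NA_real_ else sum(x) / length(x)
  nsd <- function(x) {
    if (length(x) < 2) return(NA_real_)
    m <- sum(x) / length(x)
    sqrt(sum((x - m)^2) / (length(x) - 1))
  }
  pick <- function(type, value = NULL) {
    keep <- tbl$stimulus_type == type
    if (!is.null(value)) keep <- keep & tbl$stimulus_value %in% value
    tbl[keep, , drop = FALSE]
  }
  itd_grid <- c(-600, -400, -200, 200, 400, 600)
  ild_grid <- c(-12, -8, -4, 4, 8, 12)
  di <- pick("diotic")

  ols <- function(type, vals, step) {
    rows <- pick(type, vals)
    if (!all(vals %in% rows$stimulus_value))
      return(list(slope = NA_real_, fit = NA_real_))
    x <- rows$stimulus_value / step
    y <- rows$response_key
    xb <- sum(x) / length(x); yb <- sum(y) / length(y)
    b <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
    a <- yb - b * xb
    list(slope = b, fit = nm(a + b * unique(sort(x))))
  }
  lr <- function(a, b) if (is.na(a) || is.na(b) || a <= 0 || b <= 0)
    NA_real_ else log(a / b)

  stim_means <- function(type, vals) {
    out <- c()
    for (v in vals) {
      r <- pick(type, v)
      if (v == 0) r <- di
      if (nrow(r) > 0) out <- c(out, nm(r$response_key))
    }
    out
  }
  stim_sds <- function(type, vals) {
    out <- c()
    for (v in vals) {
      r <- if (v == 0) di else pick(type, v)
      if (nrow(r) > 0) out <- c(out, nsd(r$response_key))
    }
    out
  }

  b <- list()
  itd_all <- rbind(pick("itd", itd_grid), di)
  ild_all <- rbind(pick("ild", ild_grid), di)
  b$itd_mean <- nm(itd_all$response_key)
  b$ild_mean <- nm(ild_all$response_key)
  b$diotic_percept <- nm(di$response_key)
  b$diotic_std <- nsd(di$response_key)
  b$itd_center <- nm(itd_all$stimulus_value[itd_all$response_key == 5])
  b$ild_center <- nm(ild_all$stimulus_value[ild_all$response_key == 5])
  sds_itd <- stim_sds("itd", c(itd_grid, 0))
  sds_ild <- stim_sds("ild", c(ild_grid, 0))
  b$itd_std <- nm(sds_itd[!is.na(sds_itd)])
  b$ild_std <- nm(sds_ild[!is.na(sds_ild)])
  b$itd_l_std <- nm(stim_sds("itd", c(-600, -400, -200)))
  b$itd_r_std <- nm(stim_sds("itd", c(200, 400, 600)))
  b$ild_l_std <- nm(stim_sds("ild", c(-12, -8, -4)))
  b$ild_r_std <- nm(stim_sds("ild", c(4, 8, 12)))
  b$itd_std_ratio <- lr(b$itd_l_std, b$itd_r_std)
  b$ild_std_ratio <- lr(b$ild_l_std, b$ild_r_std)
  fl <- ols("itd", c(-600, -400, -200), 200)
  fr <- ols("itd", c(200, 400, 600), 200)
  gl <- ols("ild", c(-12, -8, -4), 4)
  gr <- ols("ild", c(4, 8, 12), 4)
  b$itd_l_slope <- fl$slope; b$itd_r_slope <- fr$slope
  b$ild_l_slope <- gl$slope; b$ild_r_slope <- gr$slope
  b$itd_l_fit <- fl$fit; b$itd_r_fit <- fr$fit
  b$ild_l_fit <- gl$fit; b$ild_r_fit <- gr$fit
  b$itd_slope_ratio <- lr(fl$slope, fr$slope)
  b$ild_slope_ratio <- lr(gl$slope, gr$slope)
  mi <- stim_means("itd", c(itd_grid, 0))
  ml <- stim_means("ild", c(ild_grid, 0))
  b$itd_range <- if (length(mi) < 2) NA_real_ else max(mi) - min(mi)
  b$ild_range <- if (length(ml) < 2) NA_real_ else max(ml) - min(ml)
  b$range_ratio <- if (is.na(b$ild_range) || is.na(b$itd_range) ||
                       b$ild_range <= 0 || b$itd_range <= 0) NA_real_
                   else log(b$ild_range / b$itd_range)
  b$mon_left <- nm(pick("mon_left")$response_key)
  b$mon_right <- nm(pick("mon_right")$response_key)
  b$neg_1500 <- nm(pick("itd", -1500)$response_key)
  b$pos_1500 <- nm(pick("itd", 1500)$response_key)
  b
}

# The 18-row worked table: three left-favouring ITD stimuli x 5 trials plus
# 3 diotic trials, with hand-computed battery values (see test-latmetrics).
worked_table <- function() {
  data.frame(
    participant_id = "W1", task = "lateralization",
    trial_index = 1:18,
    stimulus_type = c(rep("itd", 15), rep("diotic", 3)),
    stimulus_value = c(rep(-600, 5), rep(-400, 5), rep(-200, 5), rep(0, 3)),
    response_key = c(1L, 1L, 2L, 1L, 2L,
                     2L, 3L, 2L, 2L, 3L,
                     4L, 3L, 4L, 4L, 4L,
                     5L, 5L, 6L))
}
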