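# The lateralization variable battery: slopes, fits and means of the
# left-favouring and right-favouring stimuli, side biases, variability,
# lateralization ranges, and the monaural / supra-physiological-ITD
# percepts, computed from a prepared trial log. All position-valued
# variables are in response keys (1 = left ear, 5 = centre, 9 = right ear;
# one key is 1/8 of the interaural distance); ratio variables are natural
# logarithms.

LAT_BATTERY <- c(
  "itd_mean", "ild_mean", "itd_l_fit", "itd_r_fit", "ild_l_fit", "ild_r_fit",
  "itd_center", "ild_center", "diotic_percept",
  "diotic_std", "itd_std", "ild_std", "itd_l_std", "itd_r_std",
  "ild_l_std", "ild_r_std", "itd_std_ratio", "ild_std_ratio",
  "itd_l_slope", "itd_r_slope", "ild_l_slope", "ild_r_slope",
  "itd_slope_ratio", "ild_slope_ratio",
  "itd_range", "ild_range", "range_ratio",
  "mon_left", "mon_right", "neg_1500", "pos_1500")

#' Names of the lateralization battery variables
#' @return Character vector of the 31 variable names.
#' @export
battery_variables <- function() LAT_BATTERY

#' Stimulus grouping key used for per-stimulus operations
#' @noRd
stim_key <- function(tbl) {
  paste(tbl$stimulus_type, ifelse(is.na(tbl$stimulus_value), "",
                                  tbl$stimulus_value))
}

#' Discard the first trial of every stimulus
#'
#' Per stimulus (type and value), the trial with the smallest presentation
#' index is removed; a stimulus with a single trial is dropped entirely and
#' recorded in the `"dropped"` attribute. On the full protocol this leaves
#' 5 trials per non-diotic stimulus and 7 diotic trials.
#'
#' @param raw Trial-log data frame with columns `trial_index`,
#'   `stimulus_type`, `stimulus_value`, `response_key`.
#' @return The prepared table, with attribute `"dropped"` listing stimuli
#'   removed for having a single trial.
#' @export
prepare_trials <- function(raw) {
  if (nrow(raw) == 0) return(raw)
  key <- stim_key(raw)
  keep <- rep(TRUE, nrow(raw))
  dropped <- character(0)
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) == 1) {
      keep[idx] <- FALSE
      dropped <- c(dropped, k)
      warning("stimulus with a single trial dropped: ", k, call. = FALSE)
    } else {
      first <- idx[which.min(raw$trial_index[idx])]
      keep[first] <- FALSE
    }
  }
  out <- raw[keep, , drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

#' Linear fit to the three stimuli of one side
#'
#' Ordinary least squares of the response key on the cue value expressed in
#' protocol steps (4 dB per ILD step, 200 us per ITD step) over all
#' retained trials of the three left-favouring (steps -3, -2, -1) or
#' right-favouring (steps 1, 2, 3) stimuli. `fit_mean` is the mean of the
#' fitted values at the three stimulus positions (for equal trial counts
#' this equals the mean observed response).
#'
#' @param tbl Prepared trial-log data frame.
#' @param cue_kind `"itd"` or `"ild"`.
#' @param side `"left"` or `"right"`.
#' @return List with `slope` (keys per step) and `fit_mean` (keys); both
#'   `NA` when any of the three side stimuli has no retained trial.
#' @export
side_slope_fit <- function(tbl, cue_kind = c("itd", "ild"),
                           side = c("left", "right")) {
  cue_kind <- match.arg(cue_kind)
  side <- match.arg(side)
  p <- protocol_constants
  step <- if (cue_kind == "itd") p$itd_step_us else p$ild_step_db
  grid <- if (cue_kind == "itd") p$itd_grid_us else p$ild_grid_db
  vals <- if (side == "left") grid[grid < 0] else grid[grid > 0]
  rows <- tbl[tbl$stimulus_type == cue_kind &
                tbl$stimulus_value %in% vals, , drop = FALSE]
  if (!all(vals %in% rows$stimulus_value)) {
    return(list(slope = NA_real_, fit_mean = NA_real_))
  }
  x <- rows$stimulus_value / step
  y <- rows$response_key
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  list(slope = slope,
       fit_mean = mean(intercept + slope * (vals / step)))
}

#' Compute the lateralization variable battery
#'
#' Computes all battery variables (see [battery_variables()]) from a
#' prepared trial log. The ITD/ILD means, standard deviations and centres
#' are taken over the physiological cue grid including the diotic stimulus
#' and excluding the monaural and +/-1500-us stimuli (which have their own
#' dedicated variables); ranges are max minus min of the per-stimulus mean
#' responses over the same grids; centres are the mean cue value (native
#' units) over trials answered with key 5, with normalised-step variants
#' `itd_center_steps` / `ild_center_steps` also emitted. Ratio variables
#' are natural logs and are missing when a constituent is zero or negative.
#'
#' @param tbl Prepared trial-log data frame (see [prepare_trials()]).
#' @param include_extreme_in_mean If `TRUE`, the +/-1500-us trials also
#'   enter `itd_mean` and `itd_std`.
#' @param diotic_in_both If `FALSE`, diotic trials are excluded from the
#'   ITD/ILD aggregates and only feed the diotic variables.
#' @return One-row data frame of battery variables (plus the step-unit
#'   centre variants); missing values are `NA`.
#' @export
compute_metrics <- function(tbl, include_extreme_in_mean = FALSE,
                            diotic_in_both = TRUE) {
  p <- protocol_constants
  m <- as.list(rep(NA_real_, length(LAT_BATTERY)))
  names(m) <- LAT_BATTERY

  sel <- function(kind, vals = NULL) {
    r <- tbl[tbl$stimulus_type == kind, , drop = FALSE]
    if (!is.null(vals)) r <- r[r$stimulus_value %in% vals, , drop = FALSE]
    r
  }
  diotic <- sel("diotic")

  itd_grid_rows <- sel("itd", if (include_extreme_in_mean)
    c(p$itd_grid_us, p$itd_extreme_us) else p$itd_grid_us)
  ild_grid_rows <- sel("ild", p$ild_grid_db)
  if (diotic_in_both) {
    itd_all <- rbind(itd_grid_rows, diotic)
    ild_all <- rbind(ild_grid_rows, diotic)
  } else {
    itd_all <- itd_grid_rows
    ild_all <- ild_grid_rows
  }

  m$itd_mean <- mean_or_na(itd_all$response_key)
  m$ild_mean <- mean_or_na(ild_all$response_key)
  m$diotic_percept <- mean_or_na(diotic$response_key)
  m$diotic_std <- sd_or_na(diotic$response_key)

  # centres: mean cue value over key-5 trials of the physiological grid
  centre <- function(rows) {
    v <- rows$stimulus_value[rows$response_key == 5]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  m$itd_center <- centre(itd_all)
  m$ild_center <- centre(ild_all)

  # per-stimulus means and sds
  per_stim <- function(rows) {
    if (nrow(rows) == 0)
      return(data.frame(value = numeric(0), mean = numeric(0),
                        sd = numeric(0)))
    vals <- sort(unique(rows$stimulus_value))
    data.frame(value = vals,
               mean = vapply(vals, function(v)
                 mean(rows$response_key[rows$stimulus_value == v]),
                 numeric(1)),
               sd = vapply(vals, function(v)
                 sd_or_na(rows$response_key[rows$stimulus_value == v]),
                 numeric(1)))
  }
  itd_ps <- per_stim(itd_all)
  ild_ps <- per_stim(ild_all)
  m$itd_std <- mean_or_na(itd_ps$sd)
  m$ild_std <- mean_or_na(ild_ps$sd)

  side_std <- function(rows, vals) {
    ps <- per_stim(rows[rows$stimulus_value %in% vals, , drop = FALSE])
    if (nrow(ps) == 0) NA_real_ else mean_or_na(ps$sd)
  }
  m$itd_l_std <- side_std(itd_grid_rows, p$itd_grid_us[p$itd_grid_us < 0])
  m$itd_r_std <- side_std(itd_grid_rows, p$itd_grid_us[p$itd_grid_us > 0])
  m$ild_l_std <- side_std(ild_grid_rows, p$ild_grid_db[p$ild_grid_db < 0])
  m$ild_r_std <- side_std(ild_grid_rows, p$ild_grid_db[p$ild_grid_db > 0])

  log_ratio <- function(a, b) {
    if (is.na(a) || is.na(b) || a <= 0 || b <= 0) NA_real_ else log(a / b)
  }
  m$itd_std_ratio <- log_ratio(m$itd_l_std, m$itd_r_std)
  m$ild_std_ratio <- log_ratio(m$ild_l_std, m$ild_r_std)

  # slopes and fit means
  for (kind in c("itd", "ild")) for (sd_ in c("left", "right")) {
    f <- side_slope_fit(tbl, kind, sd_)
    m[[paste0(kind, "_", substr(sd_, 1, 1), "_slope")]] <- f$slope
    m[[paste0(kind, "_", substr(sd_, 1, 1), "_fit")]] <- f$fit_mean
  }
  m$itd_slope_ratio <- log_ratio(m$itd_l_slope, m$itd_r_slope)
  m$ild_slope_ratio <- log_ratio(m$ild_l_slope, m$ild_r_slope)

  # ranges from per-stimulus mean responses over the physiological grids
  range_of <- function(ps) {
    if (nrow(ps) < 2) NA_real_ else max(ps$mean) - min(ps$mean)
  }
  itd_range_ps <- per_stim(rbind(sel("itd", p$itd_grid_us), diotic))
  ild_range_ps <- per_stim(rbind(sel("ild", p$ild_grid_db), diotic))
  m$itd_range <- range_of(itd_range_ps)
  m$ild_range <- range_of(ild_range_ps)
  m$range_ratio <- log_ratio(m$ild_range, m$itd_range)

  m$mon_left <- mean_or_na(sel("mon_left")$response_key)
  m$mon_right <- mean_or_na(sel("mon_right")$response_key)
  m$neg_1500 <- mean_or_na(sel("itd", -1500)$response_key)
  m$pos_1500 <- mean_or_na(sel("itd", 1500)$response_key)

  out <- as.data.frame(m)
  out$itd_center_steps <- m$itd_center / p$itd_step_us
  out$ild_center_steps <- m$ild_center / p$ild_step_db
  out
}

#' Mirror a trial log left-right
#'
#' Response keys map to `10 - key`, ITD and ILD cue values are negated, and
#' the monaural sides are exchanged. Mirroring is an involution.
#'
#' @param tbl Trial-log data frame.
#' @return The mirrored table.
#' @export
mirror_table <- function(tbl) {
  tbl$response_key <- 10L - tbl$response_key
  flip <- tbl$stimulus_type %in% c("itd", "ild")
  tbl$stimulus_value[flip] <- -tbl$stimulus_value[flip]
  ml <- tbl$stimulus_type == "mon_left"
  mr <- tbl$stimulus_type == "mon_right"
  tbl$stimulus_type[ml] <- "mon_right"
  tbl$stimulus_type[mr] <- "mon_left"
  tbl
}

#' Mirror a row of battery metrics left-right
#'
#' The algebraic image of computing the battery on a mirrored trial log:
#' position variables reflect about key 5, side-specific variables swap
#' sides (fits also reflecting), centre and ratio variables negate, and
#' side-symmetric variables (ranges, pooled stds, range ratio, detection
#' thresholds) are unchanged.
#'
#' @param metrics One-row data frame as returned by [compute_metrics()]
#'   (threshold columns, when present, are left untouched).
#' @return The mirrored metrics row.
#' @export
mirror_metrics <- function(metrics) {
  m <- metrics
  refl <- function(v) 10 - v
  m$itd_mean <- refl(metrics$itd_mean)
  m$ild_mean <- refl(metrics$ild_mean)
  m$diotic_percept <- refl(metrics$diotic_percept)
  m$itd_l_fit <- refl(metrics$itd_r_fit)
  m$itd_r_fit <- refl(metrics$itd_l_fit)
  m$ild_l_fit <- refl(metrics$ild_r_fit)
  m$ild_r_fit <- refl(metrics$ild_l_fit)
  m$mon_left <- refl(metrics$mon_right)
  m$mon_right <- refl(metrics$mon_left)
  m$neg_1500 <- refl(metrics$pos_1500)
  m$pos_1500 <- refl(metrics$neg_1500)
  m$itd_center <- -metrics$itd_center
  m$ild_center <- -metrics$ild_center
  if ("itd_center_steps" %in% names(m)) {
    m$itd_center_steps <- -metrics$itd_center_steps
    m$ild_center_steps <- -metrics$ild_center_steps
  }
  m$itd_l_slope <- metrics$itd_r_slope
  m$itd_r_slope <- metrics$itd_l_slope
  m$ild_l_slope <- metrics$ild_r_slope
  m$ild_r_slope <- metrics$ild_l_slope
  m$itd_slope_ratio <- -metrics$itd_slope_ratio
  m$ild_slope_ratio <- -metrics$ild_slope_ratio
  m$itd_l_std <- metrics$itd_r_std
  m$itd_r_std <- metrics$itd_l_std
  m$ild_l_std <- metrics$ild_r_std
  m$ild_r_std <- metrics$ild_l_std
  m$itd_std_ratio <- -metrics$itd_std_ratio
  m$ild_std_ratio <- -metrics$ild_std_ratio
  m
}
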