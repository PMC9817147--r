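# Mirror-augmented normative bands, per-variable deviation flags, and the
# cluster / lesion-group divergence summaries.
#
# Bands are control mean +/- 1.5 SD, computed after pooling each control's
# metrics with the metrics of their left-right mirrored session. The band
# interval is read inclusively: values on the boundary are normal.

#' Default variable clusters
#'
#' Cluster A holds the detection-task variables (N0S0 threshold, best N0Spi
#' threshold, BMLD); clusters B-G partition the 31 lateralization battery
#' variables into side bias (B), variability (C), slopes (D), ranges (E),
#' monaural percepts (F) and supra-physiological ITD percepts (G).
#'
#' @return Named list mapping cluster letter to variable names.
#' @export
default_clusters <- function() {
  list(
    A = c("n0s0_threshold", "nspi_threshold", "bmld"),
    B = c("itd_mean", "ild_mean", "itd_l_fit", "itd_r_fit", "ild_l_fit",
          "ild_r_fit", "itd_center", "ild_center", "diotic_percept"),
    C = c("diotic_std", "itd_std", "ild_std", "itd_l_std", "itd_r_std",
          "ild_l_std", "ild_r_std", "itd_std_ratio", "ild_std_ratio"),
    D = c("itd_l_slope", "itd_r_slope", "ild_l_slope", "ild_r_slope",
          "itd_slope_ratio", "ild_slope_ratio"),
    E = c("itd_range", "ild_range", "range_ratio"),
    F = c("mon_left", "mon_right"),
    G = c("neg_1500", "pos_1500")
  )
}

#' All variables covered by the normative analysis
#' @noRd
norm_variables <- function(clusters = default_clusters()) {
  unname(unlist(clusters))
}

#' Extract the per-participant variable row (battery + detection thresholds)
#'
#' @param session A `session_data` (simulated or read from file).
#' @param metrics Optional precomputed battery row; computed from the
#'   session's trial log otherwise.
#' @return One-row data frame with battery variables plus `n0s0_threshold`,
#'   `nspi_threshold` (better of the two runs) and `bmld`.
#' @export
session_variables <- function(session, metrics = NULL) {
  if (is.null(metrics)) {
    metrics <- compute_metrics(prepare_trials(session$lateralization))
  }
  tin <- session$tin
  metrics$n0s0_threshold <- if (!is.null(tin) && tin$n0s0$valid)
    tin$n0s0$threshold else NA_real_
  nspi_thr <- if (!is.null(tin))
    vapply(tin$nspi, function(r) if (r$valid) r$threshold else NA_real_,
           numeric(1)) else NA_real_
  metrics$nspi_threshold <- if (all(is.na(nspi_thr))) NA_real_
    else min(nspi_thr, na.rm = TRUE)
  metrics$bmld <- if (!is.null(tin)) tin$bmld else NA_real_
  metrics
}

#' Mirror a variable row including the detection thresholds
#' @noRd
mirror_variables <- function(row) {
  out <- mirror_metrics(row)
  out  # thresholds are side-symmetric and pass through unchanged
}

#' Build mirror-augmented normative bands
#'
#' Per variable: mean and sample SD over the control values, optionally
#' pooled with the values of each control's left-right mirrored session
#' (2n values), and the normal range `mean +/- 1.5 SD`. Augmentation forces
#' the mean of sign-symmetric variables onto their symmetry point (key 5
#' for position variables, 0 for centre and log-ratio variables) and folds
#' each control's asymmetry into the SD.
#'
#' @param control_metrics Data frame of per-control variable rows (from
#'   [session_variables()]), one row per control.
#' @param augment_mirror Pool with mirrored rows (default `TRUE`).
#' @param n_sd Half-width of the normal range in SDs.
#' @param variables Variables to band; defaults to all battery and
#'   detection variables present.
#' @return A `normative_bands` data frame: `variable`, `mean`, `sd`, `lo`,
#'   `hi`, `n_controls`, `augmented`.
#' @export
build_bands <- function(control_metrics, augment_mirror = TRUE, n_sd = 1.5,
                        variables = NULL) {
  check_param(nrow(control_metrics) >= 2, "need at least 2 controls")
  if (is.null(variables)) {
    variables <- intersect(norm_variables(), names(control_metrics))
  }
  pooled <- control_metrics
  if (augment_mirror) {
    pooled <- rbind(control_metrics,
                    mirror_variables(control_metrics)[names(control_metrics)])
  }
  # With augmentation the pooled 2n values are not independent observations:
  # the divisor stays at 2(n - 1) so that augmenting a perfectly symmetric
  # cohort (whose mirrored rows duplicate the originals) leaves the SD
  # unchanged.
  band_sd <- function(x) {
    x <- x[!is.na(x)]
    n <- length(x)
    if (n < 2) return(NA_real_)
    df <- if (augment_mirror) max(1L, n - 2L) else n - 1L
    sqrt(sum((x - mean(x))^2) / df)
  }
  bands <- data.frame(
    variable = variables,
    mean = vapply(variables, function(v) mean_or_na(pooled[[v]]), numeric(1)),
    sd = vapply(variables, function(v) band_sd(pooled[[v]]), numeric(1)),
    row.names = NULL)
  bands$lo <- bands$mean - n_sd * bands$sd
  bands$hi <- bands$mean + n_sd * bands$sd
  bands$n_controls <- nrow(control_metrics)
  bands$augmented <- augment_mirror
  class(bands) <- c("normative_bands", class(bands))
  bands
}

#' Flag a participant's variables against normative bands
#'
#' Each variable is flagged `"low"` (below the band), `"high"` (above it),
#' `"normal"` (inside, boundaries inclusive) or `"missing"`. An invalid
#' tone-in-noise task marks all cluster-A variables missing.
#'
#' @param metrics One-row variable data frame for the participant.
#' @param bands A `normative_bands` data frame.
#' @param tin_valid `FALSE` when the participant's tone-in-noise task did
#'   not produce the thresholds (flags cluster A missing).
#' @param clusters Cluster definition (for locating cluster A).
#' @return Data frame `variable`, `value`, `flag`.
#' @export
flag_participant <- function(metrics, bands, tin_valid = TRUE,
                             clusters = default_clusters()) {
  vals <- vapply(bands$variable, function(v) {
    if (v %in% names(metrics)) as.numeric(metrics[[v]]) else NA_real_
  }, numeric(1))
  flag <- ifelse(is.na(vals), "missing",
          ifelse(vals < bands$lo, "low",
          ifelse(vals > bands$hi, "high", "normal")))
  if (!tin_valid) flag[bands$variable %in% clusters$A] <- "missing"
  data.frame(variable = bands$variable, value = vals, flag = flag,
             row.names = NULL)
}

#' Cluster-by-group divergence matrix
#'
#' For every (lesion group, cluster) cell: the percentage of deviant
#' (participant, variable) pairs, where deviant means flagged low or high.
#' Missing pairs are excluded from the denominator; a cell with no
#' non-missing pairs is `NA`.
#'
#' @param flags Named list of per-participant flag data frames (from
#'   [flag_participant()]).
#' @param groups Named character vector: participant id -> group label.
#' @param clusters Cluster definition, see [default_clusters()].
#' @return List with `percent` (group x cluster matrix), and `counts`
#'   (long data frame with deviant / normal / missing / total per cell).
#' @export
cluster_matrix <- function(flags, groups, clusters = default_clusters()) {
  check_param(all(names(flags) %in% names(groups)),
              "every participant must have a group label")
  glab <- unique(groups[names(flags)])
  rows <- list()
  for (g in glab) for (cl in names(clusters)) {
    ids <- names(flags)[groups[names(flags)] == g]
    fl <- unlist(lapply(ids, function(id) {
      f <- flags[[id]]
      f$flag[f$variable %in% clusters[[cl]]]
    }))
    n_dev <- sum(fl %in% c("low", "high"))
    n_norm <- sum(fl == "normal")
    n_miss <- sum(fl == "missing")
    rows[[length(rows) + 1]] <- data.frame(
      group = g, cluster = cl, deviant = n_dev, normal = n_norm,
      missing = n_miss, total = length(fl),
      percent = if (n_dev + n_norm > 0) 100 * n_dev / (n_dev + n_norm)
                else NA_real_)
  }
  counts <- do.call(rbind, rows)
  percent <- matrix(NA_real_, nrow = length(glab),
                    ncol = length(clusters),
                    dimnames = list(glab, names(clusters)))
  for (i in seq_len(nrow(counts))) {
    percent[counts$group[i], counts$cluster[i]] <- counts$percent[i]
  }
  list(percent = percent, counts = counts)
}

#' Pool left/right lesion-group labels to their base label
#' @noRd
pool_group <- function(g) sub("[ _](l|r|left|right)$", "", g)

#' Group summary measures
#'
#' Per pooled lesion group (left/right variants merged): (1) the percentage
#' of patients whose BMLD was flagged low or who could not complete the
#' tone-in-noise task (non-convergent tracks); (2) the per-patient
#' percentage of non-missing cluster B-G variables flagged low or high,
#' summarised as group mean and across-patient SD.
#'
#' @param flags Named list of per-participant flag data frames.
#' @param groups Named character vector: participant id -> group label.
#' @param nonconvergent Named logical vector: participant id -> `TRUE` when
#'   the tone-in-noise task produced no BMLD because tracks failed to
#'   converge.
#' @param clusters Cluster definition.
#' @return Data frame per pooled group: `group`, `n`,
#'   `bmld_deviant_percent`, `lat_divergence_mean`, `lat_divergence_sd`.
#' @export
summary_measures <- function(flags, groups, nonconvergent = NULL,
                             clusters = default_clusters()) {
  ids <- names(flags)
  if (is.null(nonconvergent)) {
    nonconvergent <- stats::setNames(rep(FALSE, length(ids)), ids)
  }
  bg_vars <- unlist(clusters[setdiff(names(clusters), "A")])
  per_patient <- vapply(ids, function(id) {
    f <- flags[[id]]
    f <- f[f$variable %in% bg_vars, ]
    n_ok <- sum(f$flag != "missing")
    if (n_ok == 0) NA_real_
    else 100 * sum(f$flag %in% c("low", "high")) / n_ok
  }, numeric(1))
  bmld_bad <- vapply(ids, function(id) {
    f <- flags[[id]]
    isTRUE(f$flag[f$variable == "bmld"] == "low") ||
      isTRUE(nonconvergent[[id]])
  }, logical(1))
  pooled <- pool_group(groups[ids])
  out <- lapply(unique(pooled), function(g) {
    sel <- pooled == g
    data.frame(group = g, n = sum(sel),
               bmld_deviant_percent = 100 * mean(bmld_bad[sel]),
               lat_divergence_mean = mean_or_na(per_patient[sel]),
               lat_divergence_sd = sd_or_na(per_patient[sel]))
  })
  do.call(rbind, out)
}
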