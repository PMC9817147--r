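# Trial-log and session file I/O, group-level statistics, and pipeline
# orchestration.
#
# Trial-log dialect: UTF-8 CSV with a header row and columns
# participant_id, task, trial_index, stimulus_type, stimulus_value,
# response_key; stimulus_value is in native units (microseconds for ITD,
# dB for ILD), empty for monaural stimuli. Extra columns are preserved.

TRIAL_COLUMNS <- c("participant_id", "task", "trial_index", "stimulus_type",
                   "stimulus_value", "response_key")
STIM_TYPES <- c("itd", "ild", "diotic", "mon_left", "mon_right")

#' Validate a trial-log table
#'
#' @param tbl Data frame to validate.
#' @return Data frame of problems (`row`, `message`); zero rows when valid.
#'   `row` refers to the data row (add 1 for the file line when the file
#'   has a header).
#' @export
validate_trials <- function(tbl) {
  problems <- list()
  add <- function(rows, msg) {
    for (r in rows) {
      problems[[length(problems) + 1]] <<- data.frame(row = r, message = msg)
    }
  }
  missing_cols <- setdiff(TRIAL_COLUMNS, names(tbl))
  if (length(missing_cols)) {
    add(0L, paste("missing columns:", paste(missing_cols, collapse = ", ")))
    return(do.call(rbind, problems))
  }
  bad_type <- which(!tbl$stimulus_type %in% STIM_TYPES)
  add(bad_type, "unknown stimulus_type")
  bad_key <- which(!(tbl$response_key %in% 1:9))
  add(bad_key, "response_key outside 1..9")
  grids <- list(
    itd = c(protocol_constants$itd_grid_us, protocol_constants$itd_extreme_us),
    ild = protocol_constants$ild_grid_db)
  for (kind in names(grids)) {
    rows <- which(tbl$stimulus_type == kind &
                    !(tbl$stimulus_value %in% grids[[kind]]))
    add(rows, paste(kind, "value off the protocol grid"))
  }
  if (length(problems)) do.call(rbind, problems)
  else data.frame(row = integer(0), message = character(0))
}

#' Read / write a trial-log CSV
#'
#' `read_trials` validates the file and fails with a message listing the
#' offending file lines; extra columns are preserved.
#'
#' @param path CSV path.
#' @return For `read_trials`, the trial-log data frame.
#' @export
read_trials <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  problems <- validate_trials(tbl)
  if (nrow(problems)) {
    stop("invalid trial log ", path, ":\n",
         paste(sprintf("  line %d: %s", problems$row + 1L, problems$message),
               collapse = "\n"), call. = FALSE)
  }
  tbl
}

#' @rdname read_trials
#' @param tbl Trial-log data frame.
#' @export
write_trials <- function(tbl, path) {
  utils::write.csv(tbl, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Serialise a track result to a plain list
#' @noRd
track_to_list <- function(r) {
  if (is.null(r)) return(NULL)
  list(threshold = r$threshold, valid = r$valid,
       reversal_levels = r$reversal_levels, cap_hits = r$cap_hits,
       trial_log = r$trial_log)
}

#' @noRd
track_from_list <- function(l) {
  if (is.null(l)) return(NULL)
  structure(list(threshold = null_na(l$threshold), valid = l$valid,
                 reversal_levels = as.numeric(unlist(l$reversal_levels)),
                 cap_hits = l$cap_hits,
                 trial_log = as.data.frame(l$trial_log)),
            class = "track_result")
}

null_na <- function(x) if (is.null(x)) NA_real_ else x

#' Read / write a complete session as JSON
#'
#' Lossless round trip of a `session_data` object (audiometry summary,
#' tone-in-noise track results, lateralization trial log, covariates).
#'
#' @param session A `session_data`.
#' @param path JSON path.
#' @return For `read_session`, the reconstructed `session_data`.
#' @export
write_session <- function(session, path) {
  s <- session
  out <- list(
    participant_id = s$participant_id, group = s$group, seed = s$seed,
    covariates = s$covariates,
    audiometry = if (!is.null(s$audiometry)) {
      list(thresholds = s$audiometry$thresholds,
           pta3_left = s$audiometry$pta3_left,
           pta3_right = s$audiometry$pta3_right,
           pta3 = s$audiometry$pta3, pta3_asym = s$audiometry$pta3_asym,
           excluded = s$audiometry$excluded, complete = s$audiometry$complete)
    },
    tin = if (!is.null(s$tin)) {
      nspi <- lapply(s$tin$nspi, track_to_list)
      names(nspi) <- paste0("run", seq_along(nspi))
      list(n0s0 = track_to_list(s$tin$n0s0), nspi = nspi,
           bmld = s$tin$bmld, reason = s$tin$reason)
    },
    lateralization = s$lateralization)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  aud <- NULL
  if (!is.null(l$audiometry)) {
    aud <- structure(list(
      thresholds = as.data.frame(l$audiometry$thresholds),
      pta3_left = l$audiometry$pta3_left,
      pta3_right = l$audiometry$pta3_right,
      pta3 = l$audiometry$pta3, pta3_asym = l$audiometry$pta3_asym,
      excluded = l$audiometry$excluded, complete = l$audiometry$complete),
      class = "audiometry_summary")
  }
  tin <- NULL
  if (!is.null(l$tin)) {
    tin <- list(n0s0 = track_from_list(l$tin$n0s0),
                nspi = unname(lapply(l$tin$nspi, track_from_list)),
                bmld = null_na(l$tin$bmld),
                reason = if (is.null(l$tin$reason)) NA_character_
                         else l$tin$reason)
  }
  lat <- if (!is.null(l$lateralization)) {
    d <- as.data.frame(l$lateralization)
    if (!"stimulus_value" %in% names(d)) d$stimulus_value <- NA_real_
    d$stimulus_value <- as.numeric(d$stimulus_value)
    d[TRIAL_COLUMNS]
  }
  structure(list(participant_id = l$participant_id, group = l$group,
                 audiometry = aud, tin = tin, lateralization = lat,
                 covariates = l$covariates, seed = l$seed),
            class = "session_data")
}

#' Group comparisons and rank correlations
#'
#' Two-sample pooled-variance t-tests (control minus stroke, df =
#' n1 + n2 - 2, listwise deletion per measure) for the general-assessment
#' measures, and Spearman rank correlations (tie-corrected rho, asymptotic
#' p-values) of age and PTA3 with the assessment scores.
#'
#' @param covariates Data frame with columns `group` (`"control"` vs other)
#'   and the measures `age`, `pta3`, `pta3_asym`, `moca`, `mwtb`, `bdi`,
#'   `nihss`.
#' @param measures Measures to compare between groups.
#' @return List with `t_tests` and `correlations` data frames.
#' @export
group_stats <- function(covariates,
                        measures = c("age", "pta3", "pta3_asym", "moca",
                                     "mwtb", "bdi")) {
  is_control <- covariates$group == "control"
  t_rows <- lapply(measures, function(m) {
    x <- covariates[[m]][is_control]
    y <- covariates[[m]][!is_control]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    n1 <- length(x); n2 <- length(y)
    if (n1 < 2 || n2 < 2 || (stats::var(x) == 0 && stats::var(y) == 0)) {
      return(data.frame(measure = m, mean_stroke = mean_or_na(y),
                        sd_stroke = sd_or_na(y),
                        mean_control = mean_or_na(x), sd_control = sd_or_na(x),
                        t = NA_real_, df = NA_real_, p = NA_real_))
    }
    tt <- stats::t.test(x, y, var.equal = TRUE)
    data.frame(measure = m, mean_stroke = mean(y), sd_stroke = stats::sd(y),
               mean_control = mean(x), sd_control = stats::sd(x),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  pairs <- rbind(
    data.frame(var1 = "age", var2 = "pta3"),
    expand.grid(var1 = c("age", "pta3"),
                var2 = c("moca", "bdi", "nihss", "mwtb"),
                stringsAsFactors = FALSE))
  cor_rows <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- covariates[[pairs$var1[i]]]
    y <- covariates[[pairs$var2[i]]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) {
      return(data.frame(var1 = pairs$var1[i], var2 = pairs$var2[i],
                        rho = NA_real_, p = NA_real_, n = sum(ok)))
    }
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman",
                                           exact = FALSE))
    data.frame(var1 = pairs$var1[i], var2 = pairs$var2[i],
               rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  })
  list(t_tests = do.call(rbind, t_rows),
       correlations = do.call(rbind, cor_rows))
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, computes the per-participant variable
#' battery, builds mirror-augmented normative bands from the controls,
#' flags every participant, aggregates the cluster-by-group divergence
#' matrix and the group summary measures, computes group statistics, and
#' writes all artifacts with a manifest. Deterministic given the seeds in
#' the configuration.
#'
#' @param config Either a `cohort_spec`, a path to a YAML cohort
#'   specification, or a list with elements `sessions_dir` (directory of
#'   session JSON files) and optionally `covariates_csv`.
#' @param out_dir Output directory (created if needed).
#' @param mirror Use mirror augmentation for the bands.
#' @param clusters Cluster definition.
#' @return Invisibly, a list with the in-memory results (`metrics`,
#'   `bands`, `flags`, `matrix`, `summary`, `stats`, `artifacts`).
#' @export
run_pipeline <- function(config, out_dir, mirror = TRUE,
                         clusters = default_clusters()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  covariates <- NULL
  if (is.character(config) && length(config) == 1) {
    config <- read_cohort_spec(config)
  }
  if (inherits(config, "cohort_spec")) {
    cohort <- simulate_cohort(config)
    sessions <- cohort$sessions
    covariates <- cohort$covariates
  } else {
    files <- list.files(config$sessions_dir, pattern = "\\.json$",
                        full.names = TRUE)
    sessions <- lapply(files, read_session)
    names(sessions) <- vapply(sessions, `[[`, "", "participant_id")
    if (!is.null(config$covariates_csv)) {
      covariates <- utils::read.csv(config$covariates_csv,
                                    stringsAsFactors = FALSE)
    }
  }
  message(sprintf("pipeline: %d sessions", length(sessions)))

  metrics <- list()
  failed <- character(0)
  for (id in names(sessions)) {
    m <- tryCatch(session_variables(sessions[[id]]),
                  error = function(e) {
                    warning("participant ", id, " failed: ",
                            conditionMessage(e), call. = FALSE)
                    NULL
                  })
    if (is.null(m)) failed <- c(failed, id) else metrics[[id]] <- m
  }
  metrics_df <- do.call(rbind, metrics)
  metrics_df <- cbind(participant_id = names(metrics),
                      group = vapply(names(metrics),
                                     function(id) sessions[[id]]$group, ""),
                      metrics_df)
  rownames(metrics_df) <- NULL

  is_control <- metrics_df$group == "control"
  bands <- build_bands(metrics_df[is_control, , drop = FALSE],
                       augment_mirror = mirror)

  flags <- list()
  nonconv <- logical(0)
  for (i in seq_len(nrow(metrics_df))) {
    id <- metrics_df$participant_id[i]
    tin <- sessions[[id]]$tin
    tin_valid <- !is.null(tin) && is.na(tin$reason)
    flags[[id]] <- flag_participant(metrics_df[i, , drop = FALSE], bands,
                                    tin_valid = tin_valid,
                                    clusters = clusters)
    nonconv[id] <- !is.null(tin) && !is.na(tin$reason)
  }
  n_tracks_invalid <- sum(nonconv)
  message(sprintf("pipeline: %d participants with non-convergent detection tracks",
                  n_tracks_invalid))

  groups <- stats::setNames(metrics_df$group, metrics_df$participant_id)
  patient_ids <- metrics_df$participant_id[!is_control]
  mat <- if (length(patient_ids))
    cluster_matrix(flags[patient_ids], groups, clusters) else NULL
  summ <- summary_measures(flags, groups, nonconvergent = nonconv,
                           clusters = clusters)
  stats_out <- if (!is.null(covariates)) group_stats(covariates) else NULL

  # artifacts
  paths <- list(
    metrics = file.path(out_dir, "metrics.csv"),
    norms = file.path(out_dir, "norms.json"),
    flags = file.path(out_dir, "flags.csv"),
    matrix = file.path(out_dir, "cluster_matrix.csv"),
    summary = file.path(out_dir, "summary.csv"),
    manifest = file.path(out_dir, "manifest.json"))
  utils::write.csv(metrics_df, paths$metrics, row.names = FALSE)
  jsonlite::write_json(bands, paths$norms, auto_unbox = TRUE, digits = NA,
                       na = "null")
  flags_long <- do.call(rbind, lapply(names(flags), function(id) {
    cbind(participant_id = id, flags[[id]])
  }))
  utils::write.csv(flags_long, paths$flags, row.names = FALSE)
  if (!is.null(mat)) {
    utils::write.csv(mat$counts, paths$matrix, row.names = FALSE)
  }
  utils::write.csv(summ, paths$summary, row.names = FALSE)
  if (!is.null(stats_out)) {
    paths$stats_t <- file.path(out_dir, "stats_t.csv")
    paths$stats_cor <- file.path(out_dir, "stats_cor.csv")
    utils::write.csv(stats_out$t_tests, paths$stats_t, row.names = FALSE)
    utils::write.csv(stats_out$correlations, paths$stats_cor,
                     row.names = FALSE)
  }
  cfg_file <- tempfile(fileext = ".json")
  cfg_repr <- if (inherits(config, "cohort_spec"))
    config[c("n_controls", "roster", "master_seed", "tasks")] else config
  jsonlite::write_json(cfg_repr, cfg_file, auto_unbox = TRUE, force = TRUE)
  manifest <- list(
    package = "binlat",
    package_version = as.character(utils::packageVersion("binlat")),
    config = cfg_repr,
    config_md5 = unname(tools::md5sum(cfg_file)),
    mirror_augmented = mirror,
    n_sessions = length(sessions),
    n_failed = length(failed),
    n_nonconvergent_tin = n_tracks_invalid)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  unlink(cfg_file)

  invisible(list(metrics = metrics_df, bands = bands, flags = flags,
                 matrix = mat, summary = summ, stats = stats_out,
                 failed = failed, artifacts = paths))
}
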