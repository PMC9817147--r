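# AudioBuffer: calibrated one- or two-channel sample stream.
#
# Calibration convention: a digital full-scale sine (peak amplitude 1.0)
# corresponds to 100 dB SPL. Its RMS is 1/sqrt(2), so the calibration
# constant stored in `level_ref` is 100 + 20*log10(sqrt(2)) dB SPL per unit
# RMS. Sound pressure level of a buffer is level_ref + 20*log10(RMS).

FS_SINE_DB_SPL <- 100
DEFAULT_LEVEL_REF <- FS_SINE_DB_SPL + 20 * log10(sqrt(2))

#' Construct an audio buffer
#'
#' A calibrated sample stream: one column per channel, a fixed sample rate,
#' and a calibration constant mapping unit RMS to dB SPL.
#'
#' @param samples Numeric vector (mono) or matrix with one column per channel.
#' @param fs Sample rate in Hz (48000 for all protocols here).
#' @param level_ref Calibration constant in dB SPL per unit RMS. The default
#'   equates a digital full-scale sine with 100 dB SPL.
#' @return An object of class `audio_buffer`.
#' @export
audio_buffer <- function(samples, fs = 48000, level_ref = DEFAULT_LEVEL_REF) {
  if (is.vector(samples)) samples <- matrix(as.numeric(samples), ncol = 1)
  check_param(is.matrix(samples) && ncol(samples) %in% c(1L, 2L),
              "samples must be a vector or a 1- or 2-column matrix")
  check_param(is.numeric(fs) && fs > 0, "fs must be a positive sample rate")
  structure(list(samples = samples, fs = fs, level_ref = level_ref),
            class = "audio_buffer")
}

#' @export
print.audio_buffer <- function(x, ...) {
  cat(sprintf("<audio_buffer: %d ch, %d samples (%.3f s) @ %g Hz, %.1f dB SPL>\n",
              n_channels(x), n_samples(x), n_samples(x) / x$fs, x$fs,
              buffer_spl(x)))
  invisible(x)
}

#' Number of samples per channel / number of channels
#' @param buf An `audio_buffer`.
#' @return Integer count.
#' @export
n_samples <- function(buf) nrow(buf$samples)

#' @rdname n_samples
#' @export
n_channels <- function(buf) ncol(buf$samples)

#' Measure the sound pressure level of a buffer
#'
#' For multi-channel buffers the level is computed from the mean of the
#' per-channel mean-square amplitudes, so a diotic buffer measures the same
#' level as either of its channels and an energy-preserving ILD leaves the
#' measured level unchanged.
#'
#' @param buf An `audio_buffer`.
#' @param channel Optional channel index; default combines channels.
#' @return Level in dB SPL.
#' @export
buffer_spl <- function(buf, channel = NULL) {
  s <- if (is.null(channel)) buf$samples else buf$samples[, channel, drop = FALSE]
  ms <- mean(colMeans(s^2))
  buf$level_ref + 10 * log10(ms)
}

#' Scale a buffer to a nominal sound pressure level
#'
#' All channels are scaled by a common factor so that [buffer_spl()] of the
#' result equals `target_db_spl`.
#'
#' @param buf An `audio_buffer`.
#' @param target_db_spl Target level in dB SPL.
#' @return A calibrated `audio_buffer`.
#' @export
set_spl <- function(buf, target_db_spl) {
  cur <- buffer_spl(buf)
  check_param(is.finite(cur), "cannot calibrate an all-zero buffer")
  buf$samples <- buf$samples * 10^((target_db_spl - cur) / 20)
  buf
}

#' Peak amplitude for a sine of given SPL under the buffer calibration
#' @noRd
spl_to_sine_amp <- function(db_spl, level_ref = DEFAULT_LEVEL_REF) {
  sqrt(2) * 10^((db_spl - level_ref) / 20)
}

#' Swap the channels of a two-channel buffer
#' @param buf A 2-channel `audio_buffer`.
#' @return The buffer with left and right channels exchanged.
#' @export
swap_channels <- function(buf) {
  check_param(n_channels(buf) == 2, "swap_channels needs a 2-channel buffer")
  buf$samples <- buf$samples[, 2:1]
  buf
}

#' Export a buffer and sidecar metadata
#'
#' Writes the samples as plain text (one row per frame) together with a JSON
#' sidecar recording the calibration constant and any protocol metadata.
#' Intended for archiving stimuli, not for playback.
#'
#' @param buf An `audio_buffer`.
#' @param path Output path for the sample text file; the sidecar is written
#'   to `paste0(path, ".json")`.
#' @param meta Named list of additional metadata (cue, seed, protocol).
#' @return Invisibly, the sidecar path.
#' @export
write_buffer <- function(buf, path, meta = list()) {
  utils::write.table(buf$samples, path, row.names = FALSE, col.names = FALSE)
  side <- c(list(fs = buf$fs, n_channels = n_channels(buf),
                 level_ref_db_spl = buf$level_ref), meta)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(side, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}
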