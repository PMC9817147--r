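# Internal helpers shared across modules.

#' Evaluate code with a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stream of child seeds from a master seed, all below 2^31
#' @noRd
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Clip to an interval
#' @noRd
clip <- function(x, lo = -1, hi = 1) pmin(pmax(x, lo), hi)

#' Stop with a parameter error unless a condition holds
#' @noRd
check_param <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

#' Sample standard deviation that returns NA for length < 2
#' @noRd
sd_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) NA_real_ else stats::sd(x)
}

#' Mean returning NA for empty input
#' @noRd
mean_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA_real_ else mean(x)
}
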