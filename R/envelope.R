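#' Analytic signal via the FFT
#'
#' One-sided spectrum construction: positive frequencies doubled, negative
#' frequencies zeroed, DC (and Nyquist for even lengths) kept, inverse
#' transformed. The modulus of the result is the instantaneous amplitude.
#'
#' @param x real numeric vector.
#' @return complex vector of the same length.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Temporal energy envelope of a clip
#'
#' Amplitude of the analytic signal (Hilbert-transform magnitude), smoothed
#' with a causal third-order Butterworth low-pass filter with a 5 Hz cutoff;
#' negative post-filter values are clipped to zero.
#'
#' @param clip an `audio_clip` (or a list with `samples` and `sample_rate`).
#' @return object of class `temporal_envelope`: `times` (s), `values`
#'   (amplitude, >= 0), `sample_rate`.
#' @export
temporal_envelope <- function(clip) {
  x <- clip$samples
  fs <- clip$sample_rate
  stopifnot(length(x) > 0, fs > 0)
  amp <- Mod(analytic_signal(x))
  b <- signal::butter(3, 5 / (fs / 2), type = "low")
  env <- as.numeric(signal::filter(b, amp))
  env[env < 0] <- 0
  structure(list(times = (seq_along(x) - 1) / fs, values = env,
                 sample_rate = fs),
            class = "temporal_envelope")
}

#' Attack-segment detection by the weakest-effort method
#'
#' Thresholds at fixed fractions (default 10%..90% in 10% steps) of the
#' envelope maximum; the first crossing time of each threshold is found, the
#' "efforts" are the intervals between successive crossing times, and the
#' attack is bounded by the crossings whose efforts fall at or below
#' `effort_mult` times the mean effort. If the envelope is pathological
#' (degenerate crossings), the 10%/90% direct crossings are used and the
#' result flagged.
#'
#' @param env a [temporal_envelope()].
#' @param thresholds increasing fractions of the envelope maximum.
#' @param effort_mult effort cutoff as a multiple of the mean effort.
#' @return object of class `attack_segment`: `t_start`, `t_end` (s),
#'   `crossings`, `fallback` flag.
#' @export
detect_attack <- function(env, thresholds = seq(0.1, 0.9, by = 0.1),
                          effort_mult = 3) {
  v <- env$values
  m <- max(v)
  if (m <= 0) stop("envelope maximum must be positive")
  dt <- 1 / env$sample_rate
  cross_idx <- vapply(thresholds, function(th) {
    which(v >= th * m)[1]
  }, integer(1))
  cross_t <- env$times[cross_idx]
  efforts <- diff(cross_t)
  fallback <- FALSE
  if (any(is.na(cross_t)) || all(efforts == 0)) {
    fallback <- TRUE
    t_start <- env$times[which(v >= 0.1 * m)[1]]
    t_end <- env$times[which(v >= 0.9 * m)[1]]
  } else {
    ok <- efforts <= effort_mult * mean(efforts)
    i1 <- which(ok)[1]
    i2 <- max(which(ok))
    t_start <- cross_t[i1]
    t_end <- cross_t[i2 + 1]
  }
  if (t_end <= t_start) t_end <- t_start + dt
  structure(list(t_start = t_start, t_end = t_end,
                 crossings = cross_t, fallback = fallback),
            class = "attack_segment")
}

#' Temporal-envelope scalar descriptors
#'
#' Log-attack time is `log10(t_end - t_start)`; attack slope is the mean of
#' the local envelope slopes over the attack segment; the temporal centroid
#' is the center of gravity of the whole envelope,
#' `sum(t * e(t)) / sum(e(t))`.
#'
#' @param env a [temporal_envelope()].
#' @param seg an [detect_attack()] segment.
#' @return named numeric vector: `log_attack_time` (log10 s), `attack_slope`
#'   (1/s), `temp_centroid` (s).
#' @export
temporal_scalars <- function(env, seg) {
  dur <- seg$t_end - seg$t_start
  if (dur <= 0) stop("attack segment has non-positive duration")
  idx <- which(env$times >= seg$t_start & env$times <= seg$t_end)
  if (length(idx) < 2) idx <- c(idx, max(idx) + 1)
  dt <- 1 / env$sample_rate
  slope <- mean(diff(env$values[idx]) / dt)
  tc <- sum(env$times * env$values) / sum(env$values)
  c(log_attack_time = log10(dur), attack_slope = slope, temp_centroid = tc)
}
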