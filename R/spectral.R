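#' ERB-rate frequency scale
#'
#' Glasberg-Moore map from frequency in Hz to ERB-rate (number of equivalent
#' rectangular bandwidths below f): `21.4 * log10(4.37 * f / 1000 + 1)`.
#' Strictly increasing with `erb_rate(0) == 0`.
#'
#' @param f frequency in Hz (>= 0), vectorized.
#' @return ERB-rate units.
#' @export
erb_rate <- function(f) {
  if (any(f < 0)) stop("frequency must be non-negative")
  21.4 * log10(4.37 * f / 1000 + 1)
}

#' Short-time magnitude spectrogram on an ERB-rate axis
#'
#' STFT with a Hamming window of 23.2 ms and a hop of 5.8 ms (1024 / 256
#' samples at 44.1 kHz, rounded to the nearest sample at other rates),
#' frames fully contained in the clip (no padding). Bin centers are carried
#' on both the Hz and ERB-rate axes; frames whose peak magnitude falls below
#' `silence_db` relative to the loudest frame are flagged silent and are
#' excluded from descriptor time series downstream.
#'
#' @param clip an `audio_clip`.
#' @param window_s,hop_s window and hop in seconds.
#' @param silence_db silence floor in dB relative to the clipwise maximum.
#' @return object of class `erb_spectrogram`: `frame_times`, `bin_freqs_hz`,
#'   `bin_freqs_erb`, `magnitudes` (frames x bins), `silent` (logical).
#' @export
erb_spectrogram <- function(clip, window_s = 0.0232, hop_s = 0.0058,
                            silence_db = -60) {
  x <- clip$samples
  fs <- clip$sample_rate
  win <- 2L * round(window_s * fs / 2)   # nearest even sample count (1024)
  hop <- round(hop_s * fs)
  if (length(x) < win) stop("clip shorter than one analysis window")
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(win - 1)) / (win - 1))
  starts <- seq(1, length(x) - win + 1, by = hop)
  nbins <- win %/% 2 + 1
  mags <- matrix(0, length(starts), nbins)
  for (i in seq_along(starts)) {
    fr <- x[starts[i]:(starts[i] + win - 1)] * w
    mags[i, ] <- Mod(stats::fft(fr))[seq_len(nbins)]
  }
  peaks <- apply(mags, 1, max)
  silent <- peaks < max(peaks) * 10^(silence_db / 20)
  freqs <- (seq_len(nbins) - 1) * fs / win
  structure(list(frame_times = (starts - 1 + (win - 1) / 2) / fs,
                 bin_freqs_hz = freqs, bin_freqs_erb = erb_rate(freqs),
                 magnitudes = mags, silent = silent),
            class = "erb_spectrogram")
}

#' Spectral moments of one magnitude frame
#'
#' With normalized magnitudes `p_k = a_k / sum(a)` on the ERB-rate axis:
#' centroid (first moment), spread (square root of the second central
#' moment), skewness (third standardized moment) and kurtosis (fourth
#' standardized moment). Gain invariant. A single active bin gives spread 0
#' and, by convention, skewness and kurtosis 0 (flagged via attribute
#' `degenerate`).
#'
#' @param mag non-negative magnitudes, at least one positive.
#' @param freqs bin positions (ERB-rate units).
#' @return named vector: `centroid`, `spread`, `skewness`, `kurtosis`.
#' @export
spectral_moments <- function(mag, freqs) {
  s <- sum(mag)
  if (s <= 0) stop("frame has zero total magnitude")
  p <- mag / s
  mu <- sum(p * freqs)
  sigma <- sqrt(sum(p * (freqs - mu)^2))
  if (sigma == 0) {
    out <- c(centroid = mu, spread = 0, skewness = 0, kurtosis = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  c(centroid = mu, spread = sigma,
    skewness = sum(p * (freqs - mu)^3) / sigma^3,
    kurtosis = sum(p * (freqs - mu)^4) / sigma^4)
}

#' Spectral shape descriptors of one magnitude frame
#'
#' Slope: least-squares slope of the sum-normalized magnitudes against bin
#' position (normalization makes the slope gain invariant). Decrease:
#' amplitude-weighted average of the slopes from the first bin to each
#' subsequent bin, `sum((a_k - a_1)/(k - 1)) / sum(a_k)` over `k >= 2`.
#' Rolloff: the lowest bin position below which 95% of the squared-magnitude
#' energy is contained. Flatness: geometric over arithmetic mean of the
#' magnitudes (0 if any bin is exactly zero). Crest: maximum over arithmetic
#' mean.
#'
#' @param mag non-negative magnitudes, at least one positive.
#' @param freqs bin positions (ERB-rate units).
#' @return named vector: `slope`, `decrease`, `rolloff`, `flatness`,
#'   `crest`.
#' @export
spectral_shape <- function(mag, freqs) {
  s <- sum(mag)
  if (s <= 0) stop("frame has zero total magnitude")
  k <- length(mag)
  if (k == 1) {
    out <- c(slope = 0, decrease = 0, rolloff = freqs[1], flatness = 1,
             crest = 1)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  slope <- stats::cov(freqs, mag / s) / stats::var(freqs)
  dk <- 2:k
  denom <- sum(mag[dk])
  decrease <- if (denom > 0) sum((mag[dk] - mag[1]) / (dk - 1)) / denom else 0
  e <- mag^2
  rolloff <- freqs[which(cumsum(e) >= 0.95 * sum(e))[1]]
  gm <- if (any(mag == 0)) 0 else exp(mean(log(mag)))
  c(slope = slope, decrease = decrease, rolloff = rolloff,
    flatness = gm / mean(mag), crest = max(mag) / mean(mag))
}

#' Spectral variation between successive frames
#'
#' One minus the normalized correlation (cosine similarity) of two magnitude
#' frames: 0 for identical or proportionally scaled frames, 1 for frames
#' with disjoint support.
#'
#' @param a,b non-negative magnitude vectors of equal length.
#' @return unitless value in \[0, 1\].
#' @export
spectral_variation <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("silent frame passed to spectral_variation")
  1 - sum(a * b) / (na * nb)
}

#' Median and interquartile range of a descriptor time series
#'
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7), the package-wide percentile convention.
#'
#' @param series numeric vector over retained (non-silent) frames.
#' @return named vector: `med`, `iqr`.
#' @export
summarize_series <- function(series) {
  if (length(series) == 0) stop("empty descriptor series")
  q <- stats::quantile(series, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(med = q[2], iqr = q[3] - q[1])
}
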