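# Canonical descriptor naming: 10 spectral/spectrotemporal time series
# (median + IQR each) plus 3 temporal scalars = 23 columns.

spectral_series_names <- c("centroid", "spread", "skewness", "kurtosis",
                           "slope", "decrease", "rolloff", "variation",
                           "flatness", "crest")

#' Canonical names of the 23 descriptors
#'
#' @return character vector of length 23, in canonical order.
#' @export
descriptor_names <- function() {
  c(as.vector(t(outer(paste0("spec_", spectral_series_names),
                      c("_med", "_iqr"), paste0))),
    "log_attack_time", "attack_slope", "temp_centroid")
}

#' Extract the 23 timbre descriptors from one clip
#'
#' Runs the three-stage computation: (1) input representations — the
#' Butterworth-smoothed Hilbert amplitude envelope and the ERB-rate STFT;
#' (2) frame-level spectral moments/shape, inter-frame spectral variation,
#' and the weakest-effort attack descriptors; (3) median and IQR summaries
#' of each spectral time series over the non-silent frames. The spectral
#' centroid median is reported as its log10 (the scale on which it enters
#' the models); attack time is reported as log10 seconds.
#'
#' @param clip an `audio_clip`.
#' @return named numeric vector of length 23 (see [descriptor_names()]).
#' @export
extract_descriptors <- function(clip) {
  if (all(clip$samples == 0)) stop("cannot extract descriptors from silence")
  env <- temporal_envelope(clip)
  seg <- detect_attack(env)
  temporal <- temporal_scalars(env, seg)

  sp <- erb_spectrogram(clip)
  keep <- which(!sp$silent)
  if (length(keep) == 0) stop("all frames below the silence floor")
  freqs <- sp$bin_freqs_erb

  frame_vals <- matrix(NA_real_, length(keep), 9,
                       dimnames = list(NULL, c("centroid", "spread",
                                               "skewness", "kurtosis",
                                               "slope", "decrease",
                                               "rolloff", "flatness",
                                               "crest")))
  for (j in seq_along(keep)) {
    m <- sp$magnitudes[keep[j], ]
    frame_vals[j, 1:4] <- spectral_moments(m, freqs)
    sh <- spectral_shape(m, freqs)
    frame_vals[j, 5:7] <- sh[c("slope", "decrease", "rolloff")]
    frame_vals[j, 8:9] <- sh[c("flatness", "crest")]
  }
  # variation over successive retained frame pairs that are adjacent in time
  adjacent <- which(diff(keep) == 1)
  variation <- vapply(adjacent, function(i) {
    spectral_variation(sp$magnitudes[keep[i], ], sp$magnitudes[keep[i] + 1, ])
  }, numeric(1))
  if (length(variation) == 0) variation <- 0

  out <- numeric(0)
  for (nm in spectral_series_names) {
    series <- if (nm == "variation") variation else frame_vals[, nm]
    s <- summarize_series(series)
    if (nm == "centroid") s["med"] <- log10(s["med"])
    out <- c(out, stats::setNames(s, paste0("spec_", nm, c("_med", "_iqr"))))
  }
  c(out, temporal)
}

#' Extract descriptors for a whole stimulus set
#'
#' @param clips named list of `audio_clip` objects (names = stimulus ids).
#' @return data frame: `stimulus_id` plus the 23 descriptor columns.
#' @export
extract_descriptor_matrix <- function(clips) {
  vals <- t(vapply(clips, extract_descriptors, numeric(23)))
  out <- data.frame(stimulus_id = names(clips), vals,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}
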