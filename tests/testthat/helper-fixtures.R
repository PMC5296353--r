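# Shared fixture builders. Everything is generated in code at test time.

# a bare audio_clip from a sample vector
as_clip <- function(samples, sample_rate = 44100L) {
  structure(list(samples = samples, sample_rate = sample_rate),
            class = "audio_clip")
}

sine_clip <- function(freq = 440, amp = 1, duration = 0.5,
                      sample_rate = 44100L) {
  t <- (seq_len(round(duration * sample_rate)) - 1) / sample_rate
  as_clip(amp * sin(2 * pi * freq * t), sample_rate)
}

# an envelope object built directly from values (bypasses filtering)
as_envelope <- function(values, sample_rate = 1000L) {
  structure(list(times = (seq_along(values) - 1) / sample_rate,
                 values = values, sample_rate = sample_rate),
            class = "temporal_envelope")
}

# small multivariate-normal descriptor table with a planted correlation
# structure: six columns duplicated (plus small noise) from six originals
planted_collinear_matrix <- function(n = 200, seed = 42) {
  with_seed_local(seed, {
    base <- matrix(rnorm(n * 17), n, 17)
    colnames(base) <- setdiff(descriptor_names(),
                              c("spec_slope_med", "spec_slope_iqr",
                                "spec_spread_med", "spec_rolloff_med",
                                "spec_kurtosis_med", "spec_kurtosis_iqr"))
    dup <- cbind(
      spec_slope_med = base[, "spec_centroid_med"] + rnorm(n, 0, 0.15),
      spec_slope_iqr = base[, "spec_centroid_iqr"] + rnorm(n, 0, 0.15),
      spec_spread_med = base[, "spec_centroid_med"] + rnorm(n, 0, 0.15),
      spec_rolloff_med = base[, "spec_centroid_med"] + rnorm(n, 0, 0.15),
      spec_kurtosis_med = base[, "spec_skewness_med"] + rnorm(n, 0, 0.15),
      spec_kurtosis_iqr = base[, "spec_skewness_iqr"] + rnorm(n, 0, 0.15)
    )
    as.data.frame(cbind(base, dup))[descriptor_names()]
  })
}

# run code under a local seed without touching the session RNG
with_seed_local <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# shared small synthetic stimulus set + descriptors for model-level tests
# (cached across test files; built once per session)
tiny_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- default_stimulus_config()
      # 42-stimulus subset spanning families and octaves (42 = 5*8 + 2)
      idx <- seq(1, 137, length.out = 42)
      set <- generate_stimulus_set(cfg[round(idx), ], seed = 7)
      desc <- extract_descriptor_matrix(set$clips)
      cache <<- list(set = set, descriptors = desc)
    }
    cache
  }
})
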