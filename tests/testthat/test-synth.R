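# tone synthesis, WAV round trips, and the stimulus/rating generators

test_that("D# frequencies follow equal temperament anchored at A4 = 440", {
  expect_equal(round(dsharp_frequency(4)), 311)
  expect_equal(dsharp_frequency(5), 2 * dsharp_frequency(4))
  expect_equal(dsharp_frequency(1), 440 * 2^(-6 / 12) / 8, tolerance = 1e-12)
  expect_error(dsharp_frequency(0), "octave")
  expect_error(dsharp_frequency(8), "octave")
})

test_that("synthesized clips have the contracted length, fade and pitch", {
  spec <- tone_spec(4, "brass", n_partials = 1, noise_level = 0)
  clip <- synthesize_tone(spec, seed = 1)
  expect_length(clip$samples, 22050)
  expect_identical(clip$samples[22050], 0)
  # sample at 450 ms is just before the fade starts: unattenuated
  pre_fade <- synthesize_tone(spec, seed = 1)$samples[19845]
  expect_gt(abs(pre_fade) + abs(clip$samples[19846]), 0)
  expect_true(all(abs(clip$samples) <= spec$peak_level + 1e-12))
  # FFT-peak oracle on a zero-padded transform: within 1 Hz of nominal
  pad <- 2^18
  mag <- Mod(stats::fft(c(clip$samples, numeric(pad - 22050))))
  peak_hz <- (which.max(mag[1:(pad / 2)]) - 1) * 44100 / pad
  expect_lt(abs(peak_hz - dsharp_frequency(4)), 1)
})

test_that("partials above Nyquist are dropped, not aliased", {
  spec <- tone_spec(7, "brass", n_partials = 100, noise_level = 0)
  clip <- synthesize_tone(spec, seed = 1)
  nbins <- 22050
  mag <- Mod(stats::fft(clip$samples))[1:(nbins / 2)]
  f0 <- dsharp_frequency(7)
  n_above <- floor(22050 / f0)  # partials that fit below Nyquist
  # energy at would-be aliased frequencies of partials > Nyquist is absent:
  # the strongest spectral peaks all sit at harmonic positions
  peaks <- order(mag, decreasing = TRUE)[1:5]
  peak_hz <- (peaks - 1) * 2
  rel <- peak_hz / f0
  expect_true(all(abs(rel - round(rel)) < 0.05))
  expect_lte(max(round(rel)), n_above)
})

test_that("synthesis is deterministic and RMS is monotone in peak_level", {
  spec <- tone_spec(3, "string", noise_level = 0.1)
  a <- synthesize_tone(spec, seed = 5)
  b <- synthesize_tone(spec, seed = 5)
  expect_identical(a$samples, b$samples)
  rms_at <- vapply(c(0.3, 0.6, 0.9), function(p) {
    s <- spec
    s$peak_level <- p
    sqrt(mean(synthesize_tone(s, seed = 5)$samples^2))
  }, numeric(1))
  expect_true(all(diff(rms_at) > 0))
})

test_that("WAV files round-trip through the RIFF reader", {
  spec <- tone_spec(4, "woodwind", noise_level = 0.05)
  clip <- synthesize_tone(spec, seed = 3)
  path <- tempfile(fileext = ".wav")
  write_wav(clip$samples, path, clip$sample_rate)
  back <- read_wav(path)
  expect_equal(back$sample_rate, 44100L)
  expect_length(back$samples, 22050)
  expect_lt(max(abs(back$samples - clip$samples)), 1 / 32767)
  # byte-identical output under the same seed (determinism contract)
  path2 <- tempfile(fileext = ".wav")
  write_wav(synthesize_tone(spec, seed = 3)$samples, path2, 44100L)
  expect_identical(tools::md5sum(path)[[1]], tools::md5sum(path2)[[1]])
  unlink(c(path, path2))
})

test_that("the default stimulus configuration yields 137 tones", {
  cfg <- default_stimulus_config()
  expect_equal(nrow(cfg), 137)
  expect_setequal(unique(cfg$family),
                  c("brass", "woodwind", "string", "percussion"))
  expect_true(all(cfg$octave %in% 1:7))
  expect_equal(anyDuplicated(cfg$stimulus_id), 0)
  # restricting to one family/octave gives that count exactly
  sub <- cfg[cfg$family == "brass" & cfg$octave == 2, ]
  out <- generate_stimulus_set(sub, seed = 1)
  expect_length(out$clips, nrow(sub))
  expect_error(generate_stimulus_set(cfg[0, ], seed = 1), "non-empty")
})

test_that("simulated ratings respect bounds and degenerate cases", {
  feats <- data.frame(stimulus_id = sprintf("S%02d", 1:10),
                      octave = rep(1:5, 2), slope_param = runif(10, 1, 2),
                      noise_level = runif(10, 0, 0.1),
                      decay_param = runif(10, 0.3, 6))
  # constant latent 0.5, zero noise -> every rating is the midpoint 5
  eff0 <- planted_effect(list(valence = c(octave = 0)), intercept = 0.5,
                         noise_sd = 0, intercept_sd = 0)
  r0 <- generate_ratings(feats, eff0, n_participants = 4, seed = 1)
  expect_true(all(r0$rating == 5L))
  # zero noise and intercepts -> all participants identical
  eff1 <- planted_effect(list(valence = c(octave = 0.4)), noise_sd = 0,
                         intercept_sd = 0)
  r1 <- generate_ratings(feats, eff1, n_participants = 4, seed = 1)
  m <- rating_matrix(r1, "valence")
  expect_true(all(apply(m, 2, function(col) length(unique(col)) == 1)))
  # bounds always hold under heavy noise
  eff2 <- planted_effect(list(valence = c(octave = 0.4)), noise_sd = 1,
                         intercept_sd = 0.5)
  r2 <- generate_ratings(feats, eff2, n_participants = 8, seed = 2)
  expect_true(all(r2$rating >= 1 & r2$rating <= 9))
  expect_identical(r2, generate_ratings(feats, eff2, 8, seed = 2))
})

test_that("a planted monotone effect shows up in the mean ratings", {
  feats <- data.frame(stimulus_id = sprintf("S%02d", 1:30),
                      slope_param = seq(0.5, 2.5, length.out = 30))
  eff <- planted_effect(list(energy = c(slope_param = 0.5)),
                        intercept = 0.25, noise_sd = 0.05,
                        intercept_sd = 0.05)
  ratings <- generate_ratings(feats, eff, n_participants = 40, seed = 11)
  means <- aggregate_ratings(ratings)
  energy <- means$mean_rating[means$scale == "energy"]
  expect_gt(cor(feats$slope_param, energy), 0.9)
})
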