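# ERB scale, spectrogram framing, and the frame-level spectral descriptors

test_that("the ERB-rate map matches its closed form and is monotone", {
  expect_equal(erb_rate(0), 0)
  expect_equal(erb_rate(1000), 21.4 * log10(4.37 + 1), tolerance = 1e-12)
  expect_equal(round(erb_rate(1000), 2), 15.62)
  f <- seq(0, 22050, length.out = 500)
  expect_true(all(diff(erb_rate(f)) > 0))
  expect_error(erb_rate(-1), "non-negative")
})

test_that("spectrogram framing follows the declared window/hop convention", {
  clip <- sine_clip(freq = 1000)
  sp <- erb_spectrogram(clip)
  # fully-contained frames: floor((N - win)/hop) + 1 = 83 at 44.1 kHz
  expect_equal(nrow(sp$magnitudes), 83)
  expect_equal(length(sp$bin_freqs_hz), 1024 / 2 + 1)
  # per-frame spectral peak lands on the bin nearest the tone frequency
  peak_bins <- apply(sp$magnitudes, 1, which.max)
  nearest <- which.min(abs(sp$bin_freqs_hz - 1000))
  expect_true(all(abs(peak_bins - nearest) <= 1))
  expect_error(erb_spectrogram(as_clip(numeric(100))), "window")
  # silence flagging
  sp2 <- erb_spectrogram(as_clip(c(sine_clip(440, duration = 0.25)$samples,
                                   numeric(11025))))
  expect_true(any(sp2$silent))
  expect_false(sp2$silent[1])
})

test_that("spectral moments match hand-evaluated point masses", {
  m1 <- spectral_moments(c(0, 1, 0), c(10, 12, 14))
  expect_equal(as.numeric(m1), c(12, 0, 0, 0))
  m2 <- spectral_moments(c(1, 1), c(10, 20))
  expect_equal(unname(m2), c(15, 5, 0, 1))
  m3 <- spectral_moments(c(1, 3), c(10, 20))
  expect_equal(unname(m3["centroid"]), 17.5)
  expect_error(spectral_moments(c(0, 0), c(1, 2)), "zero")
})

test_that("spectral shape matches hand-evaluated cases", {
  flat <- spectral_shape(rep(2, 8), 1:8)
  expect_equal(unname(flat[c("slope", "flatness", "crest")]), c(0, 1, 1))
  spike <- spectral_shape(c(0, 0, 5, 0, 0, 0), 1:6)
  expect_equal(unname(spike["flatness"]), 0)
  expect_equal(unname(spike["crest"]), 6)
  d <- spectral_shape(c(1, 0.5, 0.25), c(1, 2, 3))
  expect_equal(unname(d["decrease"]),
               ((0.5 - 1) / 1 + (0.25 - 1) / 2) / 0.75, tolerance = 1e-12)
  # rolloff: cumulative-energy oracle
  mag <- c(4, 3, 2, 1, 0.5)
  e <- mag^2
  oracle_bin <- which(cumsum(e) >= 0.95 * sum(e))[1]
  expect_equal(unname(spectral_shape(mag, 1:5)["rolloff"]), oracle_bin)
})

test_that("spectral variation is a normalized-correlation distance", {
  a <- c(1, 2, 3, 0.5)
  expect_equal(spectral_variation(a, a), 0)
  expect_equal(spectral_variation(a, 3 * a), 0, tolerance = 1e-12)
  expect_equal(spectral_variation(c(1, 0), c(0, 1)), 1)
  expect_error(spectral_variation(c(0, 0), a), "silent")
})

test_that("series summaries follow the linear-interpolation convention", {
  expect_equal(unname(summarize_series(rep(3.3, 7))), c(3.3, 0))
  expect_equal(unname(summarize_series(c(1, 2, 3, 4, 5))["med"]), 3)
  # sort-based oracle for the declared type-7 quantiles
  x <- c(4, 1, 3, 5, 2)
  s <- sort(x)
  q25 <- s[2]  # h = 1 + 0.25*4 = 2 exactly
  q75 <- s[4]
  expect_equal(unname(summarize_series(x)["iqr"]), q75 - q25)
  expect_error(summarize_series(numeric(0)), "empty")
})

test_that("frame descriptors agree with brute-force sums on random frames", {
  with_seed_local(2024, {
    for (i in 1:1000) {
      mag <- runif(16, min = 0.001, max = 2)
      f <- sort(runif(16, 1, 38))
      # brute-force moments
      p <- mag / sum(mag)
      mu <- sum(p * f)
      sg <- sqrt(sum(p * (f - mu)^2))
      expected <- c(mu, sg, sum(p * (f - mu)^3) / sg^3,
                    sum(p * (f - mu)^4) / sg^4)
      got <- spectral_moments(mag, f)
      if (max(abs(got - expected) / abs(expected)) > 1e-9) {
        fail(sprintf("moment mismatch on frame %d", i))
      }
      # brute-force shape
      sh <- spectral_shape(mag, f)
      slope_o <- {
        pn <- mag / sum(mag)
        sum((f - mean(f)) * (pn - mean(pn))) / sum((f - mean(f))^2)
      }
      dec_o <- sum((mag[2:16] - mag[1]) / (1:15)) / sum(mag[2:16])
      e <- mag^2
      roll_o <- f[which(cumsum(e) >= 0.95 * sum(e))[1]]
      flat_o <- exp(mean(log(mag))) / mean(mag)
      crest_o <- max(mag) / mean(mag)
      expected_sh <- c(slope_o, dec_o, roll_o, flat_o, crest_o)
      if (max(abs(sh - expected_sh) / abs(expected_sh)) > 1e-9) {
        fail(sprintf("shape mismatch on frame %d", i))
      }
    }
    succeed()
  })
})

test_that("moment descriptors are gain invariant; mirroring flips skewness", {
  with_seed_local(9, {
    mag <- runif(32, 0.01, 1)
    f <- sort(runif(32, 2, 36))
    m <- spectral_moments(mag, f)
    m_scaled <- spectral_moments(0.5 * mag, f)
    expect_equal(m, m_scaled, tolerance = 1e-9)
    # mirror about the centroid: skewness flips, spread/kurtosis preserved
    mirrored <- spectral_moments(rev(mag), 2 * m["centroid"] - rev(f))
    expect_equal(unname(mirrored["skewness"]), -unname(m["skewness"]),
                 tolerance = 1e-9)
    expect_equal(unname(mirrored["spread"]), unname(m["spread"]),
                 tolerance = 1e-9)
    expect_equal(unname(mirrored["kurtosis"]), unname(m["kurtosis"]),
                 tolerance = 1e-9)
    # centroid within bin range; spread at most half the range
    expect_gte(unname(m["centroid"]), min(f))
    expect_lte(unname(m["centroid"]), max(f))
    expect_lte(unname(m["spread"]), (max(f) - min(f)) / 2)
  })
})
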