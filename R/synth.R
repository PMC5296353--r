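#' Fundamental frequency of D# in a given octave
#'
#' Equal temperament anchored at A4 = 440 Hz; D# lies six semitones below A
#' within each octave, so D#4 = 440 * 2^(-6/12) ~= 311.1 Hz and each octave
#' doubles the frequency.
#'
#' @param octave integer octave number, 1 to 7.
#' @return fundamental frequency in Hz.
#' @examples
#' dsharp_frequency(4)  # ~311 Hz
#' @export
dsharp_frequency <- function(octave) {
  if (any(octave != round(octave)) || any(octave < 1) || any(octave > 7)) {
    stop("octave must be an integer in 1..7")
  }
  440 * 2^(-6 / 12) * 2^(octave - 4)
}

#' Specify a synthetic test tone
#'
#' A tone specification bundles everything [synthesize_tone()] needs: pitch
#' register (pitch class fixed at D#), an instrument-family archetype, the
#' additive-synthesis partial structure, the amplitude envelope, a broadband
#' noise floor, and slow amplitude/frequency modulation (flutter and vibrato
#' analogs).
#'
#' @param pitch_octave octave 1-7 (D# pitch class).
#' @param family one of `"brass"`, `"woodwind"`, `"string"`, `"percussion"`.
#' @param n_partials number of harmonic partials (those above Nyquist are
#'   dropped at synthesis time).
#' @param slope_param spectral rolloff exponent: partial k has amplitude
#'   `k^-slope_param`. Smaller values give brighter tones.
#' @param attack_time linear onset ramp duration in seconds (must be shorter
#'   than the 0.5 s clip).
#' @param decay_param exponential decay rate (1/s) applied after the attack;
#'   large values give impulsive, percussion-like envelopes.
#' @param noise_level ratio of noise RMS to tone RMS, in \[0, 1\].
#' @param am_rate,am_depth amplitude-modulation rate (Hz) and depth
#'   (unitless, 0 disables); flutter analog.
#' @param fm_rate,fm_depth frequency-modulation rate (Hz) and depth (cents,
#'   0 disables); vibrato analog.
#' @param tilt_rate,tilt_depth slow drift of the spectral rolloff exponent:
#'   the effective slope oscillates sinusoidally around `slope_param` with
#'   this rate (Hz) and amplitude (exponent units). Emulates the spectral
#'   envelope motion of sustained instrument tones and drives the
#'   brightness-linked descriptor variability (IQRs).
#' @param shimmer depth of slow independent per-partial amplitude
#'   modulation (unitless, 0 disables); emulates partial-level micro-
#'   dynamics and drives crest/flatness variability.
#' @param noise_mod_rate,noise_mod_depth slow modulation of the noise-floor
#'   level (Hz / unitless, 0 disables); emulates fluctuating breathiness
#'   and drives the variability of the noise-linked descriptors.
#' @param noise_cut lower edge of the noise band as a multiple of the
#'   fundamental; breath/bow/mallet noise sits above the played pitch and
#'   its placement shapes the spectral tail.
#' @param formant_freq,formant_gain center (Hz) and gain of a static
#'   resonance bump over the partial amplitudes (gain 0 disables); the
#'   body-resonance analog that decouples the spectral-shape descriptors
#'   from pure register.
#' @param peak_level peak amplitude of the normalized clip, in (0, 1\].
#' @return object of class `tone_spec`.
#' @export
tone_spec <- function(pitch_octave, family = "brass", n_partials = 20,
                      slope_param = 1, attack_time = 0.05, decay_param = 0.5,
                      noise_level = 0, am_rate = 0, am_depth = 0,
                      fm_rate = 0, fm_depth = 0, tilt_rate = 0,
                      tilt_depth = 0, shimmer = 0, noise_mod_rate = 0,
                      noise_mod_depth = 0, noise_cut = 2.5,
                      formant_freq = 0, formant_gain = 0,
                      peak_level = 0.9) {
  stopifnot(n_partials >= 1, attack_time > 0, attack_time < 0.5,
            noise_level >= 0, noise_level <= 1,
            peak_level > 0, peak_level <= 1)
  family <- match.arg(family, c("brass", "woodwind", "string", "percussion"))
  if (pitch_octave != round(pitch_octave) ||
      pitch_octave < 1 || pitch_octave > 7) {
    stop("pitch_octave must be an integer in 1..7")
  }
  structure(list(pitch_octave = as.integer(pitch_octave), family = family,
                 n_partials = as.integer(n_partials),
                 slope_param = slope_param, attack_time = attack_time,
                 decay_param = decay_param, noise_level = noise_level,
                 am_rate = am_rate, am_depth = am_depth,
                 fm_rate = fm_rate, fm_depth = fm_depth,
                 tilt_rate = tilt_rate, tilt_depth = tilt_depth,
                 shimmer = shimmer, noise_mod_rate = noise_mod_rate,
                 noise_mod_depth = noise_mod_depth, noise_cut = noise_cut,
                 formant_freq = formant_freq, formant_gain = formant_gain,
                 peak_level = peak_level),
            class = "tone_spec")
}

#' Synthesize a 500 ms tone from a specification
#'
#' Additive synthesis at 44.1 kHz: harmonic partials with power-law amplitude
#' rolloff (partials above Nyquist dropped), a linear attack ramp followed by
#' exponential decay, an optional enveloped white-noise floor, amplitude and
#' frequency modulation, peak normalization, and a raised-cosine fade over
#' the final 50 ms so the last sample is exactly zero. Deterministic given
#' `seed` (the seed drives only the noise floor).
#'
#' @param spec a [tone_spec()].
#' @param seed integer RNG seed for the noise component.
#' @param sample_rate sampling rate in Hz.
#' @param duration clip duration in seconds.
#' @return object of class `audio_clip`: list with `samples`, `sample_rate`,
#'   and `spec`.
#' @export
synthesize_tone <- function(spec, seed = 1L, sample_rate = 44100L,
                            duration = 0.5) {
  stopifnot(inherits(spec, "tone_spec"))
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  f0 <- dsharp_frequency(spec$pitch_octave)
  if (f0 >= sample_rate / 2) stop("fundamental above Nyquist")
  ks <- seq_len(spec$n_partials)
  ks <- ks[ks * f0 < sample_rate / 2]

  # frequency modulation in cents about each partial's nominal frequency
  fm <- if (spec$fm_depth > 0 && spec$fm_rate > 0) {
    2^(spec$fm_depth / 1200 * sin(2 * pi * spec$fm_rate * t))
  } else {
    rep(1, n)
  }
  # slow drift of the rolloff exponent and per-partial shimmer, seeded
  rand <- with_seed(seed + 1L, stats::runif(2 + 2 * length(ks)))
  tilt <- if (spec$tilt_depth > 0 && spec$tilt_rate > 0) {
    spec$tilt_depth * sin(2 * pi * spec$tilt_rate * t + 2 * pi * rand[1])
  } else {
    numeric(n)
  }
  has_fm <- spec$fm_depth > 0 && spec$fm_rate > 0
  base_phase <- if (has_fm) {
    2 * pi * cumsum(f0 * fm) / sample_rate
  } else {
    2 * pi * f0 * t
  }
  # static resonance bump (formant analog) over the partial amplitudes
  formant <- if (spec$formant_gain > 0 && spec$formant_freq > 0) {
    1 + spec$formant_gain *
      exp(-(log(ks * f0) - log(spec$formant_freq))^2 / (2 * 0.5^2))
  } else {
    rep(1, length(ks))
  }
  tone <- numeric(n)
  for (i in seq_along(ks)) {
    k <- ks[i]
    phase <- k * base_phase
    amp <- formant[i] * exp(-(spec$slope_param + tilt) * log(k))
    if (spec$shimmer > 0) {
      amp <- amp * (1 + spec$shimmer *
                      sin(2 * pi * (2 + 6 * rand[2 + i]) * t +
                            2 * pi * rand[2 + length(ks) + i]))
    }
    tone <- tone + amp * sin(phase)
  }
  if (spec$am_depth > 0 && spec$am_rate > 0) {
    tone <- tone * (1 + spec$am_depth * sin(2 * pi * spec$am_rate * t)) /
      (1 + spec$am_depth)
  }
  if (spec$noise_level > 0) {
    # breath/bow/mallet noise sits above the played pitch: white noise
    # high-passed at noise_cut x f0 via FFT masking
    noise <- with_seed(seed, stats::rnorm(n))
    N <- stats::fft(noise)
    cut <- ceiling(spec$noise_cut * f0 * n / sample_rate)
    mask <- rep(1, n)
    mask[seq_len(min(cut, n))] <- 0
    mask[n + 1 - seq_len(min(cut, n %/% 2))] <- 0
    noise <- Re(stats::fft(N * mask, inverse = TRUE) / n)
    if (spec$noise_mod_depth > 0 && spec$noise_mod_rate > 0) {
      noise <- noise * (1 + spec$noise_mod_depth *
                          sin(2 * pi * spec$noise_mod_rate * t +
                                2 * pi * rand[2])) / (1 + spec$noise_mod_depth)
    }
    tone <- tone + noise * spec$noise_level * rms(tone) / rms(noise)
  }

  env <- pmin(t / spec$attack_time, 1)
  post <- t > spec$attack_time
  env[post] <- exp(-spec$decay_param * (t[post] - spec$attack_time))
  x <- tone * env
  x <- x / max(abs(x)) * spec$peak_level

  n_fade <- round(0.05 * sample_rate)
  idx <- (n - n_fade + 1):n
  x[idx] <- x[idx] * 0.5 * (1 + cos(pi * seq(0, 1, length.out = n_fade)))
  structure(list(samples = x, sample_rate = sample_rate, spec = spec),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip: %d samples @ %d Hz, D#%d %s>\n",
              length(x$samples), x$sample_rate,
              x$spec$pitch_octave, x$spec$family))
  invisible(x)
}

# Archetype parameters per family/technique/attack. These are deliberately
# schematic: the goal is wide, independent coverage of brightness (slope),
# onset (attack), noisiness and modulation across the stimulus set, not
# imitation of real instruments.
archetype_spec <- function(family, octave, technique, attack, variant) {
  # one shared spectral-envelope form: power-law partial rolloff with the
  # harmonic stack filling the band to Nyquist; families differ in
  # parameter ranges, not structure
  slope <- switch(family,
                  brass = 1.3, woodwind = 1.45, string = 1.35,
                  percussion = 1.65)
  n_partials <- 600L
  noise <- switch(family,
                  brass = 0.006, woodwind = 0.015, string = 0.01,
                  percussion = 0.02)
  tilt_rate <- switch(family,
                      brass = 3, woodwind = 2, string = 2.5, percussion = 1)
  tilt_depth <- 0.15
  shimmer <- 0.3
  decay <- switch(family,
                  brass = 0.4, woodwind = 0.3, string = 0.5, percussion = 6)
  atk <- switch(attack,
                weak = 0.15, normal = 0.06, strong = 0.015,
                felt = 0.012, wood = 0.006, metal = 0.003,
                0.06)
  am_rate <- 0; am_depth <- 0; fm_rate <- 0; fm_depth <- 0
  if (technique == "flutter") { am_rate <- 16; am_depth <- 0.6 }
  if (technique == "vibrato") { fm_rate <- 5.5; fm_depth <- 35 }
  if (technique == "pizzicato") { atk <- 0.004; decay <- 9 }
  if (attack == "metal") { slope <- slope - 0.1; noise <- noise * 1.5 }
  # deterministic per-variant spread so "instrument variants" differ
  slope <- slope * c(0.95, 1, 1.05)[((variant - 1) %% 3) + 1]
  tone_spec(pitch_octave = octave, family = family,
            n_partials = n_partials, slope_param = slope,
            attack_time = atk, decay_param = decay, noise_level = noise,
            am_rate = am_rate, am_depth = am_depth,
            fm_rate = fm_rate, fm_depth = fm_depth,
            tilt_rate = tilt_rate, tilt_depth = tilt_depth,
            shimmer = shimmer)
}

# per-stimulus "instrument individuality": seeded multiplicative jitter of
# the micro-dynamic strengths, so descriptor medians (set by register and
# spectral slope) and variabilities (set by modulation depths) have partly
# independent drivers across the set
jitter_spec <- function(spec, seed) {
  u <- with_seed(seed, stats::runif(8))
  spec$noise_level <- clamp(spec$noise_level * 10^(1.3 * (u[1] - 0.5)), 0, 1)
  spec$tilt_depth <- spec$tilt_depth * (0.4 + 1.6 * u[2])
  spec$shimmer <- spec$shimmer * (0.4 + 1.6 * u[3])
  spec$tilt_rate <- spec$tilt_rate * (0.3 + 1.7 * u[4])
  spec$noise_mod_depth <- 0.2 + 0.7 * u[5]
  spec$noise_mod_rate <- 1 + 3 * u[6]
  if (spec$fm_depth == 0) {
    # universal pitch instability (cents-scale), below vibrato depth
    spec$fm_rate <- 4 + 3 * u[7]
    spec$fm_depth <- 5 + 20 * u[8]
  }
  v <- with_seed(seed + 1L, stats::runif(3))
  spec$noise_cut <- 1.5 + 5 * v[1]
  spec$formant_freq <- exp(log(300) + v[2] * (log(5000) - log(300)))
  spec$formant_gain <- 1.5 * v[3]
  spec
}

#' Default synthetic stimulus configuration (137 tones)
#'
#' A grid over family, octave, technique, attack/mallet and instrument
#' variant chosen to span playable orchestral registers: brass D#1-D#5 with
#' three attack strengths and optional flutter; woodwinds D#2-D#7 with
#' optional flutter, three variants; strings D#1-D#7 normal/vibrato/
#' pizzicato, two variants; percussion D#3-D#7 with three mallet hardnesses,
#' two variants (one extreme high-register metal variant omitted to keep the
#' set at 137, mirroring register limits of real instruments).
#'
#' @return data frame with columns `stimulus_id`, `family`, `octave`,
#'   `technique`, `attack`, `variant`.
#' @export
default_stimulus_config <- function() {
  brass <- expand.grid(family = "brass", octave = 1:5,
                       technique = c("normal", "flutter"),
                       attack = c("weak", "normal", "strong"),
                       variant = 1L, stringsAsFactors = FALSE)
  wood <- expand.grid(family = "woodwind", octave = 2:7,
                      technique = c("normal", "flutter"),
                      attack = "normal", variant = 1:3,
                      stringsAsFactors = FALSE)
  string <- expand.grid(family = "string", octave = 1:7,
                        technique = c("normal", "vibrato", "pizzicato"),
                        attack = "normal", variant = 1:2,
                        stringsAsFactors = FALSE)
  perc <- expand.grid(family = "percussion", octave = 3:7,
                      technique = "normal",
                      attack = c("felt", "wood", "metal"), variant = 1:2,
                      stringsAsFactors = FALSE)
  perc <- perc[!(perc$octave == 7 & perc$attack == "metal" &
                   perc$variant == 2L), ]
  cfg <- rbind(brass, wood, string, perc)
  cfg <- cfg[order(cfg$family, cfg$octave, cfg$technique, cfg$attack,
                   cfg$variant), ]
  cfg$stimulus_id <- sprintf("S%03d", seq_len(nrow(cfg)))
  rownames(cfg) <- NULL
  cfg[, c("stimulus_id", "family", "octave", "technique", "attack",
          "variant")]
}

#' Generate a synthetic stimulus set
#'
#' Synthesizes one clip per configuration row (deterministically: each row's
#' noise seed is derived from `seed` and the row index) and returns the clips
#' with their metadata. Optionally writes 16-bit PCM WAV files and a
#' metadata CSV to `dir`.
#'
#' @param config data frame as returned by [default_stimulus_config()].
#' @param seed integer master seed.
#' @param dir optional output directory for WAV + `stimuli.csv`.
#' @return list with `clips` (named list of `audio_clip`) and `metadata`
#'   (the config plus synthesis parameters).
#' @export
generate_stimulus_set <- function(config = default_stimulus_config(),
                                  seed = 1L, dir = NULL) {
  if (!is.data.frame(config) || nrow(config) == 0) {
    stop("config must be a non-empty data frame")
  }
  clips <- vector("list", nrow(config))
  names(clips) <- config$stimulus_id
  meta <- config
  meta$slope_param <- NA_real_
  meta$attack_time <- NA_real_
  meta$noise_level <- NA_real_
  meta$decay_param <- NA_real_
  for (i in seq_len(nrow(config))) {
    spec <- archetype_spec(config$family[i], config$octave[i],
                           config$technique[i], config$attack[i],
                           config$variant[i])
    spec <- jitter_spec(spec, seed * 2000L + i)
    clips[[i]] <- synthesize_tone(spec, seed = seed * 1000L + i)
    meta$slope_param[i] <- spec$slope_param
    meta$attack_time[i] <- spec$attack_time
    meta$noise_level[i] <- spec$noise_level
    meta$decay_param[i] <- spec$decay_param
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(clips)) {
      write_wav(clips[[id]]$samples, file.path(dir, paste0(id, ".wav")),
                clips[[id]]$sample_rate)
    }
    utils::write.csv(meta, file.path(dir, "stimuli.csv"), row.names = FALSE)
  }
  list(clips = clips, metadata = meta)
}
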