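#' Specify a planted descriptor-to-emotion mapping
#'
#' Ground truth for the synthetic rating generator: for each rating scale, a
#' set of linear coefficients on named stimulus features (either synthesis
#' parameters from the stimulus metadata or extracted descriptors). Features
#' are range-normalized to \[0, 1\] before weighting and the resulting latent
#' mean is clamped to \[0, 1\] before discretization onto the 9-point scale.
#'
#' @param coefs named list, one element per scale; each element a named
#'   numeric vector of feature coefficients.
#' @param intercept latent intercept (applies to every scale).
#' @param nonlinear if `TRUE`, pass the linear predictor through a logistic
#'   squash (centered at `intercept`) instead of clamping alone.
#' @param noise_sd SD of the per-rating Gaussian noise, on the \[0, 1\]
#'   latent scale.
#' @param intercept_sd SD of the per-participant random intercept, on the
#'   latent scale.
#' @return object of class `planted_effect`.
#' @export
planted_effect <- function(coefs, intercept = 0.5, nonlinear = FALSE,
                           noise_sd = 0.05, intercept_sd = 0.05) {
  stopifnot(is.list(coefs), length(coefs) >= 1, !is.null(names(coefs)))
  structure(list(coefs = coefs, intercept = intercept,
                 nonlinear = nonlinear, noise_sd = noise_sd,
                 intercept_sd = intercept_sd),
            class = "planted_effect")
}

#' Default planted mapping for the six rating scales
#'
#' Uses synthesis parameters as ground-truth features: valence rewards
#' bright, crisp onsets; tension tracks brightness and modulation; energy
#' tracks register; preference/familiarity echo valence with small twists.
#'
#' @param noise_sd,intercept_sd latent-scale noise parameters.
#' @return a [planted_effect()].
#' @export
default_planted_effect <- function(noise_sd = 0.05, intercept_sd = 0.05) {
  planted_effect(
    coefs = list(
      valence = c(slope_param = -0.3, noise_level = -0.15, octave = 0.15),
      pleasure = c(slope_param = -0.3, noise_level = -0.15, octave = 0.15),
      tension = c(slope_param = -0.25, noise_level = 0.2, octave = 0.1),
      energy = c(octave = 0.4, decay_param = 0.1),
      preference = c(slope_param = -0.2, noise_level = -0.1),
      familiarity = c(octave = 0.1, noise_level = -0.2)
    ),
    noise_sd = noise_sd, intercept_sd = intercept_sd
  )
}

range01 <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(0.5, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Latent per-stimulus means implied by a planted effect
#'
#' @param features data frame of stimulus features (rows = stimuli), must
#'   contain every feature named in `effect$coefs`.
#' @param effect a [planted_effect()].
#' @return matrix stimuli x scales of latent means in \[0, 1\].
#' @export
latent_means <- function(features, effect) {
  stopifnot(inherits(effect, "planted_effect"))
  out <- sapply(names(effect$coefs), function(scale) {
    co <- effect$coefs[[scale]]
    missing <- setdiff(names(co), names(features))
    if (length(missing)) {
      stop("features missing for scale ", scale, ": ",
           paste(missing, collapse = ", "))
    }
    lin <- effect$intercept
    for (f in names(co)) lin <- lin + co[[f]] * range01(features[[f]])
    if (effect$nonlinear) {
      stats::plogis(4 * (lin - effect$intercept) )
    } else {
      clamp(lin, 0, 1)
    }
  })
  rownames(out) <- features$stimulus_id %||% rownames(features)
  out
}

#' Simulate participant ratings on 9-point scales
#'
#' Each rating is `clamp(round(1 + 8 * (latent + participant intercept +
#' noise)), 1, 9)`: a latent \[0, 1\] stimulus mean per scale, a Gaussian
#' per-participant random intercept, and Gaussian rating noise, discretized
#' onto the 1-9 scale. Participants are split evenly into musician /
#' nonmusician groups (label only; it does not alter the generative model).
#'
#' @param features stimulus feature data frame (see [latent_means()]); must
#'   carry a `stimulus_id` column.
#' @param effect a [planted_effect()].
#' @param n_participants number of simulated raters (>= 2).
#' @param seed integer RNG seed.
#' @return long data frame: `participant_id`, `group`, `stimulus_id`,
#'   `scale`, `rating`.
#' @export
generate_ratings <- function(features, effect = default_planted_effect(),
                             n_participants = 40L, seed = 1L) {
  stopifnot(n_participants >= 2)
  lat <- latent_means(features, effect)
  n_stim <- nrow(lat)
  scales <- colnames(lat)
  with_seed(seed, {
    intercepts <- stats::rnorm(n_participants, 0, effect$intercept_sd)
    out <- vector("list", n_participants)
    for (p in seq_len(n_participants)) {
      noise <- matrix(stats::rnorm(n_stim * length(scales), 0,
                                   effect$noise_sd),
                      n_stim, length(scales))
      val <- clamp(lat + intercepts[p] + noise, 0, 1)
      rating <- clamp(round(1 + 8 * val), 1, 9)
      out[[p]] <- data.frame(
        participant_id = sprintf("P%02d", p),
        group = if (p <= n_participants / 2) "musician" else "nonmusician",
        stimulus_id = rep(rownames(lat), times = length(scales)),
        scale = rep(scales, each = n_stim),
        rating = as.integer(rating),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
}
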