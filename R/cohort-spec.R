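#' Specify a synthetic cohort
#'
#' A `cohort_spec` collects everything the synthetic-cohort generator needs:
#' the number of subjects, the standardized effect sizes injected on latent
#' movement parameters, the noise on the LLFDI function score, the root seed
#' and the sampling rate of the simulated inertial sensor.
#'
#' Effect sizes are expressed as standardized group differences
#' (Very High minus High Functional Status) on the named latent parameter:
#' an effect of `-0.5` on `sts_duration_mean` makes the fitter group's
#' sit-to-stand transitions half a between-subject standard deviation
#' shorter. Valid names are the rows of [population_defaults()].
#'
#' @param n_subjects Number of subjects (>= 2). Default 160, a typical
#'   baseline cohort for a functional-status study in young-old adults.
#' @param effect_sizes Named numeric vector mapping latent parameter names
#'   to standardized group differences. Empty by default (null cohort).
#' @param llfdi_noise_sd Standard deviation (points on the 0-100 scale) of
#'   the additive noise on the LLFDI score. Default 6.
#' @param seed Integer root seed; every downstream draw is derived from it.
#' @param sampling_rate Sensor sampling rate in Hz. Default 100.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [draw_subject_params()]
#' @export
#' @examples
#' spec <- cohort_spec(n_subjects = 20, effect_sizes = c(sts_duration_mean = -0.5))
#' spec$n_subjects
cohort_spec <- function(n_subjects = 160,
                        effect_sizes = numeric(),
                        llfdi_noise_sd = 6,
                        seed = 20190122L,
                        sampling_rate = 100) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1 || n_subjects < 2) {
    abort("`n_subjects` must be a single number >= 2.", class = "imuperf_config_error")
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    abort("`sampling_rate` must be > 0.", class = "imuperf_config_error")
  }
  if (!is.numeric(llfdi_noise_sd) || llfdi_noise_sd < 0) {
    abort("`llfdi_noise_sd` must be >= 0.", class = "imuperf_config_error")
  }
  effect_sizes <- unlist(effect_sizes)
  if (length(effect_sizes)) {
    bad <- setdiff(names(effect_sizes), population_defaults()$param)
    if (length(bad)) {
      abort(paste0("Unknown effect-size target(s): ", paste(bad, collapse = ", ")),
            class = "imuperf_config_error")
    }
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      effect_sizes = effect_sizes,
      llfdi_noise_sd = llfdi_noise_sd,
      seed = as.integer(seed),
      sampling_rate = sampling_rate
    ),
    class = "cohort_spec"
  )
}

#' Population distribution of the latent movement parameters
#'
#' Each subject is characterised by latent parameters that drive the
#' rendered inertial signals. Parameters are drawn from normal
#' distributions with the means and between-subject standard deviations
#' tabled here, truncated below at `lower` (redrawn when violated), and
#' shifted by the injected effect sizes (see [draw_subject_params()]).
#'
#' @return A tibble with columns `param`, `mean`, `sd`, `lower` and `unit`.
#' @export
population_defaults <- function() {
  tibble::tribble(
    ~param,               ~mean, ~sd,   ~lower, ~unit,
    "sts_duration_mean",   1.10, 0.15,  0.40,   "s",
    "sts_duration_sd",     0.08, 0.03,  0.005,  "s",
    "st2si_duration_mean", 1.20, 0.15,  0.40,   "s",
    "stand_hold",          0.35, 0.10,  0.05,   "s",
    "sit_hold",            0.35, 0.10,  0.05,   "s",
    "turn_peak_velocity",  160,  25,    60,     "deg/s",
    "tts_peak_velocity",   145,  25,    55,     "deg/s",
    "cadence",             1.90, 0.20,  1.00,   "steps/s",
    "gait_intensity",      1.50, 0.30,  0.40,   "m/s^2",
    "walk_time",           2.60, 0.40,  1.20,   "s",
    "gyr_amp_sts",         70,   12,    25,     "deg/s",
    "gyr_amp_st2si",       70,   12,    25,     "deg/s",
    "acc_amp_ap",          1.20, 0.30,  0.30,   "m/s^2",
    "acc_amp_ml",          0.40, 0.10,  0.10,   "m/s^2",
    "acc_amp_v",           0.80, 0.20,  0.20,   "m/s^2",
    "tilt_max",            0.25, 0.05,  0.10,   "rad"
  )
}

# sensor noise levels are fixed acquisition properties, not subject traits
DEFAULT_NOISE_SD_ACC <- 0.08  # m/s^2
DEFAULT_NOISE_SD_GYR <- 1.5   # deg/s

#' Draw one subject's latent movement parameters
#'
#' The subject's position on the functional-status continuum is encoded by
#' `group_latent` in \[0, 1\] (1 = fittest). For a parameter with population
#' mean \eqn{\mu} and between-subject SD \eqn{\sigma}, an injected effect
#' \eqn{d} shifts the conditional mean linearly:
#' \deqn{\mu(g) = \mu + (g - 1/2) \, d \, \sigma,}
#' so two subjects at latent 1 and 0 differ in expectation by exactly
#' \eqn{d\sigma}. Draws are normal around \eqn{\mu(g)} with SD \eqn{\sigma},
#' redrawn below the parameter's physical floor.
#'
#' Uses the current R random-number state; seed it (e.g. with
#' [subject_seed()]) for reproducibility.
#'
#' @param group_latent Number in \[0, 1\].
#' @param spec A [cohort_spec()].
#' @param subject_id Identifier stored with the parameters.
#' @return A `subject_params` list with one element per row of
#'   [population_defaults()] plus `subject_id`, `noise_sd_acc`,
#'   `noise_sd_gyr` and `tilt_max`.
#' @export
draw_subject_params <- function(group_latent, spec, subject_id = "S001") {
  if (!inherits(spec, "cohort_spec")) {
    abort("`spec` must be a cohort_spec.", class = "imuperf_config_error")
  }
  if (!is.numeric(group_latent) || group_latent < 0 || group_latent > 1) {
    abort("`group_latent` must lie in [0, 1].", class = "imuperf_config_error")
  }
  pop <- population_defaults()
  d <- setNames(rep(0, nrow(pop)), pop$param)
  d[names(spec$effect_sizes)] <- spec$effect_sizes
  draw_one <- function(mu, sigma, lower) {
    x <- rnorm(1, mu, sigma)
    tries <- 0L
    while (x < lower && tries < 100L) {
      x <- rnorm(1, mu, sigma)
      tries <- tries + 1L
    }
    max(x, lower)
  }
  vals <- lapply(seq_len(nrow(pop)), function(i) {
    mu <- pop$mean[i] + (group_latent - 0.5) * d[[pop$param[i]]] * pop$sd[i]
    draw_one(mu, pop$sd[i], pop$lower[i])
  })
  names(vals) <- pop$param
  params <- c(
    list(subject_id = subject_id, group_latent = group_latent),
    vals,
    list(
      noise_sd_acc = DEFAULT_NOISE_SD_ACC,
      noise_sd_gyr = DEFAULT_NOISE_SD_GYR
    )
  )
  validate_subject_params(structure(params, class = "subject_params"))
}

validate_subject_params <- function(params) {
  stopifnot(inherits(params, "subject_params"))
  strictly_pos <- c("sts_duration_mean", "st2si_duration_mean",
                    "turn_peak_velocity", "cadence", "walk_time")
  for (p in strictly_pos) {
    if (params[[p]] <= 0) {
      abort(paste0("subject parameter `", p, "` must be > 0."),
            class = "imuperf_config_error")
    }
  }
  nonneg <- c("sts_duration_sd", "stand_hold", "sit_hold", "gait_intensity",
              "noise_sd_acc", "noise_sd_gyr")
  for (p in nonneg) {
    if (params[[p]] < 0) {
      abort(paste0("subject parameter `", p, "` must be >= 0."),
            class = "imuperf_config_error")
    }
  }
  cycle <- params$sts_duration_mean + params$stand_hold +
    params$st2si_duration_mean + params$sit_hold
  if (cycle > 30) {
    abort("a full chair-stand cycle exceeds the 30 s test duration.",
          class = "imuperf_config_error")
  }
  params
}

#' Derive the seed of one subject's random substream
#'
#' Subject `i` of a cohort is simulated under `set.seed(subject_seed(seed, i))`,
#' a fixed affine counter scheme modulo `2^31 - 1`, so any subject can be
#' regenerated in isolation.
#'
#' @param seed Root seed (integer).
#' @param i Subject index (1-based).
#' @return A positive integer seed.
#' @export
subject_seed <- function(seed, i) {
  s <- (as.double(seed) %% 2147483647 + 100003 * as.double(i)) %% 2147483647
  as.integer(s) + 1L
}
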