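#  Signal rendering -----------------------------------------------------------
#
#  Postural transitions are Gaussian-windowed sinusoids: over normalized time
#  tau in [0, 1],
#     biphasic(tau) = sin(2 pi tau) * exp(-((tau - 0.5) / 0.6)^2 / 2)
#     mono(tau)     = sin(pi tau)^2
#  The wide Gaussian window keeps the pulse smooth (finite jerk) while its
#  10%-of-peak crossings stay close to the nominal interval edges, so
#  envelope-based segmentation recovers the true duration.

pulse_biphasic <- function(tau) sin(2 * pi * tau) * exp(-((tau - 0.5) / 0.6)^2 / 2)
pulse_mono <- function(tau) sin(pi * tau)^2

# indices of samples falling in [t0, t0 + d]
pulse_window <- function(t, t0, d) which(t >= t0 & t <= t0 + d)

# Per-execution amplitude jitter: no two repetitions of a movement are
# performed with identical vigour. Drawn from the active RNG stream.
draw_jitter <- function(sd = 0.12) max(1 + rnorm(1, 0, sd), 0.3)

# In-place rendering of a sit-to-stand (direction = +1) or stand-to-sit
# (direction = -1) transition: medio-lateral trunk rotation (biphasic),
# antero-posterior acceleration with a gravity component from trunk tilt,
# a small medio-lateral sway, and a reduced vertical gravity reading while
# tilted. `jit` carries the per-execution amplitude factors.
render_transition <- function(sig, t, t0, d, direction, params,
                              jit = list(gyr = 1, ap = 1, ml = 1, v = 1,
                                         tilt = 1)) {
  idx <- pulse_window(t, t0, d)
  if (!length(idx)) return(sig)
  tau <- (t[idx] - t0) / d
  gyr_amp <- if (direction > 0) params$gyr_amp_sts else params$gyr_amp_st2si
  tilt <- params$tilt_max * jit$tilt * pulse_mono(tau)
  sig$gyr_ml[idx] <- sig$gyr_ml[idx] +
    direction * gyr_amp * jit$gyr * pulse_biphasic(tau)
  sig$acc_ap[idx] <- sig$acc_ap[idx] +
    direction * (params$acc_amp_ap * jit$ap * pulse_mono(tau) +
                   GRAVITY * sin(tilt))
  sig$acc_ml[idx] <- sig$acc_ml[idx] +
    params$acc_amp_ml * jit$ml * pulse_biphasic(tau)
  sig$acc_v[idx] <- sig$acc_v[idx] +
    GRAVITY * (cos(tilt) - 1) +
    params$acc_amp_v * jit$v * pulse_biphasic(tau)
  sig
}

draw_transition_jitter <- function() {
  list(gyr = draw_jitter(0.10), ap = draw_jitter(0.15),
       ml = draw_jitter(0.15), v = draw_jitter(0.15),
       tilt = draw_jitter(0.10))
}

# Cadence-locked walking: vertical/AP oscillation at step frequency, ML and
# pelvic rotation alternating at stride (half-step) frequency. Returns the
# signal plus the ground-truth step times in the segment.
render_walk <- function(sig, t, t0, dur, params, cadence_scale = 1) {
  idx <- pulse_window(t, t0, dur)
  if (!length(idx)) return(list(sig = sig, steps = numeric()))
  f_step <- params$cadence * cadence_scale
  tt <- t[idx] - t0
  phi <- 2 * pi * f_step * tt
  g <- params$gait_intensity
  sig$acc_v[idx] <- sig$acc_v[idx] + 0.9 * g * sin(phi)
  sig$acc_ap[idx] <- sig$acc_ap[idx] + 0.5 * g * sin(phi + 0.7)
  sig$acc_ml[idx] <- sig$acc_ml[idx] + 0.35 * g * sin(phi / 2)
  sig$gyr_ml[idx] <- sig$gyr_ml[idx] + 6 * sin(phi / 2 + 1)
  sig$gyr_ap[idx] <- sig$gyr_ap[idx] + 8 * sin(phi / 2)
  k <- 0:max(0, floor(dur * f_step))
  steps <- t0 + (k + 0.25) / f_step
  list(sig = sig, steps = steps[steps < t0 + dur])
}

# Smooth flat-top pulse: cosine ramps of width r on either side of a
# plateau; C1 everywhere, so angular jerk stays finite.
pulse_flat_top <- function(tau, r = 0.15) {
  up <- tau < r
  dn <- tau > 1 - r
  out <- rep(1, length(tau))
  out[up] <- 0.5 * (1 - cos(pi * tau[up] / r))
  out[dn] <- 0.5 * (1 - cos(pi * (1 - tau[dn]) / r))
  out
}

# Yaw turn on the vertical gyroscope. The profile is a flat-top pulse plus
# a mid-turn surge of relative size `overshoot` (people do not turn at a
# constant rate), renormalized so the true maximum equals `peak` (deg/s)
# exactly; duration is set so the integral is `angle` (deg).
render_turn <- function(sig, t, t0, peak, angle, direction = 1, r = 0.15,
                        overshoot = 0) {
  shape_max <- 1 + overshoot
  shape_integral <- (1 - r) + overshoot / 2 # plateau + sin^2 surge
  dur <- angle * shape_max / (peak * shape_integral)
  idx <- pulse_window(t, t0, dur)
  tau <- (t[idx] - t0) / dur
  profile <- (pulse_flat_top(tau, r) + overshoot * pulse_mono(tau)) / shape_max
  sig$gyr_v[idx] <- sig$gyr_v[idx] + direction * peak * profile
  list(sig = sig, dur = dur)
}

blank_signals <- function(n, fs) {
  tibble(
    t = seq_len(n) / fs - 1 / fs,
    acc_ap = numeric(n), acc_ml = numeric(n), acc_v = rep(GRAVITY, n),
    gyr_ap = numeric(n), gyr_ml = numeric(n), gyr_v = numeric(n)
  )
}

add_noise <- function(sig, params) {
  n <- nrow(sig)
  if (params$noise_sd_acc > 0) {
    for (col in c("acc_ap", "acc_ml", "acc_v")) {
      sig[[col]] <- sig[[col]] + rnorm(n, 0, params$noise_sd_acc)
    }
  }
  if (params$noise_sd_gyr > 0) {
    for (col in c("gyr_ap", "gyr_ml", "gyr_v")) {
      sig[[col]] <- sig[[col]] + rnorm(n, 0, params$noise_sd_gyr)
    }
  }
  sig
}

draw_duration <- function(mean, sd, floor_s = 0.3) {
  if (sd == 0) return(max(mean, floor_s))
  x <- rnorm(1, mean, sd)
  tries <- 0L
  while (x < floor_s && tries < 100L) {
    x <- rnorm(1, mean, sd)
    tries <- tries + 1L
  }
  max(x, floor_s)
}

#' Simulate a 30-s Chair Stand test recording
#'
#' Renders repeated stand-up/sit-down cycles for exactly 30 s at the
#' subject's latent transition durations and pauses. One cycle is
#' sit pause, sit-to-stand, stand pause, stand-to-sit; as many complete
#' cycles as fit in 30 s are rendered and a trailing partial cycle is
#' omitted entirely. Transition durations are drawn per cycle from
#' N(mean, sd²) truncated above 0.3 s. The ground-truth annotation of every
#' transition is attached to the returned recording.
#'
#' Uses the current R random-number state; `set.seed()` first for
#' reproducibility.
#'
#' @param params A `subject_params` object from [draw_subject_params()].
#' @param fs Sampling rate in Hz.
#' @return An [imu_recording()] of 30 s with `truth` attached.
#' @export
simulate_cst30 <- function(params, fs = 100) {
  validate_subject_params(params)
  total <- 30
  n <- round(total * fs) + 1L
  sig <- blank_signals(n, fs)
  t <- sig$t

  labels <- character()
  starts <- numeric()
  ends <- numeric()
  cursor <- 0
  repeat {
    d_up <- draw_duration(params$sts_duration_mean, params$sts_duration_sd)
    d_dn <- draw_duration(params$st2si_duration_mean, params$sts_duration_sd)
    cycle <- params$sit_hold + d_up + params$stand_hold + d_dn
    if (cursor + cycle > total) {
      if (cursor == 0) {
        abort("a single chair-stand cycle does not fit in 30 s.",
              class = "imuperf_config_error")
      }
      break
    }
    up0 <- cursor + params$sit_hold
    dn0 <- up0 + d_up + params$stand_hold
    sig <- render_transition(sig, t, up0, d_up, +1, params,
                             draw_transition_jitter())
    sig <- render_transition(sig, t, dn0, d_dn, -1, params,
                             draw_transition_jitter())
    labels <- c(labels, "SitToStand", "StandToSit")
    starts <- c(starts, up0, dn0)
    ends <- c(ends, up0 + d_up, dn0 + d_dn)
    cursor <- cursor + cycle
  }
  sig <- add_noise(sig, params)
  sig <- clip_recording(sig)
  truth <- subphase_annotation(
    "CST30",
    tibble(label = labels, start_s = starts, end_s = ends)
  )
  imu_recording(sig, params$subject_id, "CST30", fs, truth)
}

#' Simulate a Timed Up and Go test recording
#'
#' Renders the TUG sequence: quiet sitting, sit-to-walk, a 3 m walk out,
#' a 180° turn, the walk back, and a turn-to-sit composed of a second
#' ~180° turn immediately followed by the sit-down transition. Turns are
#' squared-sine yaw-rate pulses whose peak equals the subject's
#' `turn_peak_velocity` and whose integral is 180° plus a small jitter;
#' walking is cadence-locked sinusoidal acceleration of amplitude
#' `gait_intensity`. Ground truth (all subphases, the turning sub-interval
#' of the turn-to-sit, and step times) is attached.
#'
#' @inheritParams simulate_cst30
#' @return An [imu_recording()] with `truth` attached.
#' @export
simulate_tug <- function(params, fs = 100) {
  validate_subject_params(params)
  lead <- 1.0
  d_sw <- draw_duration(params$sts_duration_mean, params$sts_duration_sd)
  jit_sw <- draw_transition_jitter()
  w1 <- max(1.2, params$walk_time * (1 + rnorm(1, 0, 0.05)))
  jit1 <- runif(1, -3, 3)
  w2 <- max(1.2, params$walk_time * (1 + rnorm(1, 0, 0.05)))
  jit2 <- runif(1, -3, 3)
  d_st <- draw_duration(params$st2si_duration_mean, params$sts_duration_sd)
  jit_st <- draw_transition_jitter()
  # each turn is its own movement with its own latent peak rate (turning
  # in preparation for sitting engages planning and is typically slower),
  # plus per-execution jitter and a variable mid-turn surge
  peak1 <- params$turn_peak_velocity * draw_jitter(0.08)
  peak2 <- params$tts_peak_velocity * draw_jitter(0.08)
  over1 <- runif(1, 0, 0.5)
  over2 <- runif(1, 0, 0.5)
  t1_dur <- (180 + jit1) * (1 + over1) / (peak1 * (0.85 + over1 / 2))
  t2_dur <- (180 + jit2) * (1 + over2) / (peak2 * (0.85 + over2 / 2))

  total <- lead + d_sw + w1 + t1_dur + w2 + t2_dur + d_st + 1.0
  n <- ceiling(total * fs) + 1L
  sig <- blank_signals(n, fs)
  t <- sig$t

  sw0 <- lead
  walk1_0 <- sw0 + d_sw
  turn1_0 <- walk1_0 + w1
  walk2_0 <- turn1_0 + t1_dur
  tts0 <- walk2_0 + w2
  sit0 <- tts0 + t2_dur

  sig <- render_transition(sig, t, sw0, d_sw, +1, params, jit_sw)
  rw1 <- render_walk(sig, t, walk1_0, w1, params)
  sig <- rw1$sig
  rt1 <- render_turn(sig, t, turn1_0, peak1, 180 + jit1, +1,
                     overshoot = over1)
  sig <- rt1$sig
  # turning steps at a reduced cadence during the 180 turn
  rts <- render_walk(sig, t, turn1_0, t1_dur, params, cadence_scale = 0.8)
  sig$acc_v <- rts$sig$acc_v # only vertical stepping while turning
  turn_steps <- rts$steps
  rw2 <- render_walk(sig, t, walk2_0, w2, params)
  sig <- rw2$sig
  rt2 <- render_turn(sig, t, tts0, peak2, 180 + jit2, -1,
                     overshoot = over2)
  sig <- rt2$sig
  sig <- render_transition(sig, t, sit0, d_st, -1, params, jit_st)

  sig <- add_noise(sig, params)
  sig <- clip_recording(sig)

  truth <- subphase_annotation(
    "TUG",
    tibble(
      label = c("SitToWalk", "Walk", "Turn180", "Walk",
                "TurnToSitTurning", "TurnToSit"),
      start_s = c(sw0, walk1_0, turn1_0, walk2_0, tts0, tts0),
      end_s = c(sw0 + d_sw, turn1_0, walk2_0, tts0,
                tts0 + t2_dur, sit0 + d_st)
    ),
    steps = sort(c(rw1$steps, turn_steps, rw2$steps))
  )
  # rendered peak yaw rates (after per-turn jitter), for validation
  truth$turn_peaks <- c(Turn180 = peak1, TurnToSitTurning = peak2)
  imu_recording(sig, params$subject_id, "TUG", fs, truth)
}

#' Generate a synthetic functional-status cohort
#'
#' Draws each subject's latent functional status, movement parameters,
#' one 30CST and one TUG recording, and an LLFDI function score coupled to
#' the latent. The latent is near-binary (0.9·Bernoulli(½) + 0.1·Uniform),
#' so injected effect sizes translate into dichotomized group differences
#' of almost the nominal magnitude. The LLFDI score is a logistic map of
#' the latent onto \[44, 100\] plus Gaussian noise, clipped to \[0, 100\].
#'
#' Standard clinical outcomes are emitted alongside: the assessor-counted
#' chair-stand repetitions (the true count) and the stopwatch TUG duration
#' (true duration plus a 0.3 s reaction offset and 0.2 s timing noise).
#'
#' Subject `i` is simulated under its own substream seed
#' ([subject_seed()]), so cohorts are reproducible subject by subject.
#'
#' @param spec A [cohort_spec()].
#' @return An `imu_cohort`: list with `recordings` (tibble with columns
#'   `subject_id`, `test_type` and the list-column `recording`) and
#'   `cohort` (tibble with `subject_id`, `age`, `sex`, `llfdi`,
#'   `group_latent`, `cst30_repetitions_manual`, `tug_duration_manual`).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n_subjects = 3, seed = 7))
#' coh$cohort
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    abort("`spec` must be a cohort_spec.", class = "imuperf_config_error")
  }
  rows <- vector("list", spec$n_subjects)
  recs <- vector("list", 2L * spec$n_subjects)
  rec_meta <- vector("list", 2L * spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    set.seed(subject_seed(spec$seed, i))
    sid <- sprintf("S%03d", i)
    b <- rbinom(1, 1, 0.5)
    g <- 0.9 * b + 0.1 * runif(1)
    params <- draw_subject_params(g, spec, sid)
    rec_cst <- simulate_cst30(params, spec$sampling_rate)
    rec_tug <- simulate_tug(params, spec$sampling_rate)
    llfdi <- 44 + 56 * stats::plogis(5 * (g - 0.5))
    if (spec$llfdi_noise_sd > 0) llfdi <- llfdi + rnorm(1, 0, spec$llfdi_noise_sd)
    llfdi <- min(max(llfdi, 0), 100)
    age <- min(max(round(rnorm(1, 66.3, 2.4)), 61), 70)
    sex <- if (runif(1) < 0.54) "F" else "M"
    tug_truth <- rec_truth(rec_tug)$intervals
    tug_true_dur <- max(tug_truth$end_s) - min(tug_truth$start_s)
    rows[[i]] <- tibble(
      subject_id = sid, age = age, sex = sex, llfdi = llfdi,
      group_latent = g,
      cst30_repetitions_manual =
        nrow(ann_intervals(rec_truth(rec_cst), "SitToStand")),
      tug_duration_manual = tug_true_dur + 0.3 + rnorm(1, 0, 0.2)
    )
    recs[[2 * i - 1]] <- rec_cst
    recs[[2 * i]] <- rec_tug
    rec_meta[[2 * i - 1]] <- tibble(subject_id = sid, test_type = "CST30")
    rec_meta[[2 * i]] <- tibble(subject_id = sid, test_type = "TUG")
  }
  structure(
    list(
      recordings = mutate(bind_rows(rec_meta), recording = recs),
      cohort = bind_rows(rows),
      spec = spec
    ),
    class = "imu_cohort"
  )
}

#' @export
print.imu_cohort <- function(x, ...) {
  cat(sprintf("<imu_cohort> %d subjects, %d recordings (seed %d)\n",
              nrow(x$cohort), nrow(x$recordings), x$spec$seed))
  print(x$cohort)
  invisible(x)
}
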