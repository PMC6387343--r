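#' Segmentation configuration
#'
#' Filter and threshold settings for subphase detection, locked in one
#' place. Transition detection rectifies the medio-lateral angular velocity
#' and smooths it with a zero-phase 4th-order (2nd-order Butterworth run
#' forward and backward) low-pass; turns use the same envelope on the
#' vertical gyroscope; step detection band-passes the vertical
#' acceleration.
#'
#' @param lowpass_hz Low-pass cutoff (Hz) for transition/turn envelopes.
#' @param trans_threshold Transition peak threshold on the filtered
#'   medio-lateral angular-velocity envelope (°/s).
#' @param boundary_frac Interval boundaries sit where the envelope drops to
#'   this fraction of the local peak.
#' @param turn_threshold Turn peak threshold on the filtered vertical
#'   angular-velocity envelope (°/s).
#' @param turn_min_angle Minimum absolute yaw integral (°) for a
#'   supra-threshold burst to qualify as a turn.
#' @param min_peak_gap_s Envelope peaks closer than this (s) are always
#'   lobes of one movement; peaks whose shared valley stays above 15% of
#'   the lower peak are clustered likewise.
#' @param step_band Band-pass corner frequencies (Hz) for step detection.
#' @param step_min_gap_s Minimum spacing between step peaks (s).
#' @param min_duration_cst,min_duration_tug Shortest analysable recording (s).
#' @return A `seg_config` list.
#' @export
seg_config <- function(lowpass_hz = 2, trans_threshold = 15,
                       boundary_frac = 0.1, turn_threshold = 15,
                       turn_min_angle = 120, min_peak_gap_s = 0.35,
                       step_band = c(0.7, 3), step_min_gap_s = 0.3,
                       min_duration_cst = 5, min_duration_tug = 8) {
  cfg <- list(lowpass_hz = lowpass_hz, trans_threshold = trans_threshold,
              boundary_frac = boundary_frac, turn_threshold = turn_threshold,
              turn_min_angle = turn_min_angle, min_peak_gap_s = min_peak_gap_s,
              step_band = step_band, step_min_gap_s = step_min_gap_s,
              min_duration_cst = min_duration_cst,
              min_duration_tug = min_duration_tug)
  if (lowpass_hz <= 0 || boundary_frac <= 0 || boundary_frac >= 1) {
    abort("invalid segmentation configuration.", class = "imuperf_config_error")
  }
  structure(cfg, class = "seg_config")
}

# zero-phase low pass (2nd-order Butterworth, filtfilt => 4th-order response)
lp_filter <- function(x, fs, cutoff) {
  bf <- signal::butter(2, min(cutoff / (fs / 2), 0.99))
  as.numeric(signal::filtfilt(bf, x))
}

bp_filter <- function(x, fs, band) {
  w <- pmin(band / (fs / 2), 0.99)
  bf <- signal::butter(2, w, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# rectified + smoothed envelope
envelope <- function(x, fs, cutoff) pmax(lp_filter(abs(x), fs, cutoff), 0)

# Supra-threshold bursts of an envelope. Local envelope maxima above the
# threshold closer than min_gap_s are treated as lobes of one movement
# (the higher lobe wins); each surviving peak is expanded outwards to the
# boundary_frac * peak crossing, stopping at the envelope valley shared
# with a neighbouring peak so that back-to-back movements split cleanly.
# Returns start/end in seconds plus the peak location and height.
find_bursts <- function(env, fs, threshold, boundary_frac, min_gap_s,
                        signed = NULL) {
  n <- length(env)
  if (n < 3 || !any(env > threshold)) {
    return(tibble(start_s = numeric(), end_s = numeric(),
                  peak_s = numeric(), peak = numeric()))
  }
  is_max <- c(FALSE, env[2:(n - 1)] >= env[1:(n - 2)] &
                env[2:(n - 1)] > env[3:n], FALSE) & env > threshold
  cand <- which(is_max)
  if (!length(cand)) cand <- which.max(env)
  # Cluster lobes of one movement: consecutive maxima closer than the
  # minimum gap, or whose shared valley stays above 15% of the lower lobe
  # (between distinct movements the envelope falls essentially to the
  # noise floor), belong together; the higher lobe represents the cluster.
  # For biphasic movements the two lobes carry opposite signs of the
  # filtered signal, whereas the facing lobes of two successive opposite
  # movements carry the same sign — when `signed` is given, equal-signed
  # neighbours are never clustered by the valley rule.
  keep <- cand[1]
  if (length(cand) > 1) {
    for (p in cand[-1]) {
      last <- keep[length(keep)]
      valley <- min(env[last:p])
      opposite <- is.null(signed) || sign(signed[last]) != sign(signed[p])
      same <- (p - last) < min_gap_s * fs ||
        (opposite && valley > 0.15 * min(env[last], env[p]))
      if (same) {
        if (env[p] > env[last]) keep[length(keep)] <- p
      } else {
        keep <- c(keep, p)
      }
    }
  }
  nk <- length(keep)
  a_idx <- integer(nk)
  b_idx <- integer(nk)
  for (k in seq_len(nk)) {
    pk <- keep[k]
    level <- boundary_frac * env[pk]
    left_lim <- if (k > 1) {
      keep[k - 1L] - 1L + which.min(env[keep[k - 1L]:pk])
    } else 1L
    right_lim <- if (k < nk) {
      pk - 1L + which.min(env[pk:keep[k + 1L]])
    } else n
    a <- pk
    while (a > left_lim && env[a - 1L] >= level) a <- a - 1L
    b <- pk
    while (b < right_lim && env[b + 1L] >= level) b <- b + 1L
    a_idx[k] <- a
    b_idx[k] <- b
  }
  tibble(start_s = (a_idx - 1L) / fs, end_s = (b_idx - 1L) / fs,
         peak_s = (keep - 1) / fs, peak = env[keep])
}

#' Detect postural transitions in a 30-s Chair Stand recording
#'
#' Transitions are bursts of the rectified, low-pass-filtered
#' medio-lateral angular velocity exceeding the configured threshold; each
#' burst spans the region where the envelope stays above 10% of its peak.
#' Direction (sit-to-stand vs stand-to-sit) is assigned from the sign of
#' the low-pass-filtered antero-posterior acceleration at the envelope
#' peak: the trunk accelerates forward when rising and backward when
#' sitting down.
#'
#' @param rec An [imu_recording()] with `test_type = "CST30"`.
#' @param config A [seg_config()].
#' @return A [subphase_annotation()]; empty (with a warning) when no burst
#'   exceeds the threshold.
#' @export
detect_transitions_cst30 <- function(rec, config = seg_config()) {
  stopifnot(inherits(rec, "imu_recording"))
  if (rec_test_type(rec) != "CST30") {
    abort("recording is not a 30CST test.", class = "imuperf_config_error")
  }
  if (rec_duration(rec) < config$min_duration_cst) {
    abort(sprintf("30CST recording shorter than %g s.", config$min_duration_cst),
          class = "imuperf_segmentation_error")
  }
  fs <- rec_fs(rec)
  env <- envelope(rec$gyr_ml, fs, config$lowpass_hz)
  signed <- lp_filter(rec$gyr_ml, fs, config$lowpass_hz)
  bursts <- find_bursts(env, fs, config$trans_threshold,
                        config$boundary_frac, config$min_peak_gap_s, signed)
  if (!nrow(bursts)) {
    warn("no postural transition found; returning empty annotation.")
    return(subphase_annotation("CST30"))
  }
  ap <- lp_filter(rec$acc_ap - mean(rec$acc_ap), fs, config$lowpass_hz)
  peak_idx <- round(bursts$peak_s * fs) + 1L
  lab <- ifelse(ap[peak_idx] > 0, "SitToStand", "StandToSit")
  subphase_annotation(
    "CST30",
    tibble(label = lab, start_s = bursts$start_s, end_s = bursts$end_s)
  )
}

#' Segment a Timed Up and Go recording into subphases
#'
#' Turns are bursts of the filtered vertical angular-velocity envelope whose
#' enclosed yaw integral is at least `turn_min_angle`; the first qualifying
#' burst is the 180° turn and the second the turning part of the
#' turn-to-sit. The sit-to-walk is the last medio-lateral transition burst
#' before the first turn, the final sit-down the first one after the second
#' turn; the turn-to-sit spans from the start of its turning sub-interval
#' to the end of the sit-down. The two straight-walk gaps are labelled
#' `Walk` and treated downstream as one concatenated phase. Steps are
#' detected in the walking and turn intervals.
#'
#' @param rec An [imu_recording()] with `test_type = "TUG"`.
#' @param config A [seg_config()].
#' @return A [subphase_annotation()] with intervals `SitToWalk`, `Walk`
#'   (twice), `Turn180`, `TurnToSitTurning`, `TurnToSit`, plus step times.
#' @export
segment_tug <- function(rec, config = seg_config()) {
  stopifnot(inherits(rec, "imu_recording"))
  if (rec_test_type(rec) != "TUG") {
    abort("recording is not a TUG test.", class = "imuperf_config_error")
  }
  if (rec_duration(rec) < config$min_duration_tug) {
    abort(sprintf("TUG recording shorter than %g s.", config$min_duration_tug),
          class = "imuperf_segmentation_error")
  }
  fs <- rec_fs(rec)
  envv <- envelope(rec$gyr_v, fs, config$lowpass_hz)
  cand <- find_bursts(envv, fs, config$turn_threshold,
                      config$boundary_frac, config$min_peak_gap_s)
  if (nrow(cand)) {
    cand$angle <- vapply(seq_len(nrow(cand)), function(k) {
      idx <- interval_indices(cand$start_s[k], cand$end_s[k], fs, nrow(rec))
      abs(trapz_integral(rec$gyr_v[idx[1]:idx[2]], fs))
    }, numeric(1))
    turns <- cand[cand$angle >= config$turn_min_angle, ]
  } else {
    turns <- cand
  }
  if (nrow(turns) < 2) {
    missing_phase <- if (nrow(turns) < 1) "Turn180" else "TurnToSitTurning"
    abort(paste0("turn not found: missing subphase ", missing_phase),
          class = "imuperf_segmentation_error")
  }
  turn1 <- turns[1, ]
  turn2 <- turns[2, ]

  envm <- envelope(rec$gyr_ml, fs, config$lowpass_hz)
  signed_ml <- lp_filter(rec$gyr_ml, fs, config$lowpass_hz)
  trans <- find_bursts(envm, fs, config$trans_threshold,
                       config$boundary_frac, config$min_peak_gap_s, signed_ml)
  before <- trans[trans$end_s <= turn1$start_s + 0.1, ]
  if (!nrow(before)) {
    abort("transition not found: missing subphase SitToWalk",
          class = "imuperf_segmentation_error")
  }
  sitwalk <- before[nrow(before), ]
  after <- trans[trans$start_s >= turn2$start_s - 0.1, ]
  if (!nrow(after)) {
    abort("transition not found: missing final sit-down of TurnToSit",
          class = "imuperf_segmentation_error")
  }
  sitdown <- after[1, ]

  intervals <- tibble(
    label = c("SitToWalk", "Walk", "Turn180", "Walk",
              "TurnToSitTurning", "TurnToSit"),
    start_s = c(sitwalk$start_s, sitwalk$end_s, turn1$start_s, turn1$end_s,
                turn2$start_s, turn2$start_s),
    end_s = c(sitwalk$end_s, turn1$start_s, turn1$end_s, turn2$start_s,
              turn2$end_s, sitdown$end_s)
  )
  if (any(intervals$end_s <= intervals$start_s)) {
    abort("TUG subphases are not in the expected order.",
          class = "imuperf_segmentation_error")
  }
  step_iv <- intervals[intervals$label %in% c("Walk", "Turn180"), ]
  accv_f <- bp_filter(rec$acc_v - mean(rec$acc_v), fs, config$step_band)
  steps <- sort(unlist(lapply(seq_len(nrow(step_iv)), function(k) {
    count_steps_filtered(accv_f, fs,
                         c(step_iv$start_s[k], step_iv$end_s[k]),
                         config)$times
  })))
  subphase_annotation("TUG", intervals, steps)
}

#' Count steps within an interval
#'
#' Steps are peaks of the band-pass-filtered vertical acceleration inside
#' the interval that exceed an adaptive threshold (a fraction of the
#' interval's 95th absolute percentile, making the count invariant to
#' amplitude scaling), separated by at least `step_min_gap_s`. Near-flat
#' segments yield zero steps.
#'
#' @param rec An [imu_recording()].
#' @param interval Numeric `c(start_s, end_s)` within the recording.
#' @param config A [seg_config()].
#' @return List with `count` and `times` (step times in seconds).
#' @export
count_steps <- function(rec, interval, config = seg_config()) {
  x <- bp_filter(rec$acc_v - mean(rec$acc_v), rec_fs(rec), config$step_band)
  count_steps_filtered(x, rec_fs(rec), interval, config)
}

# step counting on a precomputed band-passed vertical acceleration
count_steps_filtered <- function(x, fs, interval, config) {
  stopifnot(length(interval) == 2, interval[1] < interval[2])
  idx <- interval_indices(interval[1], interval[2], fs, length(x))
  seg <- x[idx[1]:idx[2]]
  amp <- quantile(abs(seg), 0.95, names = FALSE)
  if (amp < 0.05) return(list(count = 0L, times = numeric()))
  threshold <- 0.4 * amp
  n <- length(seg)
  if (n < 3) return(list(count = 0L, times = numeric()))
  is_peak <- c(FALSE, seg[2:(n - 1)] > seg[1:(n - 2)] &
                 seg[2:(n - 1)] >= seg[3:n], FALSE) & seg > threshold
  peaks <- which(is_peak)
  if (!length(peaks)) return(list(count = 0L, times = numeric()))
  # enforce minimum spacing, keeping the taller peak
  keep <- integer()
  for (p in peaks[order(-seg[peaks])]) {
    if (!length(keep) || all(abs(keep - p) >= config$step_min_gap_s * fs)) {
      keep <- c(keep, p)
    }
  }
  keep <- sort(keep)
  times <- (idx[1] + keep - 2L) / fs
  list(count = length(keep), times = times)
}

#' Segment a recording according to its test type
#'
#' Dispatches to [detect_transitions_cst30()] or [segment_tug()].
#'
#' @param rec An [imu_recording()].
#' @param config A [seg_config()].
#' @return A [subphase_annotation()].
#' @export
segment_recording <- function(rec, config = seg_config()) {
  switch(rec_test_type(rec),
         CST30 = detect_transitions_cst30(rec, config),
         TUG = segment_tug(rec, config))
}

# trapezoid-rule integral of a uniformly sampled series
trapz_integral <- function(x, fs) {
  n <- length(x)
  if (n < 2) return(0)
  sum((x[-1] + x[-n]) / 2) / fs
}
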