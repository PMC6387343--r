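#' Canonical instrumented feature registries
#'
#' The 30-s Chair Stand registry has 21 features: the repetition count;
#' mean and SD of the duration of each transition type; normalized jerk
#' scores of the acceleration on the three axes per transition type; RMS
#' of the acceleration on the three axes per transition type; and RMS of
#' the medio-lateral and vertical angular velocity per transition type.
#' The TUG registry has 28: total and four subphase durations; steps while
#' walking and turning; acceleration RMS per axis in sit-to-walk, walk and
#' turn-to-sit; acceleration jerk scores per axis in sit-to-walk and
#' turn-to-sit; and angular jerk score, mean and maximum yaw velocity in
#' the 180° turn and the turning part of the turn-to-sit.
#'
#' @param test `"CST30"`, `"TUG"` or `"all"`.
#' @return Tibble with columns `name`, `test`, `subphase`, `sensor`,
#'   `axis`, `statistic`.
#' @export
feature_registry <- function(test = c("all", "CST30", "TUG")) {
  test <- match.arg(test)
  if (!is.null(.registry_cache[[test]])) return(.registry_cache[[test]])
  reg <- build_feature_registry()
  out <- if (test == "all") reg else reg[reg$test == test, ]
  .registry_cache[[test]] <- out
  out
}

.registry_cache <- new.env(parent = emptyenv())

build_feature_registry <- function() {
  cst_phases <- c(sts = "SitToStand", st2si = "StandToSit")
  axes <- c(ap = "AP", ml = "ML", v = "V")
  cst <- bind_rows(
    tibble(name = "cst_repetitions", subphase = "Total", sensor = "acc",
           axis = "none", statistic = "repetitions"),
    bind_rows(lapply(names(cst_phases), function(p) tibble(
      name = paste0("cst_", p, c("_duration_mean", "_duration_sd")),
      subphase = cst_phases[[p]], sensor = "acc", axis = "none",
      statistic = c("duration", "sd_duration")))),
    bind_rows(lapply(names(cst_phases), function(p) tibble(
      name = paste0("cst_", p, "_njs_", names(axes)),
      subphase = cst_phases[[p]], sensor = "acc", axis = unname(axes),
      statistic = "njs"))),
    bind_rows(lapply(names(cst_phases), function(p) tibble(
      name = paste0("cst_", p, "_rms_acc_", names(axes)),
      subphase = cst_phases[[p]], sensor = "acc", axis = unname(axes),
      statistic = "rms"))),
    bind_rows(lapply(names(cst_phases), function(p) tibble(
      name = paste0("cst_", p, "_rms_gyr_", c("ml", "v")),
      subphase = cst_phases[[p]], sensor = "gyr", axis = c("ML", "V"),
      statistic = "rms")))
  )
  cst$test <- "CST30"
  tug_phases <- c(sitwalk = "SitToWalk", walk = "Walk", turn = "Turn180",
                  turnsit = "TurnToSit")
  tug <- bind_rows(
    tibble(name = "tug_total_duration", subphase = "Total", sensor = "acc",
           axis = "none", statistic = "total_duration"),
    tibble(name = paste0("tug_", names(tug_phases), "_duration"),
           subphase = unname(tug_phases), sensor = "acc", axis = "none",
           statistic = "duration"),
    tibble(name = c("tug_walk_steps", "tug_turn_steps"),
           subphase = c("Walk", "Turn180"), sensor = "acc", axis = "V",
           statistic = "steps"),
    bind_rows(lapply(c("sitwalk", "walk", "turnsit"), function(p) tibble(
      name = paste0("tug_", p, "_rms_acc_", names(axes)),
      subphase = tug_phases[[p]], sensor = "acc", axis = unname(axes),
      statistic = "rms"))),
    bind_rows(lapply(c("sitwalk", "turnsit"), function(p) tibble(
      name = paste0("tug_", p, "_njs_", names(axes)),
      subphase = tug_phases[[p]], sensor = "acc", axis = unname(axes),
      statistic = "njs"))),
    tibble(name = c("tug_turn_angular_njs", "tug_tts_angular_njs"),
           subphase = c("Turn180", "TurnToSitTurning"), sensor = "gyr",
           axis = "V", statistic = "angular_njs"),
    tibble(name = c("tug_turn_mean_velocity", "tug_tts_mean_velocity"),
           subphase = c("Turn180", "TurnToSitTurning"), sensor = "gyr",
           axis = "V", statistic = "mean_velocity"),
    tibble(name = c("tug_turn_max_velocity", "tug_tts_max_velocity"),
           subphase = c("Turn180", "TurnToSitTurning"), sensor = "gyr",
           axis = "V", statistic = "max_velocity")
  )
  tug$test <- "TUG"
  bind_rows(cst, tug)[, c("name", "test", "subphase", "sensor",
                          "axis", "statistic")]
}

#' Root mean square of a mean-removed signal segment
#'
#' \deqn{RMS = \sqrt{\frac{1}{N}\sum_{i=1}^{N}(s_i - m)^2}, \quad m = mean(s)}
#' i.e. the standard deviation with 1/N normalization — a measure of
#' movement intensity unaffected by a static offset such as gravity.
#'
#' @param x Numeric signal segment (length >= 2).
#' @return Non-negative scalar in the units of `x`.
#' @export
#' @examples
#' compute_rms(c(1, 2, 3)) # sqrt(2/3)
compute_rms <- function(x) {
  if (length(x) < 2) {
    abort("RMS needs at least 2 samples.", class = "imuperf_degenerate_input")
  }
  sqrt(mean((x - mean(x))^2))
}

#' Time-normalized jerk score of an acceleration segment
#'
#' \deqn{NJS = \sqrt{\frac{T^5}{2}\int_{T_{start}}^{T_{end}} \dot a^2\,dt}}
#' with \eqn{T} the segment duration. The jerk \eqn{\dot a} is computed by
#' central differences (one-sided at the ends) and the integral by the
#' trapezoid rule. With acceleration in m/s² the score has units of
#' metres; smoother movements give smaller scores. The square root makes
#' the score scale linearly with acceleration amplitude.
#'
#' @param a Acceleration segment, m/s² (length >= 3).
#' @param fs Sampling rate, Hz.
#' @return Non-negative scalar (m).
#' @export
compute_njs <- function(a, fs) {
  n <- length(a)
  if (n < 3) {
    abort("NJS needs at least 3 samples.", class = "imuperf_degenerate_input")
  }
  dt <- 1 / fs
  jerk <- numeric(n)
  jerk[2:(n - 1)] <- (a[3:n] - a[1:(n - 2)]) / (2 * dt)
  jerk[1] <- (a[2] - a[1]) / dt
  jerk[n] <- (a[n] - a[n - 1]) / dt
  T_dur <- (n - 1) * dt
  sqrt(T_dur^5 / 2 * trapz_integral(jerk^2, fs))
}

#' Normalized angular jerk score of a turn
#'
#' \deqn{NJS = \sqrt{\frac{T^5}{2\,TA^2}\int_{T_{start}}^{T_{end}} \ddot\omega^2\,dt},
#'   \qquad TA = \int \omega\,dt}
#' a dimensionless shape functional of the yaw-rate profile: invariant to
#' both the turn's amplitude and duration, it isolates the smoothness of
#' the turning movement. The second derivative of \eqn{\omega} uses
#' central differences (endpoint values replicated from the nearest
#' interior point).
#'
#' @param w Angular-velocity segment, °/s (length >= 4).
#' @param fs Sampling rate, Hz.
#' @param ta_tol Turning angles below this magnitude (°) raise an
#'   undefined-feature error.
#' @return Non-negative dimensionless scalar.
#' @export
compute_angular_njs <- function(w, fs, ta_tol = 1) {
  n <- length(w)
  if (n < 4) {
    abort("angular NJS needs at least 4 samples.",
          class = "imuperf_degenerate_input")
  }
  dt <- 1 / fs
  ta <- trapz_integral(w, fs)
  if (abs(ta) < ta_tol) {
    abort("turning angle too small: angular NJS undefined.",
          class = "imuperf_undefined_feature")
  }
  wdd <- numeric(n)
  wdd[2:(n - 1)] <- (w[3:n] - 2 * w[2:(n - 1)] + w[1:(n - 2)]) / dt^2
  wdd[1] <- wdd[2]
  wdd[n] <- wdd[n - 1]
  T_dur <- (n - 1) * dt
  sqrt(T_dur^5 / (2 * ta^2) * trapz_integral(wdd^2, fs))
}

#' Turn kinematics: turning angle, mean and maximum yaw velocity
#'
#' The turning angle is the trapezoid-rule integral of the yaw rate over
#' the turn; the mean velocity is the arithmetic mean of the samples
#' between the turn boundaries; the maximum is reported as a magnitude,
#' irrespective of turn direction.
#'
#' @param w Vertical angular-velocity segment, °/s.
#' @param fs Sampling rate, Hz.
#' @return Tibble with `turning_angle` (°), `mean_velocity` and
#'   `max_velocity` (°/s).
#' @export
compute_turn_kinematics <- function(w, fs) {
  if (!length(w)) {
    abort("empty turn segment.", class = "imuperf_degenerate_input")
  }
  tibble(
    turning_angle = trapz_integral(w, fs),
    mean_velocity = mean(w),
    max_velocity = max(abs(w))
  )
}

axis_column <- function(sensor, axis) {
  paste0(sensor, "_", tolower(axis))
}

#' Extract the 21 instrumented 30-s Chair Stand features
#'
#' Per-transition features (duration, acceleration NJS per axis,
#' acceleration RMS per axis, gyroscope ML/V RMS) are computed for every
#' detected transition and then averaged within the sit-to-stand and
#' stand-to-sit subphase types; duration SDs use the n-1 denominator.
#' The repetition count is the number of sit-to-stand intervals. With a
#' single repetition the SD features are missing; with none, every feature
#' is missing and the count is 0.
#'
#' @param rec An [imu_recording()] (`CST30`).
#' @param ann Its [subphase_annotation()].
#' @return One-row tibble with the columns of
#'   `feature_registry("CST30")$name`.
#' @export
extract_cst30_features <- function(rec, ann) {
  reg <- feature_registry("CST30")
  out <- setNames(as.list(rep(NA_real_, nrow(reg))), reg$name)
  fs <- rec_fs(rec)
  iv <- ann$intervals
  out$cst_repetitions <- sum(iv$label == "SitToStand")
  phases <- c(sts = "SitToStand", st2si = "StandToSit")
  for (p in names(phases)) {
    sub <- iv[iv$label == phases[[p]], ]
    if (!nrow(sub)) next
    durs <- sub$end_s - sub$start_s
    out[[paste0("cst_", p, "_duration_mean")]] <- mean(durs)
    out[[paste0("cst_", p, "_duration_sd")]] <-
      if (nrow(sub) > 1) sd(durs) else NA_real_
    segs <- lapply(seq_len(nrow(sub)), function(k)
      slice_interval(rec, sub$start_s[k], sub$end_s[k]))
    for (ax in c("ap", "ml", "v")) {
      out[[paste0("cst_", p, "_njs_", ax)]] <-
        mean(vapply(segs, function(s) compute_njs(s[[paste0("acc_", ax)]], fs),
                    numeric(1)))
      out[[paste0("cst_", p, "_rms_acc_", ax)]] <-
        mean(vapply(segs, function(s) compute_rms(s[[paste0("acc_", ax)]]),
                    numeric(1)))
    }
    for (ax in c("ml", "v")) {
      out[[paste0("cst_", p, "_rms_gyr_", ax)]] <-
        mean(vapply(segs, function(s) compute_rms(s[[paste0("gyr_", ax)]]),
                    numeric(1)))
    }
  }
  if (out$cst_repetitions == 0) {
    out[setdiff(names(out), "cst_repetitions")] <- NA_real_
  }
  as_tibble(out)
}

#' Extract the 28 instrumented TUG features
#'
#' Total and subphase durations; step counts while walking (both straight
#' segments concatenated) and during the 180° turn; acceleration RMS per
#' axis in sit-to-walk, walk and turn-to-sit; acceleration jerk scores in
#' sit-to-walk and turn-to-sit; and angular jerk score, mean and maximum
#' yaw velocity in the two turns. Walk features concatenate the samples of
#' the two straight-walk intervals. A missing subphase leaves its features
#' missing.
#'
#' @param rec An [imu_recording()] (`TUG`).
#' @param ann Its [subphase_annotation()].
#' @param config A [seg_config()] (used for step detection).
#' @return One-row tibble with the columns of `feature_registry("TUG")$name`.
#' @export
extract_tug_features <- function(rec, ann, config = seg_config()) {
  reg <- feature_registry("TUG")
  out <- setNames(as.list(rep(NA_real_, nrow(reg))), reg$name)
  fs <- rec_fs(rec)
  iv <- ann$intervals
  one <- function(lbl) {
    s <- iv[iv$label == lbl, ]
    if (nrow(s)) s else NULL
  }
  sitwalk <- one("SitToWalk"); turn <- one("Turn180")
  tts <- one("TurnToSitTurning"); turnsit <- one("TurnToSit")
  walks <- iv[iv$label == "Walk", ]

  if (!is.null(sitwalk) && !is.null(turnsit)) {
    out$tug_total_duration <- max(turnsit$end_s) - min(sitwalk$start_s)
  }
  durs <- list(sitwalk = sitwalk, turn = turn, turnsit = turnsit)
  for (p in names(durs)) {
    if (!is.null(durs[[p]])) {
      out[[paste0("tug_", p, "_duration")]] <-
        sum(durs[[p]]$end_s - durs[[p]]$start_s)
    }
  }
  accv_f <- bp_filter(rec$acc_v - mean(rec$acc_v), fs, config$step_band)
  if (nrow(walks)) {
    out$tug_walk_duration <- sum(walks$end_s - walks$start_s)
    out$tug_walk_steps <- sum(vapply(seq_len(nrow(walks)), function(k)
      count_steps_filtered(accv_f, fs, c(walks$start_s[k], walks$end_s[k]),
                           config)$count,
      integer(1)))
    walk_seg <- bind_rows(lapply(seq_len(nrow(walks)), function(k)
      slice_interval(rec, walks$start_s[k], walks$end_s[k])))
    for (ax in c("ap", "ml", "v")) {
      out[[paste0("tug_walk_rms_acc_", ax)]] <-
        compute_rms(walk_seg[[paste0("acc_", ax)]])
    }
  }
  if (!is.null(turn)) {
    out$tug_turn_steps <-
      count_steps_filtered(accv_f, fs, c(turn$start_s[1], turn$end_s[1]),
                           config)$count
  }
  for (p in c("sitwalk", "turnsit")) {
    s <- if (p == "sitwalk") sitwalk else turnsit
    if (is.null(s)) next
    seg <- slice_interval(rec, s$start_s[1], s$end_s[1])
    for (ax in c("ap", "ml", "v")) {
      out[[paste0("tug_", p, "_rms_acc_", ax)]] <-
        compute_rms(seg[[paste0("acc_", ax)]])
      out[[paste0("tug_", p, "_njs_", ax)]] <-
        compute_njs(seg[[paste0("acc_", ax)]], fs)
    }
  }
  turn_feats <- list(turn = turn, tts = tts)
  for (p in names(turn_feats)) {
    s <- turn_feats[[p]]
    if (is.null(s)) next
    seg <- slice_interval(rec, s$start_s[1], s$end_s[1])
    kin <- compute_turn_kinematics(seg$gyr_v, fs)
    out[[paste0("tug_", p, "_mean_velocity")]] <- abs(kin$mean_velocity)
    out[[paste0("tug_", p, "_max_velocity")]] <- kin$max_velocity
    out[[paste0("tug_", p, "_angular_njs")]] <- tryCatch(
      compute_angular_njs(seg$gyr_v, fs),
      imuperf_undefined_feature = function(e) NA_real_
    )
  }
  as_tibble(out)
}

#' Build the per-subject feature table of a cohort
#'
#' Segments every recording (or uses the generator's ground truth when
#' `use_truth = TRUE`), extracts the canonical 30CST and TUG feature sets,
#' and joins the standard clinical measures from the cohort table.
#' Recordings whose segmentation fails yield missing features for the
#' affected test, never silent zeros.
#'
#' @param cohort An `imu_cohort` from [generate_cohort()], or a recordings
#'   tibble of the same shape.
#' @param config A [seg_config()].
#' @param use_truth Use the generator's ground-truth annotation instead of
#'   running segmentation.
#' @return A tibble with `subject_id`, the 49 instrumented features and
#'   the standard clinical measures `cst30_repetitions_manual`,
#'   `tug_duration_manual` (when present in the cohort table).
#' @export
extract_features <- function(cohort, config = seg_config(), use_truth = FALSE) {
  recs <- if (inherits(cohort, "imu_cohort")) cohort$recordings else cohort
  rows <- lapply(split(seq_len(nrow(recs)), recs$subject_id), function(ix) {
    row <- tibble(subject_id = recs$subject_id[ix[1]])
    for (k in ix) {
      rec <- recs$recording[[k]]
      ann <- tryCatch(
        if (use_truth && !is.null(rec_truth(rec))) rec_truth(rec)
        else segment_recording(rec, config),
        imuperf_segmentation_error = function(e) NULL
      )
      feats <- if (recs$test_type[k] == "CST30") {
        if (is.null(ann)) empty_feature_row("CST30")
        else extract_cst30_features(rec, ann)
      } else {
        if (is.null(ann)) empty_feature_row("TUG")
        else extract_tug_features(rec, ann, config)
      }
      row <- dplyr::bind_cols(row, feats)
    }
    row
  })
  out <- bind_rows(rows)
  if (inherits(cohort, "imu_cohort")) {
    out <- dplyr::left_join(
      out,
      select(cohort$cohort, "subject_id", dplyr::any_of(
        c("cst30_repetitions_manual", "tug_duration_manual"))),
      by = "subject_id"
    )
  }
  out
}

empty_feature_row <- function(test) {
  reg <- feature_registry(test)
  as_tibble(setNames(as.list(rep(NA_real_, nrow(reg))), reg$name))
}
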