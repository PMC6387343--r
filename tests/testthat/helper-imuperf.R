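# shared fixtures, all generated in code

# deterministic subject parameters without random draws
fixed_params <- function(sts = 1.0, sts_sd = 0, st2si = 1.0,
                         stand_hold = 1.0, sit_hold = 1.0,
                         turn_peak = 160, tts_peak = 145,
                         cadence = 2, gait = 1.5,
                         walk_time = 2.5, gyr_sts = 70, gyr_st2si = 70,
                         noise_acc = 0, noise_gyr = 0, id = "T001") {
  structure(list(
    subject_id = id, group_latent = 0.5,
    sts_duration_mean = sts, sts_duration_sd = sts_sd,
    st2si_duration_mean = st2si, stand_hold = stand_hold,
    sit_hold = sit_hold, turn_peak_velocity = turn_peak,
    tts_peak_velocity = tts_peak, cadence = cadence, gait_intensity = gait, walk_time = walk_time,
    gyr_amp_sts = gyr_sts, gyr_amp_st2si = gyr_st2si,
    acc_amp_ap = 1.2, acc_amp_ml = 0.4, acc_amp_v = 0.8,
    noise_sd_acc = noise_acc, noise_sd_gyr = noise_gyr, tilt_max = 0.25
  ), class = "subject_params")
}

quiet_recording <- function(duration = 10, fs = 100, test_type = "CST30") {
  n <- round(duration * fs) + 1
  imu_recording(
    tibble::tibble(
      t = (seq_len(n) - 1) / fs,
      acc_ap = 0, acc_ml = 0, acc_v = 9.81,
      gyr_ap = 0, gyr_ml = 0, gyr_v = 0
    ),
    subject_id = "Q001", test_type = test_type, fs = fs
  )
}

# cache expensive cohorts across tests within a run
.fixture_env <- new.env()
cached_cohort <- function(n, seed, effects = numeric(), noise = NULL) {
  key <- paste0("coh_", n, "_", seed, "_",
                paste(names(effects), effects, collapse = "_"))
  if (is.null(.fixture_env[[key]])) {
    spec <- cohort_spec(n_subjects = n, seed = seed, effect_sizes = effects)
    .fixture_env[[key]] <- generate_cohort(spec)
  }
  .fixture_env[[key]]
}

# independent logistic log-likelihood maximiser (oracle for glm fits)
oracle_logistic <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  nll <- function(beta) {
    eta <- drop(X1 %*% beta)
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  gr <- function(beta) {
    p <- stats::plogis(drop(X1 %*% beta))
    drop(crossprod(X1, p - y))
  }
  opt <- stats::optim(rep(0, ncol(X1)), nll, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  opt$par
}

# brute-force VIF via explicit per-feature R^2 regressions
oracle_vif <- function(X) {
  vapply(seq_len(ncol(X)), function(j) {
    others <- X[, -j, drop = FALSE]
    fit <- stats::lm(X[, j] ~ ., data = as.data.frame(others))
    r2 <- summary(fit)$r.squared
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

interval_midpoints <- function(iv) (iv$start_s + iv$end_s) / 2

# fraction of truth intervals matched by a detected interval of the same
# label within tol seconds (by midpoint)
match_rate <- function(truth, detected, tol = 0.2) {
  if (!nrow(truth)) return(NA_real_)
  hits <- vapply(seq_len(nrow(truth)), function(j) {
    same <- detected[detected$label == truth$label[j], ]
    nrow(same) > 0 &&
      min(abs(interval_midpoints(same) - interval_midpoints(truth[j, ]))) <= tol
  }, logical(1))
  mean(hits)
}
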