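test_that("feature registries have the canonical sizes and disjoint names", {
  reg_cst <- feature_registry("CST30")
  reg_tug <- feature_registry("TUG")
  expect_identical(nrow(reg_cst), 21L)
  expect_identical(nrow(reg_tug), 28L)
  expect_identical(anyDuplicated(c(reg_cst$name, reg_tug$name)), 0L)
})

test_that("RMS follows the mean-removed 1/N formula", {
  expect_equal(compute_rms(c(1, 2, 3)), sqrt(2 / 3), tolerance = 1e-12)
  expect_identical(compute_rms(rep(5, 100)), 0)
  # full-period sine of amplitude A at 100 Hz -> A / sqrt(2)
  t <- seq(0, 1, by = 0.01)[-101]
  for (A in c(1, 3.7)) {
    expect_equal(compute_rms(A * sin(2 * pi * t)), A / sqrt(2),
                 tolerance = 1e-3)
  }
  expect_error(compute_rms(1), class = "imuperf_degenerate_input")
})

test_that("RMS equals an independent two-pass oracle", {
  withr::with_seed(10, {
    for (i in 1:10) {
      x <- rnorm(50 + i, sd = runif(1, 0.1, 10))
      m <- sum(x) / length(x)
      oracle <- sqrt(sum((x - m)^2) / length(x))
      expect_equal(compute_rms(x), oracle, tolerance = 1e-12)
    }
  })
})

test_that("NJS matches analytic values on closed-form signals", {
  fs <- 100
  # constant acceleration: zero jerk
  expect_equal(compute_njs(rep(3, 200), fs), 0)
  # a(t) = t on [0, 1]: NJS = sqrt(1/2)
  tt <- seq(0, 1, by = 1 / fs)
  expect_equal(compute_njs(tt, fs), 1 / sqrt(2), tolerance = 1e-3)
  # homogeneity: scaling the acceleration scales the score
  a <- sin(2 * pi * tt)
  expect_equal(compute_njs(5 * a, fs), 5 * compute_njs(a, fs),
               tolerance = 1e-12)
  expect_error(compute_njs(c(1, 2), fs), class = "imuperf_degenerate_input")
})

test_that("NJS discretization error shrinks with sampling rate", {
  # a(t) = sin(t) on [0, 1]: integral of cos^2 = 1/2 + sin(2)/4
  exact <- sqrt(0.5 * (0.5 + sin(2) / 4))
  for (cfg in list(c(100, 1e-2), c(1000, 1e-4))) {
    fs <- cfg[1]
    tt <- seq(0, 1, by = 1 / fs)
    err <- abs(compute_njs(sin(tt), fs) - exact) / exact
    expect_lt(err, cfg[2])
  }
})

test_that("angular NJS is a pure shape functional of the turn profile", {
  fs <- 100
  shape <- function(peak, dur) {
    tt <- seq(0, dur, by = 1 / fs)
    peak * sin(pi * tt / dur)^2
  }
  base <- compute_angular_njs(shape(100, 2), fs)
  # amplitude invariance
  expect_equal(compute_angular_njs(shape(250, 2), fs), base,
               tolerance = 0.01 * base)
  # duration invariance (time-rescaled copy)
  expect_equal(compute_angular_njs(shape(100, 4), fs), base,
               tolerance = 0.01 * base)
  # constant omega: zero angular jerk
  expect_equal(compute_angular_njs(rep(90, 200), fs), 0)
  # near-zero turning angle: undefined
  tt <- seq(0, 2, by = 1 / fs)
  expect_error(compute_angular_njs(sin(2 * pi * tt), fs),
               class = "imuperf_undefined_feature")
})

test_that("turn kinematics match closed forms", {
  fs <- 100
  w <- rep(90, 2 * fs + 1) # 90 deg/s for 2 s
  kin <- compute_turn_kinematics(w, fs)
  expect_equal(kin$turning_angle, 180, tolerance = 1e-9)
  expect_equal(kin$mean_velocity, 90)
  expect_equal(kin$max_velocity, 90)
  # triangular pulse peaking at 120
  n <- 201
  tri <- 120 * (1 - abs(seq(-1, 1, length.out = n)))
  kin2 <- compute_turn_kinematics(tri, fs)
  expect_equal(kin2$max_velocity, 120)
  expect_equal(kin2$mean_velocity, 60, tolerance = 0.5)
})

test_that("30CST feature extraction matches generator truth", {
  p <- fixed_params(sts = 1, st2si = 1, stand_hold = 1, sit_hold = 1)
  rec <- withr::with_seed(14, simulate_cst30(p))
  feats <- extract_cst30_features(rec, rec_truth(rec))
  expect_identical(ncol(feats), 21L)
  expect_identical(feats$cst_repetitions, 7L)
  expect_lt(abs(feats$cst_sts_duration_mean - 1), 0.1)
  expect_lte(feats$cst_sts_duration_sd, 0.05)
  # extraction is a pure function of its inputs
  expect_identical(feats, extract_cst30_features(rec, rec_truth(rec)))
})

test_that("single-repetition and empty annotations degrade to missing values", {
  p <- fixed_params()
  rec <- withr::with_seed(15, simulate_cst30(p))
  tr <- rec_truth(rec)$intervals
  one_cycle <- subphase_annotation("CST30", tr[1:2, ])
  feats <- extract_cst30_features(rec, one_cycle)
  expect_identical(feats$cst_repetitions, 1L)
  expect_true(is.na(feats$cst_sts_duration_sd))
  expect_false(is.na(feats$cst_sts_duration_mean))
  empty <- subphase_annotation("CST30")
  feats0 <- extract_cst30_features(rec, empty)
  expect_identical(feats0$cst_repetitions, 0L)
  expect_true(all(is.na(feats0[setdiff(names(feats0), "cst_repetitions")])))
})

test_that("TUG feature extraction matches generator truth", {
  p <- fixed_params()
  rec <- withr::with_seed(16, simulate_tug(p))
  tr <- rec_truth(rec)
  feats <- extract_tug_features(rec, tr)
  expect_identical(ncol(feats), 28L)
  iv <- tr$intervals
  true_total <- max(iv$end_s[iv$label == "TurnToSit"]) -
    min(iv$start_s[iv$label == "SitToWalk"])
  expect_lt(abs(feats$tug_total_duration - true_total), 0.05)
  true_walk <- sum(iv$end_s[iv$label == "Walk"] - iv$start_s[iv$label == "Walk"])
  expect_lt(abs(feats$tug_walk_duration - true_walk), 0.05)
  # maximum velocity recovers the rendered peak yaw rate
  true_peak <- rec_truth(rec)$turn_peaks[["Turn180"]]
  expect_lt(abs(feats$tug_turn_max_velocity - true_peak), 0.02 * true_peak)
  # missing subphase leaves its features missing, not zero
  no_turn <- subphase_annotation("TUG",
                                 iv[iv$label != "Turn180", ])
  f2 <- extract_tug_features(rec, no_turn)
  expect_true(is.na(f2$tug_turn_duration))
  expect_true(is.na(f2$tug_turn_max_velocity))
  expect_false(is.na(f2$tug_walk_duration))
})

test_that("extract_features assembles the full per-subject table", {
  coh <- cached_cohort(3, 31)
  feats <- extract_features(coh, use_truth = TRUE)
  expect_identical(nrow(feats), 3L)
  expect_true(all(feature_registry()$name %in% names(feats)))
  expect_true(all(c("cst30_repetitions_manual", "tug_duration_manual") %in%
                    names(feats)))
  # durations positive, RMS and NJS non-negative where present
  reg <- feature_registry()
  for (col in reg$name[reg$statistic %in% c("duration", "total_duration")]) {
    expect_true(all(feats[[col]] > 0, na.rm = TRUE))
  }
  for (col in reg$name[reg$statistic %in% c("rms", "njs", "angular_njs")]) {
    expect_true(all(feats[[col]] >= 0, na.rm = TRUE))
  }
})
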