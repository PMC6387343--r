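test_that("cohort_spec validates its inputs", {
  expect_s3_class(cohort_spec(n_subjects = 2), "cohort_spec")
  expect_error(cohort_spec(n_subjects = 1), class = "imuperf_config_error")
  expect_error(cohort_spec(sampling_rate = 0), class = "imuperf_config_error")
  expect_error(cohort_spec(effect_sizes = c(not_a_param = 1)),
               class = "imuperf_config_error")
})

test_that("effect sizes shift parameter means by d standard deviations", {
  pop <- population_defaults()
  sigma <- pop$sd[pop$param == "sts_duration_mean"]
  spec0 <- cohort_spec(n_subjects = 10, seed = 1)
  spec_d <- cohort_spec(n_subjects = 10, seed = 1,
                        effect_sizes = c(sts_duration_mean = -0.8))
  n <- 2000
  draw_means <- function(spec, latent) {
    withr::with_seed(42, {
      vapply(seq_len(n), function(i)
        draw_subject_params(latent, spec)$sts_duration_mean, numeric(1))
    })
  }
  # null effect: latent 0 and latent 1 give the same distribution
  expect_equal(mean(draw_means(spec0, 0)), mean(draw_means(spec0, 1)),
               tolerance = 1e-12)
  # d = -0.8: latent 1 mean is 0.8 sigma below latent 0 mean
  diff <- mean(draw_means(spec_d, 1)) - mean(draw_means(spec_d, 0))
  se <- sigma * sqrt(2 / n)
  expect_lt(abs(diff - (-0.8 * sigma)), 3 * se)
})

test_that("Monte-Carlo draws recover the stated population mean", {
  pop <- population_defaults()
  spec <- cohort_spec(n_subjects = 10, seed = 1)
  n <- 1000
  vals <- withr::with_seed(7, {
    vapply(seq_len(n), function(i)
      draw_subject_params(0.5, spec)$sts_duration_mean, numeric(1))
  })
  mu <- pop$mean[pop$param == "sts_duration_mean"]
  sigma <- pop$sd[pop$param == "sts_duration_mean"]
  expect_lt(abs(mean(vals) - mu), 3 * sigma / sqrt(n))
})

test_that("30CST cycle packing emits exactly the complete cycles that fit", {
  # 1 s transitions + 1 s holds: 4 s cycle, 30/4 = 7.5 -> 7 up + 7 down
  p <- fixed_params(sts = 1, sts_sd = 0, st2si = 1,
                    stand_hold = 1, sit_hold = 1)
  rec <- withr::with_seed(1, simulate_cst30(p))
  tr <- rec_truth(rec)$intervals
  expect_identical(sum(tr$label == "SitToStand"), 7L)
  expect_identical(sum(tr$label == "StandToSit"), 7L)
  expect_equal(rec_duration(rec), 30)
  # a cycle that cannot fit at all is a configuration error
  p_long <- fixed_params(sts = 12, st2si = 12, stand_hold = 5, sit_hold = 5)
  expect_error(withr::with_seed(1, simulate_cst30(p_long)),
               class = "imuperf_config_error")
})

test_that("noise-free 30CST is quiet outside transitions", {
  p <- fixed_params()
  rec <- withr::with_seed(1, simulate_cst30(p))
  tr <- rec_truth(rec)$intervals
  outside <- rep(TRUE, nrow(rec))
  for (j in seq_len(nrow(tr))) {
    outside[rec$t >= tr$start_s[j] & rec$t <= tr$end_s[j]] <- FALSE
  }
  expect_true(all(rec$gyr_ml[outside] == 0))
  expect_true(all(rec$acc_v[outside] == 9.81))
})

test_that("simulation is bit-identical under the same seed", {
  spec <- cohort_spec(n_subjects = 3, seed = 99)
  p <- withr::with_seed(5, draw_subject_params(0.3, spec))
  r1 <- withr::with_seed(11, simulate_cst30(p))
  r2 <- withr::with_seed(11, simulate_cst30(p))
  expect_identical(r1, r2)
  t1 <- withr::with_seed(12, simulate_tug(p))
  t2 <- withr::with_seed(12, simulate_tug(p))
  expect_identical(t1, t2)
})

test_that("recordings respect sensor clipping ranges", {
  p <- fixed_params(gyr_sts = 400, gyr_st2si = 400, noise_acc = 5,
                    noise_gyr = 60)
  rec <- withr::with_seed(3, simulate_cst30(p))
  expect_true(all(abs(rec$gyr_ml) <= 250))
  expect_true(all(abs(rec$acc_v) <= 19.62))
  expect_true(max(abs(rec$gyr_ml)) == 250) # clipping engaged
})

test_that("TUG truth turns integrate to ~180 degrees and steps match cadence", {
  p <- fixed_params()
  rec <- withr::with_seed(2, simulate_tug(p))
  tr <- rec_truth(rec)$intervals
  fs <- rec_fs(rec)
  for (lbl in c("Turn180", "TurnToSitTurning")) {
    iv <- tr[tr$label == lbl, ]
    idx <- which(rec$t >= iv$start_s & rec$t <= iv$end_s)
    ang <- abs(sum((rec$gyr_v[idx][-1] + rec$gyr_v[idx][-length(idx)]) / 2) / fs)
    expect_gt(ang, 175)
    expect_lt(ang, 185)
  }
  # cadence 2 steps/s: every truth walk second holds ~2 steps
  walks <- tr[tr$label == "Walk", ]
  steps <- rec_truth(rec)$steps
  n_in_walk1 <- sum(steps >= walks$start_s[1] & steps < walks$end_s[1])
  expect_lt(abs(n_in_walk1 - 2 * (walks$end_s[1] - walks$start_s[1])), 1.5)
})

test_that("truth intervals lie within the recording and do not overlap", {
  for (seed in 1:5) {
    coh <- cached_cohort(2, seed)
    for (k in seq_len(nrow(coh$recordings))) {
      rec <- coh$recordings$recording[[k]]
      tr <- rec_truth(rec)$intervals
      expect_true(all(tr$start_s >= 0 & tr$end_s <= rec_duration(rec) + 1e-9))
      for (lbl in unique(tr$label)) {
        iv <- tr[tr$label == lbl, ]
        if (nrow(iv) > 1) {
          iv <- iv[order(iv$start_s), ]
          expect_true(all(iv$start_s[-1] >= iv$end_s[-nrow(iv)] - 1e-9))
        }
      }
    }
  }
})

test_that("generate_cohort is deterministic and respects its contract", {
  c1 <- generate_cohort(cohort_spec(n_subjects = 3, seed = 21))
  c2 <- generate_cohort(cohort_spec(n_subjects = 3, seed = 21))
  expect_identical(c1$cohort, c2$cohort)
  expect_identical(c1$recordings$recording[[1]], c2$recordings$recording[[1]])
  expect_identical(nrow(c1$recordings), 6L)
  expect_true(all(c1$cohort$llfdi >= 0 & c1$cohort$llfdi <= 100))
})

test_that("with zero LLFDI noise the score is strictly monotone in the latent", {
  coh <- generate_cohort(cohort_spec(n_subjects = 20, seed = 13,
                                     llfdi_noise_sd = 0))
  ord <- order(coh$cohort$group_latent)
  expect_true(all(diff(coh$cohort$llfdi[ord]) > 0))
})

test_that("realized dichotomized group difference tracks the injected effect", {
  d <- 0.6
  spec <- cohort_spec(n_subjects = 3000, seed = 3,
                      effect_sizes = c(turn_peak_velocity = d))
  # replicate the generator's latent scheme without rendering signals
  vals <- withr::with_seed(1234, {
    b <- stats::rbinom(3000, 1, 0.5)
    g <- 0.9 * b + 0.1 * stats::runif(3000)
    v <- vapply(g, function(gi)
      draw_subject_params(gi, spec)$turn_peak_velocity, numeric(1))
    list(b = b, v = v)
  })
  realized <- (mean(vals$v[vals$b == 1]) - mean(vals$v[vals$b == 0])) /
    stats::sd(vals$v)
  expect_lt(abs(realized - d), 0.15)
})
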