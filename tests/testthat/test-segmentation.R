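test_that("chair-stand transitions are recovered from noisy recordings", {
  matched <- 0L
  total <- 0L
  for (seed in 1:5) {
    coh <- cached_cohort(2, seed)
    for (k in which(coh$recordings$test_type == "CST30")) {
      rec <- coh$recordings$recording[[k]]
      tr <- rec_truth(rec)$intervals
      ann <- detect_transitions_cst30(rec)
      total <- total + nrow(tr)
      matched <- matched + round(match_rate(tr, ann$intervals, 0.2) * nrow(tr))
      # alternation: consecutive labels always differ
      labs <- ann$intervals$label
      expect_true(all(labs[-1] != labs[-length(labs)]))
    }
  }
  expect_gte(matched / total, 0.95)
})

test_that("noise-free transition durations are recovered within 0.1 s", {
  p <- fixed_params(sts = 1.2, st2si = 1.3, stand_hold = 1, sit_hold = 1)
  rec <- withr::with_seed(4, simulate_cst30(p))
  tr <- rec_truth(rec)$intervals
  ann <- detect_transitions_cst30(rec)
  expect_identical(nrow(ann$intervals), nrow(tr))
  for (j in seq_len(nrow(tr))) {
    det <- ann$intervals[j, ]
    expect_identical(det$label, tr$label[j])
    expect_lt(abs((det$end_s - det$start_s) - (tr$end_s[j] - tr$start_s[j])),
              0.1)
  }
})

test_that("a quiet recording yields an empty annotation with a warning", {
  rec <- quiet_recording(10, test_type = "CST30")
  expect_warning(ann <- detect_transitions_cst30(rec), "no postural transition")
  expect_identical(nrow(ann$intervals), 0L)
})

test_that("too-short recordings are rejected with a structured error", {
  expect_error(detect_transitions_cst30(quiet_recording(3, test_type = "CST30")),
               class = "imuperf_segmentation_error")
  expect_error(segment_tug(quiet_recording(5, test_type = "TUG")),
               class = "imuperf_segmentation_error")
})

test_that("TUG subphases are recovered in order with accurate boundaries", {
  for (seed in 1:5) {
    coh <- cached_cohort(2, seed)
    rec <- coh$recordings$recording[[2]]
    tr <- rec_truth(rec)$intervals
    ann <- segment_tug(rec)
    iv <- ann$intervals
    expect_setequal(unique(iv$label),
                    c("SitToWalk", "Walk", "Turn180", "TurnToSitTurning",
                      "TurnToSit"))
    for (lbl in c("SitToWalk", "Turn180", "TurnToSitTurning", "TurnToSit")) {
      tt <- tr[tr$label == lbl, ][1, ]
      dd <- iv[iv$label == lbl, ][1, ]
      expect_lt(abs(dd$start_s - tt$start_s), 0.3)
      expect_lt(abs(dd$end_s - tt$end_s), 0.3)
    }
    # chronological order and turning sub-interval containment
    sw <- iv[iv$label == "SitToWalk", ]
    t180 <- iv[iv$label == "Turn180", ]
    tts <- iv[iv$label == "TurnToSit", ]
    ttst <- iv[iv$label == "TurnToSitTurning", ]
    expect_lt(sw$start_s, t180$start_s)
    expect_lt(t180$start_s, tts$start_s)
    expect_gte(ttst$start_s, tts$start_s - 1e-9)
    expect_lte(ttst$end_s, tts$end_s + 1e-9)
  }
})

test_that("a TUG without turns raises an error naming the missing subphase", {
  p <- fixed_params()
  rec <- withr::with_seed(5, simulate_tug(p))
  df <- as.data.frame(rec)
  df$gyr_v <- 0
  flat <- imu_recording(df, "X", "TUG", rec_fs(rec))
  expect_error(segment_tug(flat), regexp = "Turn180",
               class = "imuperf_segmentation_error")
})

test_that("detected turn yaw integral is plausible for a 180-degree turn", {
  p <- fixed_params()
  rec <- withr::with_seed(8, simulate_tug(p))
  ann <- segment_tug(rec)
  iv <- ann$intervals[ann$intervals$label == "Turn180", ]
  idx <- which(rec$t >= iv$start_s & rec$t <= iv$end_s)
  fs <- rec_fs(rec)
  ang <- abs(sum((rec$gyr_v[idx][-1] + rec$gyr_v[idx][-length(idx)]) / 2) / fs)
  expect_gte(ang, 150)
  expect_lte(ang, 210)
})

test_that("step counting matches cadence and is amplitude invariant", {
  p <- fixed_params(cadence = 2, walk_time = 5)
  rec <- withr::with_seed(6, simulate_tug(p))
  tr <- rec_truth(rec)$intervals
  w1 <- tr[tr$label == "Walk", ][1, ]
  res <- count_steps(rec, c(w1$start_s, w1$end_s))
  expected <- 2 * (w1$end_s - w1$start_s)
  expect_lte(abs(res$count - expected), 1)
  # doubling the amplitude leaves the adaptive count unchanged
  df <- as.data.frame(rec)
  df$acc_v <- 9.81 + 2 * (df$acc_v - 9.81)
  rec2 <- imu_recording(df, "X", "TUG", rec_fs(rec))
  expect_identical(count_steps(rec2, c(w1$start_s, w1$end_s))$count, res$count)
  # flat signal: zero steps
  expect_identical(count_steps(quiet_recording(10), c(1, 6))$count, 0L)
})

test_that("prepending quiet signal shifts every boundary by the pad length", {
  p <- fixed_params(noise_acc = 0, noise_gyr = 0)
  rec <- withr::with_seed(9, simulate_cst30(p))
  fs <- rec_fs(rec)
  k <- 3
  pad <- tibble::tibble(
    t = (seq_len(k * fs) - 1) / fs,
    acc_ap = 0, acc_ml = 0, acc_v = 9.81, gyr_ap = 0, gyr_ml = 0, gyr_v = 0
  )
  shifted <- dplyr::bind_rows(pad, dplyr::mutate(as.data.frame(rec), t = t + k))
  rec2 <- imu_recording(shifted, "X", "CST30", fs)
  a1 <- detect_transitions_cst30(rec)$intervals
  a2 <- detect_transitions_cst30(rec2)$intervals
  expect_identical(nrow(a1), nrow(a2))
  expect_identical(a1$label, a2$label)
  expect_lt(max(abs(a2$start_s - a1$start_s - k)), 0.03)
  expect_lt(max(abs(a2$end_s - a1$end_s - k)), 0.03)
})
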