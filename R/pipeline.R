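#' Pipeline configuration
#'
#' Collects every tunable constant of the end-to-end analysis: the
#' synthetic-cohort specification, the segmentation settings, and the
#' statistical thresholds (liberal univariable screen at p <= 0.15,
#' stepwise retention at p <= 0.05, VIF threshold 10, spline knots at the
#' 0.1/0.5/0.9 quantiles, bootstrap replicates).
#'
#' @param cohort A [cohort_spec()].
#' @param seg A [seg_config()].
#' @param screen_alpha Univariable screening threshold.
#' @param step_alpha Stepwise retention threshold.
#' @param vif_threshold VIF pruning threshold.
#' @param knot_quantiles Quantiles of the three spline knots.
#' @param boot_B Bootstrap replicates for internal validation (0 skips it).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_spec(), seg = seg_config(),
                            screen_alpha = 0.15, step_alpha = 0.05,
                            vif_threshold = 10,
                            knot_quantiles = c(0.1, 0.5, 0.9),
                            boot_B = 1000) {
  if (screen_alpha <= 0 || screen_alpha >= 1 || step_alpha <= 0 ||
      step_alpha >= 1 || vif_threshold <= 1 ||
      length(knot_quantiles) != 3 || is.unsorted(knot_quantiles) ||
      any(knot_quantiles <= 0) || any(knot_quantiles >= 1) || boot_B < 0) {
    abort("invalid pipeline configuration.", class = "imuperf_config_error")
  }
  structure(list(cohort = cohort, seg = seg, screen_alpha = screen_alpha,
                 step_alpha = step_alpha, vif_threshold = vif_threshold,
                 knot_quantiles = knot_quantiles, boot_B = boot_B),
            class = "pipeline_config")
}

# candidate sets per test: the sensor-derived analogues of the standard
# clinical outcomes are excluded from the instrumented candidates
test_candidates <- function(test) {
  reg <- feature_registry(test)
  if (test == "CST30") {
    list(standard = "cst30_repetitions_manual",
         sensor_standard = "cst_repetitions",
         instrumented = setdiff(reg$name, "cst_repetitions"))
  } else {
    list(standard = "tug_duration_manual",
         sensor_standard = "tug_total_duration",
         instrumented = setdiff(reg$name, "tug_total_duration"))
  }
}

#' Sensitivity analysis: standard, instrumented and combined models
#'
#' For each test, fits (i) the standard clinical model — a univariable
#' logistic regression on the assessor-recorded outcome (chair-stand
#' repetitions or stopwatch TUG duration); (ii) the instrumented model —
#' VIF pruning, univariable screen and stepwise backward selection over
#' the instrumented features, excluding the sensor-derived analogue of
#' the standard outcome; and (iii) the combined model — the instrumented
#' survivors plus that sensor-derived standard measure. The three models
#' are compared pairwise with the DeLong test on the same subjects
#' (listwise deletion over the columns involved).
#'
#' @param features Preprocessed feature table ([preprocess_features()])
#'   including the `*_manual` standard measures.
#' @param group Binary outcome aligned with the rows (HFS/VHFS factor).
#' @param config A [pipeline_config()].
#' @param tests Which tests to analyse.
#' @return A `model_report`: per test, the three `perf_logistic` fits, an
#'   `aucs` tibble and a `delong` tibble with the three pairwise
#'   comparisons.
#' @export
run_sensitivity <- function(features, group, config = pipeline_config(),
                            tests = c("CST30", "TUG")) {
  tbl <- as_tibble(features)
  y <- as_binary_outcome(group)
  out <- list()
  for (test in tests) {
    cand <- test_candidates(test)
    cols <- intersect(c(cand$standard, cand$sensor_standard,
                        cand$instrumented), names(tbl))
    if (!cand$standard %in% names(tbl)) {
      abort(sprintf("feature table lacks the standard measure `%s`.",
                    cand$standard), class = "imuperf_config_error")
    }
    keep <- complete.cases(tbl[, cols, drop = FALSE]) & !is.na(y)
    dat <- tbl[keep, , drop = FALSE]
    yy <- y[keep]

    standard <- fit_logistic_model(dat, yy, cand$standard)
    instrumented <- fit_instrumented_model(
      dat, yy, intersect(cand$instrumented, names(dat)),
      screen_alpha = config$screen_alpha, step_alpha = config$step_alpha,
      vif_threshold = config$vif_threshold)
    combined <- fit_logistic_model(
      dat, yy, unique(c(instrumented$features, cand$sensor_standard)))

    scores <- list(
      standard = predict(standard, dat),
      instrumented = predict(instrumented, dat),
      combined = predict(combined, dat)
    )
    aucs <- bind_rows(lapply(names(scores), function(nm) {
      a <- compute_auc(scores[[nm]], yy)
      mutate(a, model = nm, .before = 1)
    }))
    pairs <- list(c("standard", "instrumented"),
                  c("instrumented", "combined"),
                  c("standard", "combined"))
    delong <- bind_rows(lapply(pairs, function(pr) {
      cmp <- delong_test(scores[[pr[1]]], scores[[pr[2]]], yy)
      tibble(comparison = paste(pr[1], pr[2], sep = " vs "),
             auc_a = cmp$auc_a, auc_b = cmp$auc_b,
             delong_z = cmp$delong_z, delong_p = cmp$delong_p)
    }))
    out[[test]] <- list(
      standard = standard, instrumented = instrumented, combined = combined,
      scores = scores, group = yy, n = sum(keep),
      aucs = aucs, delong = delong
    )
  }
  structure(list(tests = out, config = config), class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  for (test in names(x$tests)) {
    res <- x$tests[[test]]
    cat(sprintf("== %s (n = %d) ==\n", test, res$n))
    cat(sprintf("  instrumented model: %s\n",
                if (res$instrumented$intercept_only) "(intercept only)"
                else paste(res$instrumented$features, collapse = " + ")))
    print(res$aucs)
    print(res$delong)
    if (!is.null(res$validation)) print(res$validation)
  }
  invisible(x)
}

#' Run the full pipeline: simulate, segment, extract, analyse
#'
#' Generates the synthetic cohort, segments every recording, extracts the
#' instrumented features, dichotomizes the LLFDI score at the median,
#' preprocesses (log jerk scores, z-scores), reports the restricted cubic
#' spline linearity check per candidate, fits and compares the standard,
#' instrumented and combined models per test, and (optionally)
#' bootstrap-validates each model with optimism correction. When
#' `out_dir` is given, recordings, annotations, the feature table and the
#' report are written there along with a manifest carrying the seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional artifact directory.
#' @param use_truth Use generator ground-truth annotations instead of
#'   running segmentation (for diagnostics).
#' @param progress Print per-stage progress counts.
#' @return A `model_report` with `cohort`, `features` and `linearity`
#'   fields added.
#' @export
run_end_to_end <- function(config = pipeline_config(), out_dir = NULL,
                           use_truth = FALSE, progress = FALSE) {
  say <- function(...) if (progress) message(sprintf(...))
  coh <- generate_cohort(config$cohort)
  say("simulated %d subjects (%d recordings)", nrow(coh$cohort),
      nrow(coh$recordings))
  feats <- extract_features(coh, config$seg, use_truth = use_truth)
  say("extracted features for %d subjects (%d missing cells)",
      nrow(feats), sum(is.na(feats)))
  cohort <- dichotomize_llfdi(coh$cohort)
  pre <- preprocess_features(feats)
  stopifnot(identical(pre$subject_id, cohort$subject_id))
  group <- cohort$group

  reg <- feature_registry()
  lin <- bind_rows(lapply(intersect(reg$name, names(pre)), function(col) {
    ok <- complete.cases(pre[[col]], group)
    if (sum(ok) < 20) return(NULL)
    res <- check_linearity_rcs(pre[[col]][ok], group[ok],
                               config$knot_quantiles)
    mutate(res, feature = col, .before = 1)
  }))

  report <- run_sensitivity(pre, group, config)
  if (config$boot_B > 0) {
    boot_seed <- subject_seed(config$cohort$seed, 999983L)
    for (test in names(report$tests)) {
      res <- report$tests[[test]]
      cand <- test_candidates(test)
      val <- bind_rows(
        mutate(bootstrap_optimism(
          pre, group, cand$standard, B = config$boot_B, seed = boot_seed,
          vif_threshold = NULL, screen_alpha = 1,
          step_alpha = config$step_alpha),
          model = "standard", .before = 1),
        mutate(bootstrap_optimism(
          pre, group, intersect(cand$instrumented, names(pre)),
          B = config$boot_B, seed = boot_seed + 1L,
          screen_alpha = config$screen_alpha,
          step_alpha = config$step_alpha,
          vif_threshold = config$vif_threshold),
          model = "instrumented", .before = 1)
      )
      report$tests[[test]]$validation <- val
      say("%s: bootstrap validation done (B = %d)", test, config$boot_B)
    }
  }
  report$cohort <- cohort
  report$features <- feats
  report$linearity <- lin
  if (!is.null(out_dir)) write_artifacts(report, coh, out_dir)
  report
}
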