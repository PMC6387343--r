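#' Read and write recordings, annotations, features and reports
#'
#' Recordings are CSV files with header
#' `t,acc_ap,acc_ml,acc_v,gyr_ap,gyr_ml,gyr_v` (one row per sample, `t` in
#' seconds) plus a JSON sidecar carrying `subject_id`, `test_type`, `fs`
#' and, when known, the truth intervals `{label, start_s, end_s}` and step
#' times. Numeric values round-trip at full double precision.
#'
#' @param rec An [imu_recording()].
#' @param path CSV file path; the sidecar sits next to it with extension
#'   `.json`.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   an `imu_recording`.
#' @export
write_recording <- function(rec, path) {
  df <- as.data.frame(rec)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  sidecar <- list(
    subject_id = rec_subject_id(rec),
    test_type = rec_test_type(rec),
    fs = rec_fs(rec)
  )
  truth <- rec_truth(rec)
  if (!is.null(truth)) {
    sidecar$truth <- list(intervals = truth$intervals, steps = truth$steps)
  }
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  df <- utils::read.csv(path)
  required <- c("t", "acc_ap", "acc_ml", "acc_v", "gyr_ap", "gyr_ml", "gyr_v")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort(paste0("recording CSV is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "imuperf_parse_error")
  }
  sc <- sidecar_path(path)
  meta <- if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE)
          else NULL
  fs <- if (!is.null(meta$fs)) meta$fs else 1 / median(diff(df$t))
  truth <- NULL
  if (!is.null(meta$truth)) {
    truth <- subphase_annotation(
      meta$test_type,
      as_tibble(meta$truth$intervals),
      if (is.null(meta$truth$steps)) numeric() else unlist(meta$truth$steps)
    )
  }
  imu_recording(df,
                subject_id = if (is.null(meta$subject_id)) "unknown"
                             else meta$subject_id,
                test_type = if (is.null(meta$test_type)) "CST30"
                            else meta$test_type,
                fs = fs, truth = truth)
}

#' Read and write subphase annotations
#'
#' Annotations serialize as JSON: a list of `{label, start_s, end_s}` plus
#' a `steps` array — the same schema as the generator's truth sidecar.
#'
#' @param ann A [subphase_annotation()].
#' @param path JSON file path.
#' @return `write_annotation()` returns `path` invisibly;
#'   `read_annotation()` a `subphase_annotation`.
#' @export
write_annotation <- function(ann, path) {
  jsonlite::write_json(
    list(test_type = ann$test_type, intervals = ann$intervals,
         steps = ann$steps),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  subphase_annotation(obj$test_type, as_tibble(obj$intervals),
                      if (is.null(obj$steps)) numeric() else unlist(obj$steps))
}

#' Read and write the per-subject feature table
#'
#' One row per subject; the canonical instrumented columns plus the
#' standard clinical measures. On read, unknown columns are dropped with
#' a warning and a missing `subject_id` column is a structured error.
#'
#' @param features Feature table ([extract_features()]).
#' @param path CSV file path.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   a tibble.
#' @export
write_features <- function(features, path) {
  utils::write.csv(format(as.data.frame(features), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- as_tibble(utils::read.csv(path))
  if (!"subject_id" %in% names(df)) {
    abort("features CSV is missing column subject_id.",
          class = "imuperf_parse_error")
  }
  known <- c("subject_id", feature_registry()$name,
             "cst30_repetitions_manual", "tug_duration_manual")
  unknown <- setdiff(names(df), known)
  if (length(unknown)) {
    warn(paste0("ignoring unknown feature column(s): ",
                paste(unknown, collapse = ", ")))
    df <- df[, setdiff(names(df), unknown), drop = FALSE]
  }
  df
}

# serializable summary of a model report
report_summary <- function(report) {
  tests <- lapply(report$tests, function(res) {
    list(
      n = res$n,
      instrumented_features = res$instrumented$features,
      instrumented_trail = res$instrumented$trail,
      coefficients = list(
        standard = res$standard$coefficients,
        instrumented = res$instrumented$coefficients,
        combined = res$combined$coefficients
      ),
      aucs = res$aucs,
      delong = res$delong,
      validation = res$validation
    )
  })
  list(tests = tests,
       config = list(
         n_subjects = report$config$cohort$n_subjects,
         seed = report$config$cohort$seed,
         effect_sizes = as.list(report$config$cohort$effect_sizes),
         screen_alpha = report$config$screen_alpha,
         step_alpha = report$config$step_alpha,
         vif_threshold = report$config$vif_threshold,
         boot_B = report$config$boot_B
       ))
}

#' Write a model report to JSON
#'
#' Serializes the selection trail, coefficients with odds ratios, AUCs
#' with confidence intervals, the pairwise DeLong comparisons and (when
#' run) the bootstrap validation of a [run_sensitivity()] /
#' [run_end_to_end()] report.
#'
#' @param report A `model_report`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report_summary(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

write_artifacts <- function(report, coh, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rec_dir <- file.path(out_dir, "recordings")
  ann_dir <- file.path(out_dir, "annotations")
  dir.create(rec_dir, showWarnings = FALSE)
  dir.create(ann_dir, showWarnings = FALSE)
  for (k in seq_len(nrow(coh$recordings))) {
    rec <- coh$recordings$recording[[k]]
    stem <- sprintf("%s_%s", coh$recordings$subject_id[k],
                    tolower(coh$recordings$test_type[k]))
    write_recording(rec, file.path(rec_dir, paste0(stem, ".csv")))
    ann <- tryCatch(segment_recording(rec, report$config$seg),
                    imuperf_segmentation_error = function(e) NULL)
    if (!is.null(ann)) {
      write_annotation(ann, file.path(ann_dir, paste0(stem, ".json")))
    }
  }
  write_features(report$features, file.path(out_dir, "features.csv"))
  utils::write.csv(report$cohort, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  write_report(report, file.path(out_dir, "report.json"))
  manifest <- list(
    seed = report$config$cohort$seed,
    n_subjects = report$config$cohort$n_subjects,
    config_hash = config_hash(report$config),
    created = "run_end_to_end"
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

# order-stable hash of the deparsed configuration
config_hash <- function(config) {
  txt <- paste(deparse(config[order(names(config))]), collapse = "")
  sum(utf8ToInt(txt) * (seq_len(nchar(txt)) %% 97 + 1)) %% 1e9
}
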