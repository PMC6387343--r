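ACC_CLIP <- 19.62   # m/s^2, +/- 2 g accelerometer range
GYR_CLIP <- 250     # deg/s, gyroscope range
GRAVITY <- 9.81

#' Construct an IMU recording
#'
#' An `imu_recording` is a tibble with one row per sample and columns
#' `t, acc_ap, acc_ml, acc_v, gyr_ap, gyr_ml, gyr_v` (seconds, m/s² and
#' °/s; antero-posterior, medio-lateral and vertical axes of a sensor at
#' the fifth lumbar vertebra). Sampling metadata and, for simulated data,
#' the ground-truth annotation travel as attributes.
#'
#' @param data Data frame with the seven signal columns.
#' @param subject_id Subject identifier.
#' @param test_type `"CST30"` or `"TUG"`.
#' @param fs Sampling rate in Hz.
#' @param truth Optional [subphase_annotation()] with generator ground truth.
#' @return An `imu_recording` tibble.
#' @export
imu_recording <- function(data, subject_id, test_type = c("CST30", "TUG"),
                          fs, truth = NULL) {
  test_type <- match.arg(test_type)
  cols <- c("t", "acc_ap", "acc_ml", "acc_v", "gyr_ap", "gyr_ml", "gyr_v")
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(paste0("recording is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "imuperf_parse_error")
  }
  if (nrow(data) < 2) {
    abort("a recording needs at least 2 samples.", class = "imuperf_parse_error")
  }
  out <- as_tibble(data[cols])
  attr(out, "subject_id") <- subject_id
  attr(out, "test_type") <- test_type
  attr(out, "fs") <- fs
  attr(out, "truth") <- truth
  class(out) <- c("imu_recording", class(tibble()))
  out
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %s  subject %s  %.0f Hz  %.2f s%s\n",
              rec_test_type(x), rec_subject_id(x), rec_fs(x), rec_duration(x),
              if (is.null(rec_truth(x))) "" else "  [with truth]"))
  NextMethod()
}

#' Recording accessors
#'
#' Small helpers reading the metadata attributes of an [imu_recording()].
#'
#' @param rec An `imu_recording`.
#' @return The sampling rate (Hz), duration (s), test type, subject id, or
#'   ground-truth annotation (`NULL` when absent).
#' @export
rec_fs <- function(rec) attr(rec, "fs")

#' @rdname rec_fs
#' @export
rec_duration <- function(rec) (nrow(rec) - 1) / rec_fs(rec)

#' @rdname rec_fs
#' @export
rec_test_type <- function(rec) attr(rec, "test_type")

#' @rdname rec_fs
#' @export
rec_subject_id <- function(rec) attr(rec, "subject_id")

#' @rdname rec_fs
#' @export
rec_truth <- function(rec) attr(rec, "truth")

#' Construct a subphase annotation
#'
#' Labelled, ordered time intervals over a recording: postural transitions
#' for the chair-stand test; sit-to-walk, walking, the 180° turn and the
#' turn-to-sit (with its turning sub-interval) for the TUG. Step times, when
#' detected or known, are carried alongside.
#'
#' @param test_type `"CST30"` or `"TUG"`.
#' @param intervals Tibble with columns `label`, `start_s`, `end_s`.
#' @param steps Numeric vector of step times in seconds.
#' @return A `subphase_annotation` object.
#' @export
subphase_annotation <- function(test_type = c("CST30", "TUG"),
                                intervals = tibble(label = character(),
                                                   start_s = numeric(),
                                                   end_s = numeric()),
                                steps = numeric()) {
  test_type <- match.arg(test_type)
  intervals <- as_tibble(intervals)
  if (nrow(intervals)) {
    if (any(intervals$end_s <= intervals$start_s)) {
      abort("every interval must satisfy start_s < end_s.",
            class = "imuperf_parse_error")
    }
    intervals <- intervals[order(intervals$start_s), ]
  }
  structure(list(test_type = test_type, intervals = intervals,
                 steps = as.numeric(steps)),
            class = "subphase_annotation")
}

#' @export
print.subphase_annotation <- function(x, ...) {
  cat(sprintf("<subphase_annotation> %s  %d interval(s), %d step(s)\n",
              x$test_type, nrow(x$intervals), length(x$steps)))
  print(x$intervals)
  invisible(x)
}

#' Intervals of one label
#' @param ann A [subphase_annotation()].
#' @param label Label to filter on.
#' @return Tibble of matching intervals.
#' @export
ann_intervals <- function(ann, label = NULL) {
  if (is.null(label)) return(ann$intervals)
  ann$intervals[ann$intervals$label == label, ]
}

# half-open [start, end) seconds -> sample index range (floor start, ceil end)
interval_indices <- function(start_s, end_s, fs, n) {
  i1 <- max(1L, floor(start_s * fs) + 1L)
  i2 <- min(n, ceiling(end_s * fs) + 1L)
  c(i1, i2)
}

slice_interval <- function(rec, start_s, end_s) {
  idx <- interval_indices(start_s, end_s, rec_fs(rec), nrow(rec))
  rec[idx[1]:idx[2], , drop = FALSE]
}

clip_recording <- function(df) {
  for (col in c("acc_ap", "acc_ml", "acc_v")) {
    df[[col]] <- pmin(pmax(df[[col]], -ACC_CLIP), ACC_CLIP)
  }
  for (col in c("gyr_ap", "gyr_ml", "gyr_v")) {
    df[[col]] <- pmin(pmax(df[[col]], -GYR_CLIP), GYR_CLIP)
  }
  df
}
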