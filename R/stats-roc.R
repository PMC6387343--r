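# DeLong structural components of the empirical AUC, computed with the
# O(N log N) midrank formulation. For cases X (m of them) and controls Y
# (n), psi(x, y) = 1[x > y] + 0.5 * 1[x == y]; the AUC is the mean of psi
# over all pairs, V10_i its row means and V01_j its column means.
delong_components <- function(scores, labels) {
  y <- as_binary_outcome(labels)
  x_case <- scores[y == 1]
  x_ctrl <- scores[y == 0]
  m <- as.double(length(x_case))
  n <- as.double(length(x_ctrl))
  if (m == 0 || n == 0) {
    abort("both classes must be present to compute an AUC.",
          class = "imuperf_config_error")
  }
  r_all <- rank(c(x_case, x_ctrl), ties.method = "average")
  r_case <- rank(x_case, ties.method = "average")
  r_ctrl <- rank(x_ctrl, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_case) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_ctrl) / m
  auc <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
}

#' Area under the ROC curve with a DeLong confidence interval
#'
#' The AUC is the Mann–Whitney probability that a randomly chosen case
#' scores above a randomly chosen control, ties counted one half. The
#' standard error comes from the variance of the DeLong structural
#' components; the 95% CI uses the normal approximation, clipped to
#' \[0, 1\].
#'
#' @param scores Numeric risk scores.
#' @param labels Binary outcome (factor second level / logical TRUE /
#'   nonzero = case).
#' @param conf_level Confidence level.
#' @return One-row tibble: `auc`, `se`, `ci_lower`, `ci_upper`, `n_case`,
#'   `n_control`.
#' @export
compute_auc <- function(scores, labels, conf_level = 0.95) {
  cmp <- delong_components(scores, labels)
  v <- var(cmp$v10) / cmp$m + var(cmp$v01) / cmp$n
  se <- sqrt(max(v, 0))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble(
    auc = cmp$auc, se = se,
    ci_lower = max(0, cmp$auc - z * se),
    ci_upper = min(1, cmp$auc + z * se),
    n_case = cmp$m, n_control = cmp$n
  )
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two risk scores evaluated on the same subjects,
#' using the covariance of their DeLong structural components. Identical
#' (or rank-identical) scores give a difference of exactly zero and
#' p = 1; a degenerate variance with a non-zero difference yields a
#' missing p-value, flagged.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Shared binary outcome.
#' @return A `roc_comparison`: one-row tibble with `auc_a`, `auc_b`,
#'   `auc_diff`, `delong_z`, `delong_p` and the per-model CIs.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(scores_b))
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / ca$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / ca$n
  d <- ca$auc - cb$auc
  if (abs(d) < 1e-12) {
    z <- 0; p <- 1
  } else if (v <= 1e-14) {
    z <- NA_real_; p <- NA_real_
  } else {
    z <- d / sqrt(v)
    p <- 2 * pnorm(-abs(z))
  }
  aa <- compute_auc(scores_a, labels)
  ab <- compute_auc(scores_b, labels)
  out <- tibble(
    auc_a = ca$auc, auc_a_low = aa$ci_lower, auc_a_high = aa$ci_upper,
    auc_b = cb$auc, auc_b_low = ab$ci_lower, auc_b_high = ab$ci_upper,
    auc_diff = d, delong_z = z, delong_p = p
  )
  class(out) <- c("roc_comparison", class(out))
  out
}

#' Refit the screened stepwise instrumented model on a data set
#'
#' The full instrumented selection pipeline as a function of a data set,
#' as needed for internal validation: iterative VIF pruning, the
#' univariable screen at `screen_alpha`, then stepwise backward selection
#' at `step_alpha`.
#'
#' @param features Data frame with the candidate columns.
#' @param group Binary outcome aligned with the rows.
#' @param candidates Candidate column names.
#' @param screen_alpha,step_alpha Selection thresholds.
#' @param vif_threshold VIF threshold; `NULL` skips pruning.
#' @return A `perf_logistic`.
#' @export
fit_instrumented_model <- function(features, group, candidates,
                                   screen_alpha = 0.15, step_alpha = 0.05,
                                   vif_threshold = 10) {
  tbl <- as_tibble(features)
  cand <- candidates
  if (!is.null(vif_threshold) && length(cand) >= 2) {
    vr <- iterative_vif_prune(tbl[, cand, drop = FALSE], vif_threshold)
    cand <- vr$surviving
  }
  scr <- suppressWarnings(
    univariable_screen(tbl[, cand, drop = FALSE], group, screen_alpha))
  cand <- attr(scr, "selected")
  fit <- suppressWarnings(
    stepwise_backward(tbl, group, candidates = cand, alpha = step_alpha))
  fit
}

#' Bootstrap optimism-corrected AUC with backward step-down reselection
#'
#' Harrell-style internal validation: the entire selection-and-fit
#' pipeline is repeated on `B` bootstrap resamples of the subjects; each
#' resample's model is scored on the resample (apparent) and on the
#' original data (test); the optimism is the mean apparent-minus-test AUC
#' and is subtracted from the apparent AUC of the model fitted on the full
#' data. Resamples with a single outcome class are redrawn (counted).
#'
#' @param features Data frame with the candidate columns.
#' @param group Binary outcome aligned with the rows.
#' @param candidates Candidate column names.
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed for the resampling stream.
#' @param fit_fun Function `(features, group)` returning a
#'   `perf_logistic`; defaults to the full instrumented pipeline on
#'   `candidates`.
#' @param ... Passed to [fit_instrumented_model()] when `fit_fun` is NULL.
#' @return One-row tibble: `apparent_auc`, `optimism`, `corrected_auc`,
#'   `b_effective`, `redraws`.
#' @export
bootstrap_optimism <- function(features, group, candidates, B = 1000,
                               seed = 1L, fit_fun = NULL, ...) {
  tbl <- as_tibble(features)
  y <- as_binary_outcome(group)
  ok <- complete.cases(tbl[, candidates, drop = FALSE]) & !is.na(y)
  tbl <- tbl[ok, , drop = FALSE]
  y <- y[ok]
  if (is.null(fit_fun)) {
    fit_fun <- function(f, g) fit_instrumented_model(f, g, candidates, ...)
  }
  full_fit <- fit_fun(tbl, y)
  full_scores <- predict(full_fit, tbl[, candidates, drop = FALSE])
  apparent <- compute_auc(full_scores, y)$auc
  set.seed(as.integer(seed))
  opt <- numeric(B)
  redraws <- 0L
  b <- 1L
  while (b <= B) {
    idx <- sample.int(length(y), replace = TRUE)
    if (length(unique(y[idx])) < 2) {
      redraws <- redraws + 1L
      if (redraws > 10L * B) {
        abort("bootstrap resampling keeps producing one-class samples.",
              class = "imuperf_config_error")
      }
      next
    }
    fit_b <- tryCatch(fit_fun(tbl[idx, , drop = FALSE], y[idx]),
                      error = function(e) NULL)
    if (is.null(fit_b)) {
      redraws <- redraws + 1L
      next
    }
    sc_boot <- predict(fit_b, tbl[idx, candidates, drop = FALSE])
    sc_orig <- predict(fit_b, tbl[, candidates, drop = FALSE])
    opt[b] <- compute_auc(sc_boot, y[idx])$auc - compute_auc(sc_orig, y)$auc
    b <- b + 1L
  }
  tibble(
    apparent_auc = apparent,
    optimism = mean(opt),
    corrected_auc = apparent - mean(opt),
    b_effective = B,
    redraws = redraws
  )
}
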