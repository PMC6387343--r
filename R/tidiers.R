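#' Tidy a fitted performance model
#'
#' One row per model term with the coefficient, Wald statistics and the
#' odds ratio with its 95% Wald confidence interval.
#'
#' @param x A `perf_logistic`.
#' @param ... Unused.
#' @return A tibble with broom-style columns `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`, `odds.ratio`, `conf.low`,
#'   `conf.high` (CI on the odds-ratio scale).
#' @exportS3Method generics::tidy
#' @export
tidy.perf_logistic <- function(x, ...) {
  dplyr::rename(x$coefficients,
                std.error = "std_error", p.value = "p_value",
                odds.ratio = "odds_ratio", conf.low = "or_low",
                conf.high = "or_high")
}

#' Glance at a fitted performance model
#'
#' @param x A `perf_logistic`.
#' @param ... Unused.
#' @return One-row tibble: `nobs`, `n_features`, `auc`, `auc_low`,
#'   `auc_high`, `deviance`, `aic`, `converged`, `intercept_only`.
#' @exportS3Method generics::glance
#' @export
glance.perf_logistic <- function(x, ...) {
  a <- compute_auc(x$fitted, x$y)
  tibble(
    nobs = length(x$y), n_features = length(x$features),
    auc = a$auc, auc_low = a$ci_lower, auc_high = a$ci_upper,
    deviance = x$model$deviance, aic = x$model$aic,
    converged = x$converged, intercept_only = x$intercept_only
  )
}

#' Tidy a VIF pruning report
#'
#' @param x A `vif_report`.
#' @param ... Unused.
#' @return Tibble of all features with their status: removed (with the
#'   VIF at removal time, in removal order) or surviving (final VIF).
#' @exportS3Method generics::tidy
#' @export
tidy.vif_report <- function(x, ...) {
  bind_rows(
    mutate(x$removed, status = "removed", order = dplyr::row_number()),
    tibble(feature = x$surviving, vif = unname(x$vif_final[x$surviving]),
           status = "surviving", order = NA_integer_)
  )
}

#' Tidy a model report
#'
#' @param x A `model_report`.
#' @param ... Unused.
#' @return Tibble of the pairwise DeLong comparisons across tests.
#' @exportS3Method generics::tidy
#' @export
tidy.model_report <- function(x, ...) {
  bind_rows(lapply(names(x$tests), function(test) {
    mutate(x$tests[[test]]$delong, test = test, .before = 1)
  }))
}

#' Glance at a model report
#'
#' @param x A `model_report`.
#' @param ... Unused.
#' @return Tibble of per-model AUCs with confidence intervals across tests.
#' @exportS3Method generics::glance
#' @export
glance.model_report <- function(x, ...) {
  bind_rows(lapply(names(x$tests), function(test) {
    mutate(x$tests[[test]]$aucs, test = test, .before = 1)
  }))
}
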