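#' Dichotomize the LLFDI function score at the cohort median
#'
#' Subjects with an LLFDI function scaled score at or above the sample
#' median are labelled Very High Functional Status (`VHFS`), the rest High
#' Functional Status (`HFS`). The >= tie rule puts the median itself in
#' the VHFS group, so with ties at the median the split can be uneven.
#'
#' @param cohort Data frame with an `llfdi` column in \[0, 100\].
#' @return The cohort with a `group` factor (`HFS`, `VHFS`) added.
#' @export
#' @examples
#' dichotomize_llfdi(data.frame(llfdi = c(60, 70, 80, 90)))
dichotomize_llfdi <- function(cohort) {
  if (!"llfdi" %in% names(cohort)) {
    abort("cohort has no `llfdi` column.", class = "imuperf_config_error")
  }
  x <- cohort$llfdi
  if (length(unique(x[!is.na(x)])) < 2) {
    abort("all LLFDI values identical: no median split possible.",
          class = "imuperf_config_error")
  }
  med <- median(x, na.rm = TRUE)
  mutate(as_tibble(cohort),
         group = factor(ifelse(.data$llfdi >= med, "VHFS", "HFS"),
                        levels = c("HFS", "VHFS")))
}

#' Preprocess the instrumented feature table for modelling
#'
#' Jerk-score columns (acceleration and angular NJS), whose distributions
#' are right-skewed, are natural-log transformed; every instrumented
#' feature column is then centred and scaled to unit sample SD (computed
#' on its non-missing values), so model coefficients compare on the
#' z-score scale. Standard clinical measure columns (`*_manual`) pass
#' through untouched.
#'
#' @param features Feature table from [extract_features()].
#' @return The standardized table, with attribute `scaling` recording the
#'   per-column centre and scale.
#' @export
preprocess_features <- function(features) {
  tbl <- as_tibble(features)
  reg <- feature_registry()
  feat_cols <- intersect(reg$name, names(tbl))
  if (!length(feat_cols)) {
    extra <- setdiff(names(tbl), c("subject_id", "cst30_repetitions_manual",
                                   "tug_duration_manual"))
    feat_cols <- extra[vapply(tbl[extra], is.numeric, logical(1))]
  }
  njs_cols <- intersect(
    c(reg$name[reg$statistic %in% c("njs", "angular_njs")],
      grep("njs", feat_cols, value = TRUE)),
    feat_cols
  )
  for (col in njs_cols) {
    bad <- which(!is.na(tbl[[col]]) & tbl[[col]] <= 0)
    if (length(bad)) {
      abort(sprintf("non-positive jerk score in column `%s`, row %d: cannot log-transform.",
                    col, bad[1]),
            class = "imuperf_config_error")
    }
    tbl[[col]] <- log(tbl[[col]])
  }
  centre <- scale_ <- setNames(rep(NA_real_, length(feat_cols)), feat_cols)
  for (col in feat_cols) {
    v <- tbl[[col]]
    m <- mean(v, na.rm = TRUE)
    s <- sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      abort(sprintf("feature column `%s` is constant: cannot z-score.", col),
            class = "imuperf_config_error")
    }
    tbl[[col]] <- (v - m) / s
    centre[col] <- m
    scale_[col] <- s
  }
  attr(tbl, "scaling") <- tibble(feature = feat_cols, centre = unname(centre),
                                 scale = unname(scale_),
                                 logged = feat_cols %in% njs_cols)
  tbl
}

# restricted cubic spline basis, 3 knots -> one nonlinear column
rcs_nonlinear_basis <- function(x, knots) {
  stopifnot(length(knots) == 3)
  k1 <- knots[1]; k2 <- knots[2]; k3 <- knots[3]
  pp <- function(u) pmax(u, 0)^3
  (pp(x - k1) - pp(x - k2) * (k3 - k1) / (k3 - k2) +
     pp(x - k3) * (k2 - k1) / (k3 - k2)) / (k3 - k1)^2
}

#' Check linearity of a feature's association on the logit scale
#'
#' Fits a logistic model of the binary group on the feature plus the
#' nonlinear restricted-cubic-spline term built from three knots at the
#' 0.1, 0.5 and 0.9 empirical quantiles, and reports the likelihood-ratio
#' p-value for the nonlinear term. Report-only: the modelling pipeline
#' takes no action on the result.
#'
#' @param x Numeric feature vector.
#' @param group Binary outcome (factor or 0/1), second level = event.
#' @param knot_quantiles Quantiles of the three knots.
#' @return One-row tibble with the knots, `p_nonlinear` and `converged`.
#' @export
check_linearity_rcs <- function(x, group, knot_quantiles = c(0.1, 0.5, 0.9)) {
  y <- as_binary_outcome(group)
  ok <- complete.cases(x, y)
  if (sum(ok) < 20) {
    abort("linearity check needs at least 20 complete observations.",
          class = "imuperf_config_error")
  }
  x <- x[ok]; y <- y[ok]
  knots <- quantile(x, knot_quantiles, names = FALSE, type = 7)
  if (length(unique(knots)) < 3) {
    return(tibble(knot1 = knots[1], knot2 = knots[2], knot3 = knots[3],
                  p_nonlinear = NA_real_, converged = FALSE))
  }
  z <- rcs_nonlinear_basis(x, knots)
  fit <- tryCatch({
    f1 <- glm(y ~ x + z, family = binomial(),
              control = glm.control(epsilon = 1e-8, maxit = 100))
    f0 <- glm(y ~ x, family = binomial(),
              control = glm.control(epsilon = 1e-8, maxit = 100))
    list(f1 = f1, f0 = f0)
  }, warning = function(w) NULL, error = function(e) NULL)
  if (is.null(fit) || !fit$f1$converged || !fit$f0$converged) {
    return(tibble(knot1 = knots[1], knot2 = knots[2], knot3 = knots[3],
                  p_nonlinear = NA_real_, converged = FALSE))
  }
  p <- anova(fit$f0, fit$f1, test = "Chisq")$`Pr(>Chi)`[2]
  tibble(knot1 = knots[1], knot2 = knots[2], knot3 = knots[3],
         p_nonlinear = p, converged = TRUE)
}

compute_vif <- function(X) {
  p <- ncol(X)
  R <- suppressWarnings(stats::cor(X))
  vifs <- tryCatch(diag(solve(R)), error = function(e) NULL)
  if (is.null(vifs) || any(!is.finite(vifs)) || any(vifs < 0)) {
    # singular correlation matrix: fall back to per-feature R^2
    vifs <- vapply(seq_len(p), function(j) {
      fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
      r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
      if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  setNames(vifs, colnames(X))
}

#' Iteratively prune collinear features by the variance inflation factor
#'
#' Computes VIF_j = 1/(1 - R²_j) for every feature (via the diagonal of
#' the inverse correlation matrix; explicit per-feature regressions when
#' the matrix is singular), removes the feature with the largest VIF when
#' it reaches the threshold, and repeats until all VIFs are below the
#' threshold. Ties break to the first feature in column order; perfectly
#' collinear features have infinite VIF and go first.
#'
#' @param features Data frame of numeric candidate features (subject
#'   identifier columns are ignored).
#' @param threshold VIF threshold (default 10).
#' @return A `vif_report`: list with `removed` (tibble of feature and the
#'   VIF at removal time), `surviving` (character), and `vif_final`.
#' @export
iterative_vif_prune <- function(features, threshold = 10) {
  tbl <- select(as_tibble(features), -dplyr::any_of("subject_id"))
  tbl <- tbl[, vapply(tbl, is.numeric, logical(1)), drop = FALSE]
  tbl <- tbl[complete.cases(tbl), , drop = FALSE]
  if (ncol(tbl) < 2) {
    abort("VIF pruning needs at least 2 features.", class = "imuperf_config_error")
  }
  if (nrow(tbl) <= ncol(tbl)) {
    abort("VIF pruning needs more complete observations than features.",
          class = "imuperf_config_error")
  }
  X <- as.matrix(tbl)
  removed <- tibble(feature = character(), vif = numeric())
  while (ncol(X) >= 2) {
    vifs <- compute_vif(X)
    worst <- which.max(vifs) # ties and Inf resolve to the first maximum
    if (vifs[worst] < threshold) break
    removed <- bind_rows(removed,
                         tibble(feature = colnames(X)[worst],
                                vif = unname(vifs[worst])))
    X <- X[, -worst, drop = FALSE]
  }
  final <- if (ncol(X) >= 2) compute_vif(X) else setNames(1, colnames(X))
  structure(list(removed = removed, surviving = colnames(X),
                 vif_final = final, threshold = threshold),
            class = "vif_report")
}

#' @export
print.vif_report <- function(x, ...) {
  cat(sprintf("<vif_report> removed %d feature(s), %d surviving (threshold %g)\n",
              nrow(x$removed), length(x$surviving), x$threshold))
  if (nrow(x$removed)) print(x$removed)
  invisible(x)
}

as_binary_outcome <- function(group) {
  if (is.factor(group)) as.integer(group) - 1L
  else if (is.logical(group)) as.integer(group)
  else if (is.numeric(group)) as.integer(group != 0)
  else as.integer(factor(group)) - 1L
}

fit_logistic <- function(df, outcome = "y") {
  glm(stats::reformulate(setdiff(names(df), outcome), outcome),
      family = binomial(), data = df,
      control = glm.control(epsilon = 1e-8, maxit = 100))
}

#' Univariable logistic screen of candidate features
#'
#' Fits one logistic regression of the group on each candidate feature
#' and keeps features whose Wald p-value is at most `alpha` (default
#' 0.15, a deliberately liberal screen). Features whose fit does not
#' converge are excluded with a warning.
#'
#' @param features Data frame of standardized candidate features.
#' @param group Binary outcome vector aligned with the rows.
#' @param alpha Screening significance level.
#' @return Tibble with `feature`, `estimate`, `p_value`, `selected`,
#'   `converged`; the selected set is `attr(, "selected")`.
#' @export
univariable_screen <- function(features, group, alpha = 0.15) {
  tbl <- select(as_tibble(features), -dplyr::any_of("subject_id"))
  y <- as_binary_outcome(group)
  if (!ncol(tbl)) {
    out <- tibble(feature = character(), estimate = numeric(),
                  p_value = numeric(), converged = logical(),
                  selected = logical())
    attr(out, "selected") <- character(0)
    return(out)
  }
  rows <- lapply(names(tbl), function(col) {
    ok <- complete.cases(tbl[[col]], y)
    res <- tryCatch({
      fit <- suppressWarnings(
        glm(y[ok] ~ x, data = data.frame(x = tbl[[col]][ok]),
            family = binomial(),
            control = glm.control(epsilon = 1e-8, maxit = 100)))
      sm <- summary(fit)$coefficients
      conv <- fit$converged && all(abs(coef(fit)) < 20)
      tibble(feature = col, estimate = sm["x", "Estimate"],
             p_value = sm["x", "Pr(>|z|)"], converged = conv)
    }, error = function(e)
      tibble(feature = col, estimate = NA_real_, p_value = NA_real_,
             converged = FALSE))
    res
  })
  out <- bind_rows(rows)
  if (any(!out$converged)) {
    warn(paste0("screen: non-converged feature(s) excluded: ",
                paste(out$feature[!out$converged], collapse = ", ")))
  }
  out$selected <- out$converged & !is.na(out$p_value) & out$p_value <= alpha
  attr(out, "selected") <- out$feature[out$selected]
  out
}

#' Stepwise backward logistic regression
#'
#' Starting from the screened candidate set, repeatedly refits the
#' multivariable logistic model and drops the feature with the largest
#' Wald p-value while that p-value exceeds `alpha` (default 0.05). When
#' no feature survives an intercept-only model is returned, flagged. A
#' warning is raised when the subjects-per-variable ratio of the starting
#' model is below 10.
#'
#' @param features Data frame holding (at least) the candidate columns.
#' @param group Binary outcome vector aligned with the rows.
#' @param candidates Character vector of candidate column names; defaults
#'   to every numeric column except `subject_id`.
#' @param alpha Retention significance level.
#' @return A `perf_logistic` object: the final `glm` fit plus the
#'   selection trail, per-subject probabilities and odds ratios.
#' @export
stepwise_backward <- function(features, group, candidates = NULL,
                              alpha = 0.05) {
  tbl <- select(as_tibble(features), -dplyr::any_of("subject_id"))
  if (is.null(candidates)) {
    candidates <- names(tbl)[vapply(tbl, is.numeric, logical(1))]
  }
  y <- as_binary_outcome(group)
  df <- tbl[, candidates, drop = FALSE]
  ok <- complete.cases(df) & !is.na(y)
  df <- df[ok, , drop = FALSE]
  yy <- y[ok]
  if (length(candidates) && sum(ok) / length(candidates) < 10) {
    warn(sprintf("only %.1f subjects per candidate variable (< 10).",
                 sum(ok) / length(candidates)))
  }
  trail <- tibble(step = integer(), dropped = character(), p_value = numeric())
  current <- candidates
  step_i <- 0L
  repeat {
    if (!length(current)) break
    dat <- cbind(df[, current, drop = FALSE], y = yy)
    fit <- suppressWarnings(fit_logistic(dat))
    sm <- summary(fit)$coefficients
    feats <- intersect(rownames(sm), current)
    if (!length(feats)) break
    pvals <- sm[feats, "Pr(>|z|)"]
    worst <- which.max(pvals)
    if (pvals[worst] <= alpha) break
    step_i <- step_i + 1L
    trail <- bind_rows(trail, tibble(step = step_i, dropped = feats[worst],
                                     p_value = unname(pvals[worst])))
    current <- setdiff(current, feats[worst])
  }
  new_perf_logistic(df, yy, current, trail, keep_rows = ok)
}

# final (re)fit on a fixed feature set, wrapped with metadata
new_perf_logistic <- function(df, y, features, trail = NULL, keep_rows = NULL) {
  if (length(features)) {
    dat <- cbind(df[, features, drop = FALSE], y = y)
    fit <- suppressWarnings(fit_logistic(dat))
  } else {
    fit <- suppressWarnings(glm(y ~ 1, family = binomial(),
                                data = data.frame(y = y),
                                control = glm.control(epsilon = 1e-8,
                                                      maxit = 100)))
  }
  sm <- summary(fit)$coefficients
  ci <- suppressMessages(suppressWarnings(
    tryCatch(stats::confint.default(fit), error = function(e) NULL)))
  coefs <- tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std_error = sm[, "Std. Error"],
    statistic = sm[, "z value"],
    p_value = sm[, "Pr(>|z|)"],
    odds_ratio = exp(sm[, "Estimate"]),
    or_low = if (is.null(ci)) NA_real_ else exp(ci[, 1]),
    or_high = if (is.null(ci)) NA_real_ else exp(ci[, 2])
  )
  structure(
    list(model = fit, features = features, coefficients = coefs,
         trail = trail, fitted = unname(fit$fitted.values),
         y = y, keep_rows = keep_rows,
         converged = fit$converged && all(abs(coef(fit)) < 20),
         intercept_only = !length(features)),
    class = "perf_logistic"
  )
}

#' Fit a logistic model on a fixed feature set
#'
#' Convenience wrapper used for the standard clinical and combined models,
#' where the feature set is fixed rather than selected.
#'
#' @inheritParams stepwise_backward
#' @param features Data frame holding the columns in `candidates`.
#' @return A `perf_logistic` object.
#' @export
fit_logistic_model <- function(features, group, candidates) {
  tbl <- select(as_tibble(features), -dplyr::any_of("subject_id"))
  y <- as_binary_outcome(group)
  df <- tbl[, candidates, drop = FALSE]
  ok <- complete.cases(df) & !is.na(y)
  new_perf_logistic(df[ok, , drop = FALSE], y[ok], candidates, keep_rows = ok)
}

#' @export
print.perf_logistic <- function(x, ...) {
  cat(sprintf("<perf_logistic> %s%s\n",
              if (x$intercept_only) "intercept-only (no feature survived)"
              else paste(x$features, collapse = " + "),
              if (x$converged) "" else "  [not converged]"))
  print(x$coefficients)
  invisible(x)
}

#' Predicted event probabilities from a fitted performance model
#'
#' @param object A `perf_logistic`.
#' @param newdata Data frame with the model's feature columns; omitted,
#'   the training probabilities are returned.
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.perf_logistic <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  if (object$intercept_only) {
    return(rep(mean(object$y), nrow(newdata)))
  }
  unname(predict(object$model, newdata = as.data.frame(newdata),
                 type = "response"))
}
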