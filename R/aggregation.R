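# Step 4: final models on each imputed data set, Rubin-rule pooling,
# per-patient aggregate risk scores and quantile risk groups.

#' Fit the final model on each imputed data set
#'
#' @param imputed list of `m` completed cohorts.
#' @param forms named list of final [risk_form]s from [refine()].
#' @param time_col,event_col outcome column names.
#' @return list of `m` `cox_fit`s with identical design columns. Any
#'   per-imputation non-convergence aborts with diagnostics.
#' @export
fit_final <- function(imputed, forms, time_col = "time_rfs",
                      event_col = "event_rfs") {
  if (!length(forms)) stop_config("fit_final: empty final variable set")
  lapply(seq_along(imputed), function(j) {
    d <- imputed[[j]]
    X <- apply_forms(d, forms)
    tryCatch(fit_cox(d[[time_col]], d[[event_col]], X),
             error = function(e) stop_config(
               "fit_final: imputation %d failed: %s", j, conditionMessage(e)))
  })
}

#' Pool Cox fits across imputations by Rubin's rules
#'
#' Pooled coefficient = mean of the per-imputation coefficients; pooled
#' variance = mean within-imputation variance + `(1 + 1/m)` times the
#' between-imputation variance. Confidence intervals and p-values use the
#' normal approximation. Hazard ratios can be reported per `hr_scale` units
#' of the design column (the per-100-unit convention for raw-scale
#' continuous biomarkers).
#'
#' @param fits list of `cox_fit`s with identical coefficient names.
#' @param hr_scale named vector of units per reported hazard ratio (default
#'   1 for every column).
#' @param conf_level confidence level of the pooled intervals.
#' @return object of class `aggregated_model`: `pooled_coefficients`,
#'   `pooled_se`, `within_var`, `between_var`, `hazard_ratios` (data frame
#'   with HR, CI, p), `m`, `fits`.
#' @export
rubin_pool <- function(fits, hr_scale = NULL, conf_level = 0.95) {
  m <- length(fits)
  stopifnot(m >= 1)
  nm <- names(fits[[1]]$coefficients)
  for (f in fits)
    if (!identical(names(f$coefficients), nm))
      stop_config("rubin_pool: coefficient name mismatch across fits")
  Q <- do.call(rbind, lapply(fits, `[[`, "coefficients"))
  U <- do.call(rbind, lapply(fits, function(f) diag(f$covariance)))
  qbar <- colMeans(Q)
  ubar <- colMeans(U)
  bvar <- if (m > 1) apply(Q, 2, var) else setNames(rep(0, length(nm)), nm)
  tvar <- ubar + (1 + 1 / m) * bvar
  se <- sqrt(tvar)
  if (is.null(hr_scale)) hr_scale <- setNames(rep(1, length(nm)), nm)
  s <- hr_scale[nm]; s[is.na(s)] <- 1
  z <- qnorm(1 - (1 - conf_level) / 2)
  hr <- data.frame(
    term = nm,
    hr = exp(qbar * s),
    lower = exp((qbar - z * se) * s),
    upper = exp((qbar + z * se) * s),
    p = 2 * pnorm(-abs(qbar / se)),
    units = as.numeric(s), row.names = NULL)
  structure(list(pooled_coefficients = qbar, pooled_se = se,
                 within_var = ubar, between_var = bvar,
                 hazard_ratios = hr, m = m, fits = fits,
                 conf_level = conf_level),
            class = "aggregated_model")
}

#' @export
print.aggregated_model <- function(x, ...) {
  cat(sprintf("<aggregated_model> pooled over m = %d imputations\n", x$m))
  h <- x$hazard_ratios
  h[c("hr", "lower", "upper")] <- round(h[c("hr", "lower", "upper")], 3)
  h$p <- signif(h$p, 2)
  print(h)
  invisible(x)
}

#' Aggregate per-patient risk scores across imputations
#'
#' Each patient's risk score is the mean over imputations of the linear
#' predictor of that imputation's final model evaluated on that imputation's
#' completed data; the standardised score is its z-score over the cohort.
#'
#' @param fits list of `m` `cox_fit`s from [fit_final()].
#' @param imputed list of `m` completed cohorts (aligned by index).
#' @param forms the final [risk_form] list the fits used.
#' @return object of class `risk_scores`: `score`, `standardised`.
#' @export
aggregate_scores <- function(fits, imputed, forms) {
  stopifnot(length(fits) == length(imputed), length(fits) >= 1)
  lp <- 0
  for (j in seq_along(fits)) {
    X <- apply_forms(imputed[[j]], forms)
    lp <- lp + as.numeric(X %*% fits[[j]]$coefficients)
  }
  score <- lp / length(fits)
  structure(list(score = score,
                 standardised = as.numeric(scale(score))),
            class = "risk_scores")
}

#' Split scores into k equally sized risk groups
#'
#' Cutoffs are the empirical `1/k, ..., (k-1)/k` quantiles; a score exactly
#' at a cutoff goes to the lower group (deterministic tie rule). Group 1 is
#' lowest risk.
#'
#' @param scores numeric risk scores.
#' @param k number of groups (4 for the recurrence-free-survival convention,
#'   3 for the on-treatment endpoint).
#' @return integer group labels 1..k with attribute `"cutoffs"`.
#' @export
make_risk_groups <- function(scores, k) {
  stopifnot(k >= 2)
  if (length(unique(scores)) < k)
    stop_config("make_risk_groups: fewer than k distinct score values")
  cuts <- qtl(scores, seq_len(k - 1) / k)
  g <- 1L + rowSums(outer(scores, cuts, ">"))
  attr(g, "cutoffs") <- cuts
  g
}
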