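# Statistical kernel: Cox partial-likelihood fitting, likelihood-ratio tests,
# Kaplan-Meier estimation and the log-rank test. All fitting is delegated to
# the survival package (Efron tie handling); this layer adds the error
# contracts (rank deficiency, monotone likelihood, degenerate inputs) that the
# resampling machinery upstream relies on.

#' Fit a Cox proportional-hazards model on a design matrix
#'
#' Thin, contract-checked wrapper around [survival::coxph.fit()] with Efron
#' tie handling. Coefficients maximise the partial likelihood; the covariance
#' is the inverse observed information.
#'
#' @param time follow-up times (years), non-negative.
#' @param event 0/1 event indicator.
#' @param design numeric matrix of (already transformed) covariates with
#'   unique column names and no missing entries.
#' @return object of class `cox_fit`: `coefficients`, `covariance`,
#'   `loglik_null`, `loglik_fit`, `n_events`, `n_subjects`.
#' @details Errors (never silent garbage): missing values, fewer than 2
#'   events, rank-deficient design, non-convergence, and monotone likelihood
#'   (detected by divergence of a standardised coefficient).
#' @export
fit_cox <- function(time, event, design) {
  design <- as.matrix(design)
  storage.mode(design) <- "double"
  n <- length(time)
  if (is.null(colnames(design)) || anyDuplicated(colnames(design)))
    stop_config("fit_cox: design needs unique column names")
  if (anyNA(time) || anyNA(event) || anyNA(design))
    stop_config("fit_cox: missing values in inputs")
  if (any(time < 0)) stop_config("fit_cox: negative times")
  if (!all(event %in% c(0, 1))) stop_config("fit_cox: event must be 0/1")
  if (nrow(design) != n || length(event) != n)
    stop_config("fit_cox: input length mismatch")
  if (sum(event) < 2) stop_config("fit_cox: fewer than 2 events")
  xsd <- apply(design, 2, sd)
  if (any(xsd == 0))
    stop_config("fit_cox: constant column(s): %s",
                paste(colnames(design)[xsd == 0], collapse = ", "))
  if (qr(cbind(design))$rank < ncol(design))
    stop_config("fit_cox: rank-deficient design")
  # warnings about possibly-infinite coefficients are superseded by the
  # explicit divergence check below
  fit <- suppressWarnings(survival::coxph.fit(design, survival::Surv(time, event),
                             strata = NULL, offset = NULL, init = NULL,
                             control = survival::coxph.control(
                               eps = 1e-09, iter.max = 100),
                             weights = NULL, method = "efron",
                             rownames = NULL, resid = FALSE))
  beta <- fit$coefficients
  if (anyNA(beta) || any(!is.finite(beta)))
    stop_config("fit_cox: non-convergence (undefined coefficients)")
  # monotone likelihood: a coefficient running away on the standardised scale
  # (a standardised log-HR of 10 is far beyond anything estimable)
  if (any(abs(beta) * xsd > 10))
    stop_config("fit_cox: monotone likelihood (coefficient divergence)")
  if (isTRUE(fit$iter >= 100))
    stop_config("fit_cox: Newton-Raphson failed to converge")
  V <- matrix(fit$var, ncol(design), ncol(design),
              dimnames = list(colnames(design), colnames(design)))
  structure(list(coefficients = setNames(as.numeric(beta), colnames(design)),
                 covariance = V,
                 loglik_null = fit$loglik[1], loglik_fit = fit$loglik[2],
                 n_events = as.integer(sum(event)), n_subjects = n),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> %d subjects, %d events, loglik %.3f (null %.3f)\n",
              x$n_subjects, x$n_events, x$loglik_fit, x$loglik_null))
  se <- sqrt(diag(x$covariance))
  print(data.frame(coef = x$coefficients, `exp(coef)` = exp(x$coefficients),
                   se = se, check.names = FALSE))
  invisible(x)
}

# partial log-likelihood of a fixed beta (used for null fits of sub-models)
cox_loglik_at <- function(time, event, design, beta) {
  f <- survival::coxph.fit(as.matrix(design), survival::Surv(time, event),
                           strata = NULL, offset = NULL, init = beta,
                           control = survival::coxph.control(iter.max = 0),
                           weights = NULL, method = "efron",
                           rownames = NULL, resid = FALSE)
  f$loglik[2]
}

#' Likelihood-ratio test between nested Cox fits
#'
#' @param nested,full `cox_fit` objects for nested and encompassing models
#'   fitted to the same data.
#' @param df difference in free parameters.
#' @return p-value: upper tail of chi-square(`df`) at
#'   `2 (loglik_full - loglik_nested)`.
#' @export
lr_test <- function(nested, full, df) {
  ll_n <- if (inherits(nested, "cox_fit")) nested$loglik_fit else as.numeric(nested)
  ll_f <- if (inherits(full, "cox_fit")) full$loglik_fit else as.numeric(full)
  stat <- 2 * (ll_f - ll_n)
  if (stat < -1e-06)
    stop_config("lr_test: full model log-likelihood below nested (%.3g)", stat)
  stopifnot(df >= 1)
  pchisq(max(stat, 0), df = df, lower.tail = FALSE)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time,event follow-up times and 0/1 event indicator.
#' @return object of class `km_fit` with the risk-set table (`time`,
#'   `n_risk`, `n_event`, `surv`); `S(0) = 1`, non-increasing, constant
#'   between event times. Evaluate with [km_surv()].
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1) stop_config("km_estimate: no subjects")
  if (anyNA(time) || anyNA(event)) stop_config("km_estimate: missing values")
  if (any(time < 0)) stop_config("km_estimate: negative times")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, conf.type = "none")
  structure(list(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                 surv = sf$surv, n = length(time)),
            class = "km_fit")
}

#' Evaluate a Kaplan-Meier step function
#'
#' @param km a [km_estimate()] result.
#' @param t times at which to evaluate `S(t)` (right-continuous step).
#' @param extend if `FALSE` (default) times beyond the last follow-up give
#'   `NA`; if `TRUE` the last estimate is carried forward.
#' @return numeric vector of survival probabilities.
#' @export
km_surv <- function(km, t, extend = FALSE) {
  stopifnot(inherits(km, "km_fit"))
  idx <- findInterval(t, km$time)
  s <- ifelse(idx == 0, 1, km$surv[pmax(idx, 1)])
  if (!extend) s[t > max(km$time)] <- NA_real_
  s
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("<km_fit> %d subjects, %d events, %d time points\n",
              x$n, sum(x$n_event), length(x$time)))
  invisible(x)
}

#' Log-rank test
#'
#' @param time,event follow-up times and 0/1 event indicator.
#' @param group group labels (at least two distinct).
#' @return p-value of the k-sample log-rank chi-square test.
#' @export
logrank_test <- function(time, event, group) {
  g <- as.factor(group)
  if (nlevels(droplevels(g)) < 2) stop_config("logrank_test: single group")
  if (sum(event) < 1) stop_config("logrank_test: no events")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  pchisq(sd$chisq, df = length(sd$n) - 1, lower.tail = FALSE)
}

#' Nagelkerke (max-rescaled Cox-Snell) R-squared of a Cox fit
#'
#' `R2_cs = 1 - exp(2 (loglik_null - loglik_fit) / n)`, rescaled by its
#' maximum `1 - exp(2 loglik_null / n)` and clipped to `[0, 1]`. A fit no
#' better than the null model scores 0; 1 indicates perfect prediction.
#'
#' @param fit a `cox_fit` (or any list with `loglik_null`, `loglik_fit`,
#'   `n_subjects`).
#' @return numeric scalar in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(fit) {
  n <- fit$n_subjects
  if (is.null(n) || n < 1) stop_config("nagelkerke_r2: n must be positive")
  r2_cs <- 1 - exp(2 * (fit$loglik_null - fit$loglik_fit) / n)
  r2_max <- 1 - exp(2 * fit$loglik_null / n)
  min(max(r2_cs / r2_max, 0), 1)
}
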