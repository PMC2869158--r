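# Step 2: multiple imputation by chained equations, followed by bootstrap
# resampling of each completed data set. Continuous variables are imputed by
# predictive mean matching (Bayesian regression draw, 5 donors); ordinal
# variables by a proportional-odds draw (MASS::polr, with a PMM fallback when
# the ordinal fit degenerates). Imputation models condition on the other
# candidate variables, the event indicator and the Nelson-Aalen cumulative
# hazard, the standard composition for survival outcomes.

#' Imputation configuration
#'
#' @param m number of imputed data sets (default 10; at least 2 for Rubin
#'   pooling).
#' @param n_iterations chained-equation sweeps per imputation (default 20,
#'   minimum 5).
#' @param donors predictive-mean-matching donor pool size.
#' @param ordinal_max_levels variables with at most this many distinct values
#'   are treated as ordinal and imputed by a proportional-odds draw.
#' @return object of class `imputation_config`.
#' @export
imputation_config <- function(m = 10, n_iterations = 20, donors = 5,
                              ordinal_max_levels = 5) {
  if (m < 2) stop_config("imputation_config: m must be >= 2 for Rubin pooling")
  if (n_iterations < 5) stop_config("imputation_config: need >= 5 iterations")
  structure(list(m = as.integer(m), n_iterations = as.integer(n_iterations),
                 donors = as.integer(donors),
                 ordinal_max_levels = as.integer(ordinal_max_levels)),
            class = "imputation_config")
}

# Nelson-Aalen cumulative hazard at each subject's follow-up time
nelson_aalen <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, conf.type = "none")
  H <- cumsum(sf$n.event / sf$n.risk)
  idx <- findInterval(time, sf$time)
  ifelse(idx == 0, 0, H[pmax(idx, 1)])
}

# Bayesian-draw predictive mean matching (standard mice.impute.pmm recipe):
# draw (sigma, beta) from the posterior of the normal linear model on
# observed rows, match yhat(mis | beta_draw) against yhat(obs | beta_hat),
# impute by sampling one of `donors` nearest observed values.
impute_pmm <- function(y_obs, X_obs, X_mis, donors) {
  X_obs <- cbind(1, X_obs); X_mis <- cbind(1, X_mis)
  f <- lm.fit(X_obs, y_obs)
  keep <- !is.na(f$coefficients)
  Xo <- X_obs[, keep, drop = FALSE]; Xm <- X_mis[, keep, drop = FALSE]
  f <- lm.fit(Xo, y_obs)
  p <- ncol(Xo); nobs <- length(y_obs)
  df <- max(nobs - p, 1)
  sigma2 <- sum(f$residuals^2) / stats::rchisq(1, df)
  XtX <- crossprod(Xo)
  R <- tryCatch(chol(XtX),
                error = function(e) chol(XtX + diag(1e-08 * diag(XtX) + 1e-10)))
  beta_hat <- f$coefficients
  beta_hat[is.na(beta_hat)] <- 0
  beta_draw <- beta_hat + backsolve(R, rnorm(p)) * sqrt(sigma2)
  yhat_obs <- as.numeric(Xo %*% beta_hat)
  yhat_mis <- as.numeric(Xm %*% beta_draw)
  d <- abs(outer(yhat_mis, yhat_obs, "-"))
  k <- min(donors, nobs)
  apply(d, 1, function(row) {
    cand <- order(row)[seq_len(k)]
    y_obs[cand[sample.int(k, 1)]]
  })
}

# proportional-odds draw for ordinal variables; falls back to PMM when the
# polr fit fails (e.g. separation in a small bootstrap or sparse level)
impute_ordinal <- function(y_obs, X_obs, X_mis, donors) {
  lev <- sort(unique(y_obs))
  if (length(lev) < 2) return(rep(lev, nrow(X_mis)))
  fit <- tryCatch({
    df_obs <- data.frame(.y = factor(y_obs, levels = lev), X_obs)
    suppressWarnings(MASS::polr(.y ~ ., data = df_obs, Hess = FALSE))
  }, error = function(e) NULL)
  if (is.null(fit)) return(impute_pmm(y_obs, X_obs, X_mis, donors))
  pr <- tryCatch(stats::predict(fit, newdata = data.frame(X_mis),
                                type = "probs"),
                 error = function(e) NULL)
  if (is.null(pr)) return(impute_pmm(y_obs, X_obs, X_mis, donors))
  pr <- rbind(pr)  # single-row predictions come back as a vector
  lev[apply(pr, 1, function(p) sample.int(length(lev), 1, prob = p))]
}

#' Multiple imputation by chained equations
#'
#' Produces `m` completed copies of the cohort. Missing entries are
#' initialised by random draws from the observed values, then each variable
#' in turn (visit order: increasing missingness) is re-imputed from its
#' conditional model given all other candidate variables plus the event
#' indicator and Nelson-Aalen cumulative hazard; the sweep is repeated
#' `n_iterations` times per chain. Observed entries are never modified.
#'
#' @param cohort data frame with outcome columns complete.
#' @param variables candidate variables to impute / condition on.
#' @param config an [imputation_config()].
#' @param time_col,event_col outcome column names.
#' @param seed integer master seed; chain `j` uses `derive_seed(seed, j)`.
#' @return list of `m` completed data frames.
#' @export
mice_impute <- function(cohort, variables, config = imputation_config(),
                        time_col = "time_rfs", event_col = "event_rfs",
                        seed = 1) {
  stopifnot(inherits(config, "imputation_config"),
            all(variables %in% names(cohort)))
  tt <- cohort[[time_col]]; ee <- cohort[[event_col]]
  if (anyNA(tt) || anyNA(ee)) stop_config("mice_impute: outcomes must be complete")
  frac_mis <- vapply(variables, function(v) mean(is.na(cohort[[v]])), 0)
  if (any(frac_mis >= 1))
    stop_config("mice_impute: variable(s) 100%% missing: %s",
                paste(variables[frac_mis >= 1], collapse = ", "))
  if (any(frac_mis >= 0.5))
    stop_config("mice_impute: variable(s) with >= 50%% missingness: %s",
                paste(variables[frac_mis >= 0.5], collapse = ", "))
  needs <- variables[frac_mis > 0]
  if (!length(needs)) return(replicate(config$m, cohort, simplify = FALSE))
  visit <- needs[order(frac_mis[needs])]
  aux <- cbind(event = ee, cumhaz = nelson_aalen(tt, ee))
  is_ord <- vapply(variables, function(v)
    length(unique(stats::na.omit(cohort[[v]]))) <= config$ordinal_max_levels,
    TRUE)
  lapply(seq_len(config$m), function(j) {
    set.seed(derive_seed(seed, j))
    d <- cohort
    for (v in needs) {             # initialise by random observed draws
      mis <- is.na(d[[v]])
      d[[v]][mis] <- sample(d[[v]][!mis], sum(mis), replace = TRUE)
    }
    for (it in seq_len(config$n_iterations)) {
      for (v in visit) {
        mis <- is.na(cohort[[v]])
        preds <- setdiff(variables, v)
        X <- as.matrix(cbind(d[preds], aux))
        y_obs <- cohort[[v]][!mis]
        imp <- if (is_ord[[v]])
          impute_ordinal(y_obs, X[!mis, , drop = FALSE],
                         X[mis, , drop = FALSE], config$donors)
        else
          impute_pmm(y_obs, X[!mis, , drop = FALSE],
                     X[mis, , drop = FALSE], config$donors)
        d[[v]][mis] <- imp
      }
    }
    d
  })
}

#' Draw bootstrap samples from a completed data set
#'
#' Simple case resampling with replacement, `n` rows per sample. Seeds derive
#' deterministically from `(seed, imputation, b)` so every sample can be
#' re-materialised from its provenance alone.
#'
#' @param completed a completed (no missing values) data frame.
#' @param B number of bootstrap samples.
#' @param seed master seed.
#' @param imputation imputation index used in seed derivation.
#' @return list of `B` elements `list(imputation, bootstrap, rows)`; use
#'   `completed[rows, ]` to materialise.
#' @export
draw_bootstrap <- function(completed, B, seed, imputation = 1L) {
  stopifnot(B >= 1)
  n <- nrow(completed)
  lapply(seq_len(B), function(b) {
    set.seed(derive_seed(seed, imputation, b))
    list(imputation = as.integer(imputation), bootstrap = as.integer(b),
         rows = sample.int(n, n, replace = TRUE))
  })
}

#' Build the full m x B sample set
#'
#' @param imputed list of `m` completed cohorts from [mice_impute()].
#' @param B bootstrap samples per imputation (default 100, so the default
#'   `m = 10` yields 1000 sample data sets).
#' @param seed master seed.
#' @return object of class `sample_set`: `imputed` plus `samples`, a list of
#'   `m * B` provenance records.
#' @export
make_sample_set <- function(imputed, B = 100, seed = 1) {
  samples <- list()
  for (j in seq_along(imputed))
    samples <- c(samples, draw_bootstrap(imputed[[j]], B, seed, j))
  structure(list(imputed = imputed, samples = samples, B = as.integer(B),
                 seed = seed),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> m = %d imputations x B = %d bootstraps = %d samples\n",
              length(x$imputed), x$B, length(x$samples)))
  invisible(x)
}
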