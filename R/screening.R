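# Step 1: univariate screening. Each candidate variable is screened through a
# fixed cascade — fractional-polynomial closed test, then a minimum-p-value
# threshold scan, then non-ordinal quartile dichotomisations — with thresholds
# calibrated so every route corresponds to roughly P = 0.1 in a standard
# univariate Cox model: 0.1 for the FP closed test, 0.005 for the
# multiplicity-prone minimum-p scan, 0.025 (= 0.1 / 4) per non-ordinal
# comparison.

#' Screening configuration
#'
#' @param alpha_fp significance level of the fractional-polynomial closed
#'   test (default 0.1).
#' @param alpha_minp threshold on the minimum p over cutpoints (default
#'   0.005, the calibrated equivalent of a family level of about 0.1).
#' @param alpha_nonordinal per-comparison level of the four non-ordinal
#'   quartile dichotomisations (default `0.1 / 4 = 0.025`, Bonferroni).
#' @param minp_range inner fraction of the empirical distribution scanned for
#'   cutpoints (default 0.8: 10 percent trimmed from each tail).
#' @param min_distinct minimum distinct values for a variable to be treated
#'   as continuous (FP / scan routes); below this it is screened as linear
#'   only.
#' @return object of class `screening_config`.
#' @export
screening_config <- function(alpha_fp = 0.1, alpha_minp = 0.005,
                             alpha_nonordinal = alpha_fp / 4,
                             minp_range = 0.8, min_distinct = 10) {
  stopifnot(alpha_fp > 0, alpha_fp < 1, alpha_minp > 0, alpha_minp < 1,
            alpha_nonordinal > 0, alpha_nonordinal < 1,
            minp_range > 0, minp_range <= 1)
  structure(list(alpha_fp = alpha_fp, alpha_minp = alpha_minp,
                 alpha_nonordinal = alpha_nonordinal,
                 minp_range = minp_range, min_distinct = min_distinct),
            class = "screening_config")
}

screening_result <- function(variable, selected, form, p_value, method,
                             n_available, status = "ok") {
  structure(list(variable = variable, selected = selected, form = form,
                 p_value = p_value, method = method,
                 n_available = n_available, status = status),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("<screening> %s: %s (method %s, p = %.4g, n = %d)%s\n",
              x$variable,
              if (x$selected) format(x$form) else "not selected",
              x$method, x$p_value, x$n_available,
              if (x$status != "ok") paste0(" [", x$status, "]") else ""))
  invisible(x)
}

# all FP1 powers and unordered FP2 power pairs (28 pairs incl. repeats)
fp2_pairs <- function() {
  ps <- FP_POWERS
  out <- list()
  for (i in seq_along(ps)) for (j in i:length(ps))
    out[[length(out) + 1]] <- c(ps[i], ps[j])
  out
}

# maximised partial loglik of x entering via `form`, adjusted for `adjust`
fp_fit_loglik <- function(time, event, x, form, adjust = NULL) {
  cols <- fp_transform(x, form)
  colnames(cols) <- paste0(".fp", seq_len(ncol(cols)))
  X <- if (is.null(adjust)) cols else cbind(cols, adjust)
  tryCatch(fit_cox(time, event, X)$loglik_fit, error = function(e) NA_real_)
}

# best form by maximum partial likelihood over a list of candidate forms
best_fp <- function(time, event, x, forms, adjust = NULL) {
  ll <- vapply(forms, function(f) fp_fit_loglik(time, event, x, f, adjust),
               numeric(1))
  if (all(is.na(ll))) return(NULL)
  k <- which.max(ll)
  list(form = forms[[k]], loglik = ll[[k]])
}

#' Fractional-polynomial closed test for one continuous variable
#'
#' The Royston-Sauerbrei closed testing cascade at level `alpha`:
#' (1) best FP2 against the null model on 4 df — if not significant the
#' variable shows no (polynomial) association; (2) best FP2 against linear on
#' 3 df — if not significant the linear form suffices; (3) best FP2 against
#' best FP1 on 2 df — FP1 if not significant, else FP2. "Best" means maximum
#' partial likelihood over the power set `{-2, -1, 0, 0.5, 1, 2, 3}`.
#'
#' @param time,event survival outcome (complete rows for this variable).
#' @param x covariate values (no missing entries).
#' @param config a [screening_config()]; `alpha` may override `alpha_fp`.
#' @param alpha level of each step of the closed test.
#' @param adjust optional design matrix of adjustment covariates (used by the
#'   multivariable FP refinement); tests are then conditional on it.
#' @param variable name used in the result.
#' @return a `screening_result`; `p_value` is the step-(1) overall
#'   association p (best FP2 vs null, 4 df).
#' @export
fp_closed_test <- function(time, event, x, config = screening_config(),
                           alpha = config$alpha_fp, adjust = NULL,
                           variable = "x") {
  n_avail <- length(x)
  if (length(unique(x)) < config$min_distinct)
    return(screening_result(variable, FALSE, NULL, NA_real_, "fp", n_avail,
                            status = "too few distinct values"))
  sc <- fp_scaling(x)
  lin <- form_linear(scaling = sc)
  fp1s <- lapply(FP_POWERS, function(p) form_fp1(p, scaling = sc))
  fp2s <- lapply(fp2_pairs(), function(pp) form_fp2(pp[1], pp[2], scaling = sc))
  # null model: adjustment only (or empty)
  ll_null <- if (is.null(adjust)) {
    f <- tryCatch(fit_cox(time, event, cbind(.z = x)), error = function(e) NULL)
    if (is.null(f)) return(screening_result(variable, FALSE, NULL, NA_real_,
                                            "fp", n_avail, status = "fit failed"))
    f$loglik_null
  } else {
    f <- tryCatch(fit_cox(time, event, adjust), error = function(e) NULL)
    if (is.null(f)) return(screening_result(variable, FALSE, NULL, NA_real_,
                                            "fp", n_avail, status = "fit failed"))
    f$loglik_fit
  }
  b2 <- best_fp(time, event, x, fp2s, adjust)
  b1 <- best_fp(time, event, x, fp1s, adjust)
  ll_lin <- fp_fit_loglik(time, event, x, lin, adjust)
  if (is.null(b2) || is.null(b1) || is.na(ll_lin))
    return(screening_result(variable, FALSE, NULL, NA_real_, "fp", n_avail,
                            status = "fit failed"))
  p_overall <- lr_test(ll_null, b2$loglik, df = 4)
  if (p_overall >= alpha)
    return(screening_result(variable, FALSE, NULL, p_overall, "fp", n_avail))
  p_nonlin <- lr_test(ll_lin, b2$loglik, df = 3)
  if (p_nonlin >= alpha)
    return(screening_result(variable, TRUE, lin, p_overall, "fp", n_avail))
  p_fp2 <- lr_test(b1$loglik, b2$loglik, df = 2)
  form <- if (p_fp2 >= alpha) b1$form else b2$form
  screening_result(variable, TRUE, form, p_overall, "fp", n_avail)
}

# log-rank chi-square for every cutpoint at once (>= cut vs < cut).
# Returns data.frame(cut, chisq, p). Vectorised over cutpoints via the
# standard O-E / hypergeometric-variance accumulation at each event time.
logrank_scan <- function(time, event, x, cuts) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  n <- length(time)
  Z <- outer(x, cuts, ">=") * 1  # n x m membership of the ">= cut" group
  ev_times <- unique(time[event == 1])
  first_at_risk <- findInterval(ev_times, time, left.open = TRUE) + 1L
  # reverse cumulative sums: at-risk group sizes just before each event time
  rc <- apply(Z[n:1, , drop = FALSE], 2, cumsum)[n:1, , drop = FALSE]
  O <- E <- V <- numeric(length(cuts))
  for (j in seq_along(ev_times)) {
    i0 <- first_at_risk[j]
    nj <- n - i0 + 1
    at <- which(time == ev_times[j] & event == 1)
    dj <- length(at)
    n1 <- rc[i0, ]
    d1 <- if (dj == 1) Z[at, ] else colSums(Z[at, , drop = FALSE])
    O <- O + d1
    E <- E + dj * n1 / nj
    if (nj > 1)
      V <- V + dj * (n1 / nj) * (1 - n1 / nj) * (nj - dj) / (nj - 1)
  }
  chisq <- ifelse(V > 0, (O - E)^2 / V, NA_real_)
  data.frame(cut = cuts, chisq = chisq,
             p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

minp_candidate_cuts <- function(x, minp_range) {
  vals <- sort(unique(x))
  lo <- qtl(x, (1 - minp_range) / 2)
  hi <- qtl(x, 1 - (1 - minp_range) / 2)
  vals <- vals[vals >= lo & vals <= hi]
  # a cut equal to the minimum puts everyone in the ">=" group
  vals[vals > min(x)]
}

#' Minimum-p-value threshold scan
#'
#' Tests the dichotomisation `x >= cut` against `x < cut` with a log-rank
#' test at every candidate cutpoint (the distinct observed values inside the
#' inner `minp_range` of the empirical distribution) and returns the
#' minimising cutpoint. The variable is selected if the minimum p falls below
#' `alpha_minp`, the multiplicity-calibrated level. Ties in p resolve to the
#' smallest cutpoint.
#'
#' @inheritParams fp_closed_test
#' @param alpha selection threshold on the minimum p.
#' @return a `screening_result` with a threshold [risk_form] when selected;
#'   the full scan table is attached as attribute `"scan"`.
#' @export
minp_scan <- function(time, event, x, config = screening_config(),
                      alpha = config$alpha_minp, variable = "x") {
  n_avail <- length(x)
  cuts <- minp_candidate_cuts(x, config$minp_range)
  if (length(cuts) < 2 || sum(event) < 1)
    return(screening_result(variable, FALSE, NULL, NA_real_, "minp", n_avail,
                            status = "too few candidate cutpoints"))
  scan <- logrank_scan(time, event, x, cuts)
  ok <- which(!is.na(scan$p))
  if (!length(ok))
    return(screening_result(variable, FALSE, NULL, NA_real_, "minp", n_avail,
                            status = "degenerate scan"))
  k <- ok[which.min(scan$p[ok])]
  res <- screening_result(variable, scan$p[k] < alpha,
                          form_threshold(scan$cut[k]), scan$p[k], "minp",
                          n_avail)
  if (!res$selected) res$form <- NULL
  attr(res, "scan") <- scan
  attr(res, "best_cut") <- scan$cut[k]
  res
}

nonordinal_patterns <- c("R2", "R3", "R2R3", "R1R3")

#' Non-ordinal quartile dichotomisation scan
#'
#' Performs exactly four comparisons, contrasting quartile ranges of the
#' variable against the remaining cases: R2 vs rest, R3 vs rest, R2+R3 vs
#' rest, and R1+R3 vs rest (log-rank test each). The best (smallest p)
#' pattern is selected iff its p falls below `alpha_nonordinal`, the
#' Bonferroni level 0.1 / 4. Degenerate patterns (a range emptied by ties)
#' are skipped and reported.
#'
#' @inheritParams fp_closed_test
#' @param alpha per-comparison selection threshold.
#' @return a `screening_result` with a non-ordinal [risk_form] when selected.
#' @export
nonordinal_scan <- function(time, event, x, config = screening_config(),
                            alpha = config$alpha_nonordinal, variable = "x") {
  n_avail <- length(x)
  q <- qtl(x, c(0.25, 0.5, 0.75))
  ps <- setNames(rep(NA_real_, 4), nonordinal_patterns)
  skipped <- character(0)
  for (pat in nonordinal_patterns) {
    f <- form_nonordinal(pat, q)
    ind <- form_indicator(x, f)
    if (length(unique(ind)) < 2) { skipped <- c(skipped, pat); next }
    ps[[pat]] <- tryCatch(logrank_test(time, event, ind),
                          error = function(e) NA_real_)
  }
  if (all(is.na(ps)))
    return(screening_result(variable, FALSE, NULL, NA_real_, "nonordinal",
                            n_avail, status = "all patterns degenerate"))
  best <- names(ps)[which.min(ps)]
  status <- if (length(skipped))
    paste("patterns skipped:", paste(skipped, collapse = ",")) else "ok"
  res <- screening_result(variable, ps[[best]] < alpha,
                          form_nonordinal(best, q), ps[[best]], "nonordinal",
                          n_avail, status = status)
  if (!res$selected) res$form <- NULL
  attr(res, "pattern_p") <- ps
  res
}

# linear-only screen for ordinal / few-valued variables (clinical variables)
linear_screen <- function(time, event, x, alpha, variable) {
  n_avail <- length(x)
  f <- tryCatch(fit_cox(time, event, cbind(.z = x)), error = function(e) NULL)
  if (is.null(f))
    return(screening_result(variable, FALSE, NULL, NA_real_, "linear",
                            n_avail, status = "fit failed"))
  p <- lr_test(f$loglik_null, f$loglik_fit, df = 1)
  res <- screening_result(variable, p < alpha, form_linear(), p, "linear",
                          n_avail)
  if (!res$selected) res$form <- NULL
  res
}

#' Screen all candidate variables through the selection cascade
#'
#' Each continuous variable passes through the fixed cascade: FP closed test;
#' if unselected, minimum-p threshold scan; if still unselected, non-ordinal
#' quartile scan. Variables with fewer than `min_distinct` distinct values
#' (ordinal clinical variables) are screened with a plain linear Cox test at
#' `alpha_fp`. Screening is univariate on the rows with the variable
#' observed; transformations (scalings, cutpoints, quartiles) are frozen from
#' this data for all later stages.
#'
#' @param data data frame with outcome columns and candidate variables;
#'   missing covariate values allowed (rows dropped per variable).
#' @param time_col,event_col names of the outcome columns.
#' @param variables character vector of candidate variable names.
#' @param config a [screening_config()].
#' @return object of class `screening_table`: list of `screening_result`s
#'   (exactly one per variable, in input order). Convert with
#'   [as.data.frame()].
#' @export
screen_all <- function(data, variables, time_col = "time_rfs",
                       event_col = "event_rfs", config = screening_config()) {
  stopifnot(all(c(time_col, event_col) %in% names(data)))
  absent <- setdiff(variables, names(data))
  if (length(absent))
    stop_config("screen_all: variables absent from data: %s",
                paste(absent, collapse = ", "))
  out <- vector("list", length(variables))
  names(out) <- variables
  for (v in variables) {
    keep <- !is.na(data[[v]])
    tt <- data[[time_col]][keep]; ee <- data[[event_col]][keep]
    x <- data[[v]][keep]
    if (length(unique(x)) < config$min_distinct) {
      out[[v]] <- linear_screen(tt, ee, x, config$alpha_fp, v)
      next
    }
    r <- fp_closed_test(tt, ee, x, config, variable = v)
    if (!r$selected) {
      r2 <- minp_scan(tt, ee, x, config, variable = v)
      r <- if (r2$selected) r2 else {
        r3 <- nonordinal_scan(tt, ee, x, config, variable = v)
        if (r3$selected) r3 else r  # report the FP overall p when nothing hits
      }
    }
    out[[v]] <- r
  }
  structure(out, class = "screening_table")
}

#' @export
as.data.frame.screening_table <- function(x, ...) {
  do.call(rbind, lapply(x, function(r) data.frame(
    variable = r$variable, selected = r$selected,
    form = if (is.null(r$form)) NA_character_ else format(r$form),
    method = r$method, p_value = r$p_value, n_available = r$n_available,
    status = r$status, row.names = NULL)))
}

#' @export
print.screening_table <- function(x, ...) {
  print(as.data.frame(x)); invisible(x)
}

#' Write a screening table as CSV
#'
#' @param x a `screening_table` from [screen_all()].
#' @param path output CSV path.
#' @export
write_screening <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

selected_forms <- function(screening) {
  sel <- Filter(function(r) isTRUE(r$selected), screening)
  setNames(lapply(sel, `[[`, "form"), vapply(sel, `[[`, "", "variable"))
}
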