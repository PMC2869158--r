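# Step 3: refinement against instability. Threshold / non-ordinal screened
# effects are first re-scanned across the bootstrap samples; variables whose
# special form re-manifests in at least half of the samples enter (as frozen
# indicators) the per-sample multivariable-fractional-polynomial backward
# elimination together with the linear / polynomial screened variables and
# the clinical variables. Inclusion frequencies over all samples drive the
# 50% reliability rule; the form-stability rule drops continuous variables
# whose risk-function class wobbles across the retaining models.

#' Re-assess a special (threshold / non-ordinal) form on one sample
#'
#' Re-runs the corresponding scan ([minp_scan()] or [nonordinal_scan()]) on a
#' bootstrap sample and reports whether the effect is selected again at the
#' screening level.
#'
#' @param time,event sample outcome.
#' @param x sample covariate values.
#' @param screened_form the frozen [risk_form] from screening (threshold or
#'   non-ordinal kind).
#' @param config a [screening_config()].
#' @return logical flag; degenerate samples (no events, no cutpoints) give
#'   `FALSE`.
#' @export
reassess_special_form <- function(time, event, x, screened_form,
                                  config = screening_config()) {
  stopifnot(inherits(screened_form, "risk_form"),
            screened_form$kind %in% c("threshold", "non_ordinal"))
  if (sum(event) < 2) return(FALSE)
  res <- tryCatch(
    if (screened_form$kind == "threshold")
      minp_scan(time, event, x, config)
    else nonordinal_scan(time, event, x, config),
    error = function(e) NULL)
  isTRUE(res$selected)
}

# -- fast grouped Cox machinery for the per-sample MFP loop -----------------

# fit on a column subset; returns loglik (NA on failure) and the fit
fast_cox <- function(y, X, cols) {
  if (!length(cols)) return(list(loglik = NA_real_, fit = NULL))
  Xs <- X[, cols, drop = FALSE]
  f <- tryCatch(
    suppressWarnings(
      survival::coxph.fit(Xs, y, strata = NULL, offset = NULL, init = NULL,
                          control = survival::coxph.control(eps = 1e-09,
                                                            iter.max = 50),
                          weights = NULL, method = "efron", rownames = NULL,
                          resid = FALSE)),
    error = function(e) NULL)
  if (is.null(f) || anyNA(f$coefficients) || any(!is.finite(f$coefficients)) ||
      any(abs(f$coefficients) * attr(X, "colsd")[cols] > 10))
    return(list(loglik = NA_real_, fit = NULL))
  list(loglik = f$loglik[2], fit = f)
}

prep_design <- function(X) {
  storage.mode(X) <- "double"
  attr(X, "colsd") <- apply(X, 2, sd)
  X
}

#' Multivariable-FP backward elimination on one sample
#'
#' Backward elimination by likelihood-ratio test at `alpha_remove`: each
#' cycle drops the least significant variable group (largest LR p at or above
#' the threshold) and refits, until all retained groups are significant.
#' After elimination converges, every retained screened-linear continuous
#' variable is re-examined by the FP closed test at `alpha_remove`, adjusted
#' for the rest of the model, and upgraded to FP1/FP2 when warranted; any
#' form change triggers another elimination round. Special-form indicators
#' and already-polynomial screened variables keep their frozen columns.
#'
#' @param data one bootstrap sample (completed rows).
#' @param forms named list of frozen [risk_form]s for the candidate variables.
#' @param time_col,event_col outcome column names.
#' @param alpha_remove removal threshold (default 0.05).
#' @param fp_vars names of variables eligible for FP upgrading (continuous,
#'   screened linear); default: all candidates with a linear form and more
#'   than 10 distinct values.
#' @param max_cycles cap on elimination/upgrade rounds.
#' @return object of class `sample_model`: `retained` (variable names),
#'   `forms` (forms actually used), `loglik`, `converged`, `provenance`.
#' @export
mfp_backward <- function(data, forms, time_col = "time_rfs",
                         event_col = "event_rfs", alpha_remove = 0.05,
                         fp_vars = NULL, max_cycles = 10) {
  stopifnot(length(forms) >= 1)
  tt <- data[[time_col]]; ee <- data[[event_col]]
  if (is.null(fp_vars))
    fp_vars <- names(forms)[vapply(forms, function(f) f$kind == "linear",
                                   TRUE) &
                            vapply(names(forms), function(v)
                              length(unique(data[[v]])) > 10, TRUE)]
  forms_cur <- forms
  retained <- names(forms)
  y <- survival::Surv(tt, ee)
  build <- function(fs, vars) {
    X <- apply_forms(data, fs[vars])
    prep_design(X)
  }
  converged <- TRUE
  for (cycle in seq_len(max_cycles)) {
    changed <- FALSE
    # ---- backward elimination to convergence on current forms -------------
    repeat {
      if (!length(retained)) break
      X <- build(forms_cur, retained)
      groups <- attr(X, "groups")
      full <- fast_cox(y, X, seq_len(ncol(X)))
      if (is.na(full$loglik)) {      # degenerate sample; drop nothing more
        converged <- FALSE; break
      }
      ll0 <- if (!is.null(full$fit)) full$fit$loglik[1] else NA_real_
      pvals <- vapply(retained, function(v) {
        keep <- which(groups != v)
        red <- if (length(keep)) fast_cox(y, X, keep)$loglik else ll0
        if (is.na(red)) return(NA_real_)
        df <- sum(groups == v)
        pchisq(max(2 * (full$loglik - red), 0), df, lower.tail = FALSE)
      }, numeric(1))
      worst <- which.max(pvals)
      if (!length(worst) || all(is.na(pvals))) { converged <- FALSE; break }
      if (pvals[worst] >= alpha_remove) {
        retained <- setdiff(retained, retained[worst])
        changed <- TRUE
      } else break
    }
    if (!length(retained)) break
    # ---- FP upgrade pass over retained screened-linear variables ----------
    upgraded <- FALSE
    for (v in intersect(retained, fp_vars)) {
      others <- setdiff(retained, v)
      adjust <- if (length(others)) apply_forms(data, forms_cur[others]) else NULL
      res <- tryCatch(
        fp_closed_test(tt, ee, data[[v]], alpha = alpha_remove,
                       adjust = adjust, variable = v),
        error = function(e) NULL)
      if (is.null(res)) next
      if (isTRUE(res$selected) && res$form$kind != forms_cur[[v]]$kind) {
        forms_cur[[v]] <- res$form
        upgraded <- TRUE
      }
    }
    if (upgraded) changed <- TRUE
    if (!changed) break
    if (cycle == max_cycles) converged <- FALSE
  }
  ll <- if (length(retained)) {
    Xf <- build(forms_cur, retained)
    fast_cox(y, Xf, seq_len(ncol(Xf)))$loglik
  } else NA_real_
  structure(list(retained = retained, forms = forms_cur[retained],
                 loglik = ll, converged = converged, provenance = NULL),
            class = "sample_model")
}

#' @export
print.sample_model <- function(x, ...) {
  cat("<sample_model>", if (length(x$retained))
    paste(x$retained, collapse = ", ") else "(empty)", "\n")
  invisible(x)
}

#' Inclusion frequencies and stability verdicts over sample models
#'
#' @param models list of `sample_model`s (one per bootstrap x imputation
#'   sample).
#' @param candidates candidate variable names (defaults to the union of all
#'   screened forms seen).
#' @param screened_forms named list of frozen screened [risk_form]s, used to
#'   judge form stability (same FP degree class: linear vs FP1 vs FP2) among
#'   the models retaining each variable.
#' @param special_stability named logical-fraction vector for threshold /
#'   non-ordinal variables (fraction of samples whose re-scan confirmed the
#'   form); used as their form-stability fraction.
#' @param threshold stability threshold (default 0.5; the rule is "at least").
#' @return object of class `stability_report`: per-variable
#'   `inclusion_frequency`, `form_stability`, `verdict` in
#'   `{reliable-stable, unreliable, unstable-form}`.
#' @export
inclusion_frequency <- function(models, candidates = NULL,
                                screened_forms = NULL,
                                special_stability = NULL, threshold = 0.5) {
  stopifnot(length(models) >= 1)
  if (is.null(candidates))
    candidates <- unique(unlist(lapply(models, `[[`, "retained")))
  nmod <- length(models)
  freq <- setNames(numeric(length(candidates)), candidates)
  stab <- setNames(rep(1, length(candidates)), candidates)
  for (v in candidates) {
    keeps <- vapply(models, function(m) v %in% m$retained, TRUE)
    freq[[v]] <- mean(keeps)
    if (!is.null(special_stability) && v %in% names(special_stability)) {
      stab[[v]] <- special_stability[[v]]
    } else if (!is.null(screened_forms) && v %in% names(screened_forms) &&
               screened_forms[[v]]$kind %in% c("linear", "fp1", "fp2") &&
               any(keeps)) {
      cls <- vapply(models[keeps], function(m) m$forms[[v]]$kind, "")
      stab[[v]] <- mean(cls == screened_forms[[v]]$kind)
    }
  }
  verdict <- ifelse(freq < threshold, "unreliable",
                    ifelse(stab < threshold, "unstable-form",
                           "reliable-stable"))
  structure(list(inclusion_frequency = freq, form_stability = stab,
                 verdict = setNames(verdict, candidates),
                 n_models = nmod, threshold = threshold),
            class = "stability_report")
}

#' @export
as.data.frame.stability_report <- function(x, ...) {
  data.frame(variable = names(x$inclusion_frequency),
             inclusion_frequency = as.numeric(x$inclusion_frequency),
             form_stability = as.numeric(x$form_stability),
             verdict = as.character(x$verdict), row.names = NULL)
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %d sample models, threshold %.0f%%\n",
              x$n_models, 100 * x$threshold))
  d <- as.data.frame(x)
  d$inclusion_frequency <- round(100 * d$inclusion_frequency, 1)
  d$form_stability <- round(100 * d$form_stability, 1)
  print(d)
  invisible(x)
}

#' Write a stability report as CSV
#'
#' Columns mirror the reporting convention: inclusion frequency in percent
#' plus a verdict key (`a` = unreliable, `b` = unstable form, blank =
#' retained).
#'
#' @param x a `stability_report`.
#' @param path output CSV path.
#' @export
write_stability <- function(x, path) {
  d <- as.data.frame(x)
  d$inclusion_frequency <- 100 * d$inclusion_frequency
  d$key <- c("unreliable" = "a", "unstable-form" = "b",
             "reliable-stable" = "")[d$verdict]
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Refine to the reliable, stable variable set
#'
#' Applies the two 50% rules: variables retained in at least `threshold` of
#' the sample models AND whose risk-function form is stable keep their frozen
#' screened form; everything else is dropped. An empty final set is a valid
#' (flagged) outcome.
#'
#' @param report a [inclusion_frequency()] result.
#' @param screened_forms named list of frozen screened [risk_form]s.
#' @return named list of forms for the final variables (possibly empty, with
#'   attribute `"empty"` set).
#' @export
refine <- function(report, screened_forms) {
  stopifnot(inherits(report, "stability_report"))
  keep <- names(report$verdict)[report$verdict == "reliable-stable"]
  keep <- intersect(names(screened_forms), keep)
  out <- screened_forms[keep]
  if (!length(out)) attr(out, "empty") <- TRUE
  out
}
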