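# End-to-end orchestration of the four modelling steps plus evaluation:
# screen -> impute + transform + bootstrap -> stability refinement ->
# aggregation -> performance against the Nottingham Prognostic Index.

CLINICAL_VARS <- c("nodal", "grade", "size", "age")

#' Pipeline configuration
#'
#' Consolidates every tuning constant of the four-step procedure. Defaults
#' are the published ones: screening levels 0.1 / 0.005 / 0.025, m = 10
#' imputations, B = 100 bootstrap samples per imputation (1000 sample data
#' sets), 50% stability threshold, removal level 0.05, four risk groups for
#' recurrence-free survival and three for the on-treatment endpoint.
#'
#' @param endpoint `"RFS"`, `"RFoT"` or `"OS"`.
#' @param screening a [screening_config()].
#' @param m,B imputations and bootstrap samples per imputation.
#' @param n_iterations chained-equation sweeps per imputation.
#' @param stability_threshold inclusion / form-stability threshold.
#' @param alpha_remove backward-elimination removal level.
#' @param n_groups risk-group count; defaults to 4 (RFS, OS) or 3 (RFoT).
#' @param seed master seed; every stochastic sub-task derives from it.
#' @param hr_units hazard-ratio reporting units for raw-scale continuous
#'   biomarker columns (default 100: per-100-unit histoscore convention).
#' @param out_dir optional directory: when set, intermediate artifacts
#'   (screening table, stability report, model report) are written there.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(endpoint = c("RFS", "RFoT", "OS"),
                            screening = screening_config(), m = 10, B = 100,
                            n_iterations = 20, stability_threshold = 0.5,
                            alpha_remove = 0.05, n_groups = NULL, seed = 1,
                            hr_units = 100, out_dir = NULL) {
  endpoint <- match.arg(endpoint)
  stopifnot(alpha_remove > 0, alpha_remove < 1,
            stability_threshold > 0, stability_threshold <= 1)
  if (m * B < 100)
    warning("m * B < 100: stability fractions will be noisy", call. = FALSE)
  n_groups <- n_groups %||% if (endpoint == "RFoT") 3L else 4L
  structure(list(endpoint = endpoint, screening = screening,
                 m = as.integer(m), B = as.integer(B),
                 n_iterations = as.integer(n_iterations),
                 stability_threshold = stability_threshold,
                 alpha_remove = alpha_remove, n_groups = as.integer(n_groups),
                 seed = as.integer(seed), hr_units = hr_units,
                 out_dir = out_dir),
            class = "pipeline_config")
}

endpoint_cols <- function(endpoint) {
  switch(endpoint,
         RFS = c("time_rfs", "event_rfs"),
         RFoT = c("time_rfot", "event_rfot"),
         OS = c("time_os", "event_os"))
}

# per-100-unit HR convention: raw-scale linear biomarker columns only
hr_scale_for <- function(forms, hr_units) {
  out <- c()
  for (v in names(forms)) {
    f <- forms[[v]]
    if (f$kind == "linear" && !(v %in% CLINICAL_VARS)) {
      # reporting unit on the design-column scale: `hr_units` raw units
      out[v] <- hr_units / f$scaling[2]
    } else if (f$kind == "fp2") {
      out[paste0(v, c(".1", ".2"))] <- 1
    } else out[v] <- 1
  }
  out
}

#' Run the four-step modelling pipeline on a cohort
#'
#' Executes univariate screening, chained-equation multiple imputation with
#' frozen screened transformations, bootstrap resampling, special-form
#' stability checks and per-sample MFP backward elimination, the 50%
#' reliability/stability refinement, Rubin-rule aggregation, risk grouping,
#' and evaluation against the Nottingham Prognostic Index. Identical
#' `config` + seed gives an identical report.
#'
#' @param cohort a cohort data frame (see [generate_cohort()] for the column
#'   contract). For the RFoT endpoint, rows with missing tamoxifen duration
#'   are excluded (the count is recorded).
#' @param config a [pipeline_config()].
#' @param markers candidate biomarker variable names; defaults to every
#'   non-outcome, non-clinical, non-id column.
#' @return object of class `run_report`: `screening`, `special_stability`,
#'   `stability`, `final_forms`, `model`, `scores`, `groups`, `evaluation`,
#'   `provenance`. An empty candidate or final set yields a report with
#'   explicit empty-model status rather than an error.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), markers = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  n_excluded <- 0L
  if (config$endpoint == "RFoT") {
    if (!"tam_duration" %in% names(cohort))
      stop_config("run_pipeline: RFoT endpoint needs tam_duration")
    miss <- is.na(cohort$tam_duration)
    n_excluded <- sum(miss)
    cohort <- derive_rfot(cohort[!miss, , drop = FALSE])
  }
  oc <- endpoint_cols(config$endpoint)
  time_col <- oc[1]; event_col <- oc[2]
  stopifnot(all(oc %in% names(cohort)))
  reserved <- c("id", "tam_duration", "time_rfs", "event_rfs", "time_os",
                "event_os", "time_rfot", "event_rfot")
  markers <- markers %||% setdiff(names(cohort), c(reserved, CLINICAL_VARS))
  clinical <- intersect(CLINICAL_VARS, names(cohort))

  ## Step 1: univariate screening -------------------------------------------
  screening <- screen_all(cohort, c(markers, clinical), time_col, event_col,
                          config$screening)
  forms_scr <- selected_forms(screening)
  # clinical variables are always offered to the multivariate stage (linear)
  for (v in setdiff(clinical, names(forms_scr)))
    forms_scr[[v]] <- form_linear()
  candidates <- unique(c(intersect(markers, names(forms_scr)), clinical))
  report <- list(config = config, screening = screening,
                 n_excluded_missing_duration = n_excluded)
  if (!length(candidates)) {
    report$status <- "empty candidate set after screening"
    class(report) <- "run_report"
    return(report)
  }

  ## Step 2: imputation + bootstrap -----------------------------------------
  imp_cfg <- imputation_config(m = config$m, n_iterations = config$n_iterations)
  imputed <- mice_impute(cohort, candidates, imp_cfg, time_col, event_col,
                         seed = derive_seed(config$seed, 2))
  sset <- make_sample_set(imputed, B = config$B,
                          seed = derive_seed(config$seed, 3))

  ## Step 3a: stability of threshold / non-ordinal forms ---------------------
  special <- names(forms_scr)[vapply(forms_scr, function(f)
    f$kind %in% c("threshold", "non_ordinal"), TRUE)]
  special <- intersect(special, candidates)
  special_stability <- setNames(numeric(0), character(0))
  if (length(special)) {
    special_stability <- vapply(special, function(v) {
      hits <- vapply(sset$samples, function(s) {
        d <- sset$imputed[[s$imputation]][s$rows, , drop = FALSE]
        reassess_special_form(d[[time_col]], d[[event_col]], d[[v]],
                              forms_scr[[v]], config$screening)
      }, TRUE)
      mean(hits)
    }, numeric(1))
    unstable <- names(special_stability)[
      special_stability < config$stability_threshold]
    candidates <- setdiff(candidates, unstable)
  }
  forms_cand <- forms_scr[candidates]

  ## Step 3b: per-sample MFP backward elimination ----------------------------
  if (!length(forms_cand)) {
    report$special_stability <- special_stability
    report$status <- "no candidates survived form-stability checks"
    class(report) <- "run_report"
    return(report)
  }
  models <- lapply(sset$samples, function(s) {
    d <- sset$imputed[[s$imputation]][s$rows, , drop = FALSE]
    m <- mfp_backward(d, forms_cand, time_col, event_col,
                      alpha_remove = config$alpha_remove)
    m$provenance <- s[c("imputation", "bootstrap")]
    m
  })
  stability <- inclusion_frequency(
    models, candidates = candidates, screened_forms = forms_cand,
    special_stability = special_stability,
    threshold = config$stability_threshold)
  final_forms <- refine(stability, forms_cand)
  report$special_stability <- special_stability
  report$stability <- stability
  report$sample_models <- models
  report$final_forms <- final_forms
  if (!length(final_forms)) {
    report$status <- "empty final model"
    class(report) <- "run_report"
    return(report)
  }

  ## Step 4: aggregation ------------------------------------------------------
  fits <- fit_final(imputed, final_forms, time_col, event_col)
  model <- rubin_pool(fits, hr_scale = hr_scale_for(final_forms,
                                                    config$hr_units))
  scores <- aggregate_scores(fits, imputed, final_forms)
  # grouping can be impossible when the final model collapses to a single
  # ordinal variable (fewer distinct scores than groups); degrade, don't die
  groups <- tryCatch(make_risk_groups(scores$score, config$n_groups),
                     error = function(e) NULL)

  ## Evaluation ---------------------------------------------------------------
  tt <- cohort[[time_col]]; ee <- cohort[[event_col]]
  evaluation <- list(
    c_index = harrell_c(scores$score, tt, ee),
    r2 = mean(vapply(fits, nagelkerke_r2, numeric(1))))
  if (!is.null(groups))
    evaluation$event_free <- event_free_rate(tt, ee, groups)
  if (!is.null(groups) &&
      all(c("size", "grade", "nodal") %in% names(cohort)) &&
      !anyNA(cohort[c("size", "grade", "nodal")])) {
    npi <- npi_score(cohort$size, cohort$grade, cohort$nodal)
    npi_g <- if (config$n_groups == 4) npi_group(npi, "quartile")
             else npi_group(npi, "tertile")
    evaluation$npi_c_index <- harrell_c(npi, tt, ee)
    evaluation$reclassification <- reclassify(groups, npi_g, ee)
    evaluation$npi_event_free <-
      event_free_rate(tt, ee, npi_group(npi, "standard"))
  }
  report <- c(report, list(model = model, scores = scores, groups = groups,
                           evaluation = evaluation, status = "ok"))
  if (is.null(groups)) report$status <- "ok (risk grouping skipped: too few distinct scores)"
  report$provenance <- list(seed = config$seed, endpoint = config$endpoint,
                            m = config$m, B = config$B,
                            n_samples = length(models),
                            elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                            units = "secs")),
                            package_version =
                              as.character(utils::packageVersion("markerstab")))
  class(report) <- "run_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", x$config$endpoint, "endpoint, status:", x$status, "\n")
  if (!is.null(x$stability)) print(x$stability)
  if (!is.null(x$model)) print(x$model)
  if (!is.null(x$evaluation)) {
    cat(sprintf("C-index %.3f", x$evaluation$c_index))
    if (!is.null(x$evaluation$npi_c_index))
      cat(sprintf(" (NPI %.3f)", x$evaluation$npi_c_index))
    cat(sprintf(", Nagelkerke R2 %.3f\n", x$evaluation$r2))
  }
  invisible(x)
}

#' Persist a run report's artifacts
#'
#' Writes the screening table and stability report as CSV and the pooled
#' model + evaluation metrics + provenance as JSON under `dir`.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$screening))
    write_screening(report$screening, file.path(dir, "screening.csv"))
  if (!is.null(report$stability))
    write_stability(report$stability, file.path(dir, "stability.csv"))
  js <- list(status = report$status, provenance = report$provenance)
  if (!is.null(report$model)) {
    js$pooled_coefficients <- as.list(report$model$pooled_coefficients)
    js$pooled_se <- as.list(report$model$pooled_se)
    js$hazard_ratios <- report$model$hazard_ratios
  }
  if (!is.null(report$evaluation))
    js$evaluation <- list(c_index = report$evaluation$c_index,
                          r2 = report$evaluation$r2,
                          npi_c_index = report$evaluation$npi_c_index)
  jsonlite::write_json(js, file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Generate a synthetic cohort, run the pipeline, report recovery diagnostics
#'
#' The acceptance harness: draws a cohort from a known generating model,
#' optionally injects missingness, runs [run_pipeline()], and compares the
#' result against the ground truth — inclusion frequencies of true-effect vs
#' noise variables, pooled coefficients vs generating coefficients (for
#' variables recovered with the generating form), and the concordance of the
#' fitted aggregate score vs the true linear predictor.
#'
#' @param cohort_cfg a [cohort_config()].
#' @param model a [generating_model()].
#' @param pipeline_cfg a [pipeline_config()].
#' @param seed master seed (overrides `pipeline_cfg$seed`).
#' @param missing_spec optional [missingness_spec()].
#' @param n_markers passed to [generate_cohort()].
#' @return list: `report` (the `run_report`) and `diagnostics`.
#' @export
simulate_and_run <- function(cohort_cfg, model, pipeline_cfg, seed = 1,
                             missing_spec = NULL, n_markers = 0) {
  pipeline_cfg$seed <- as.integer(seed)
  cohort <- generate_cohort(cohort_cfg, model, seed = derive_seed(seed, 11),
                            n_markers = n_markers)
  true_lp <- attr(cohort, "true_lp")
  if (!is.null(missing_spec))
    cohort <- inject_missingness(cohort, missing_spec,
                                 seed = derive_seed(seed, 12))
  report <- run_pipeline(cohort, pipeline_cfg)
  true_vars <- vapply(model$effects, `[[`, "", "variable")
  diag <- list(true_variables = true_vars)
  if (!is.null(report$stability)) {
    freq <- report$stability$inclusion_frequency
    diag$true_inclusion <- freq[intersect(true_vars, names(freq))]
    diag$noise_inclusion <- freq[setdiff(names(freq), true_vars)]
  }
  if (identical(report$status, "ok")) {
    oc <- endpoint_cols(pipeline_cfg$endpoint)
    keep <- if (pipeline_cfg$endpoint == "RFoT")
      !is.na(cohort$tam_duration) else rep(TRUE, nrow(cohort))
    cohort_used <- if (pipeline_cfg$endpoint == "RFoT")
      derive_rfot(cohort[keep, , drop = FALSE]) else cohort
    diag$c_index_fitted <- report$evaluation$c_index
    diag$c_index_true <- harrell_c(true_lp[keep], cohort_used[[oc[1]]],
                                   cohort_used[[oc[2]]])
    # pooled vs generating coefficients where the recovered form matches the
    # generating one. Linear effects are compared per raw unit (screening
    # freezes its own scaling); FP effects require matching powers + scaling;
    # threshold / non-ordinal effects compare the indicator coefficient when
    # the form kind (and pattern) matches.
    est <- se <- truth <- c()
    for (ef in model$effects) {
      v <- ef$variable
      ff <- report$final_forms[[v]]
      if (is.null(ff) || ff$kind != ef$form$kind) next
      cols <- if (ff$kind == "fp2") paste0(v, c(".1", ".2")) else v
      if (!all(cols %in% names(report$model$pooled_coefficients))) next
      b <- report$model$pooled_coefficients[cols]
      s <- report$model$pooled_se[cols]
      b0 <- ef$beta
      if (ff$kind == "linear") {
        # per-raw-unit slope: design column is (x + shift)/scale
        b <- b / ff$scaling[2]; s <- s / ff$scaling[2]
        b0 <- b0 / ef$form$scaling[2]
      } else if (ff$kind %in% c("fp1", "fp2")) {
        if (!identical(ff$powers, ef$form$powers) ||
            !isTRUE(all.equal(ff$scaling, ef$form$scaling))) next
      } else if (ff$kind == "non_ordinal") {
        if (!identical(ff$pattern, ef$form$pattern)) next
      }
      est <- c(est, b); se <- c(se, s); truth <- c(truth, setNames(b0, cols))
    }
    diag$coefficients <- data.frame(term = names(est), estimate = est,
                                    se = se, truth = truth, row.names = NULL)
  }
  list(report = report, diagnostics = diag)
}
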