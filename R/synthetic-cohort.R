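# Synthetic cohorts with known ground truth. The generator emulates the data
# structure the pipeline assumes: ~400 tamoxifen-treated patients, censored
# recurrence endpoints, four clinical variables, positively skewed biomarker
# histoscores on the 0-300 scale, declared covariate effects of every
# supported risk-function form, and moderate per-variable missingness.

#' Declare a ground-truth generating model
#'
#' @param effects list of effects, each `list(variable =, form = <risk_form>,
#'   beta =)` with `beta` of length 1 (length 2 for FP2 forms); coefficients
#'   are on the log-hazard scale applied to the form's design column(s).
#' @param baseline_hazard exponential baseline event rate per year.
#' @param censoring_rate independent exponential censoring rate per year.
#' @param admin_censor_time administrative censoring horizon (years).
#' @param os_hazard_ratio multiplier relating the death-process baseline to
#'   `baseline_hazard` (the overall-survival endpoint shares the linear
#'   predictor).
#' @return object of class `generating_model`.
#' @export
generating_model <- function(effects = list(), baseline_hazard = 0.055,
                             censoring_rate = 0.10, admin_censor_time = 10,
                             os_hazard_ratio = 0.6) {
  if (baseline_hazard <= 0 || censoring_rate <= 0 || admin_censor_time <= 0)
    stop_config("generating_model: rates and horizon must be positive")
  vars <- vapply(effects, `[[`, "", "variable")
  if (anyDuplicated(vars))
    stop_config("generating_model: duplicate effect variables")
  for (ef in effects) {
    stopifnot(inherits(ef$form, "risk_form"), all(is.finite(ef$beta)))
    want <- if (ef$form$kind == "fp2") 2L else 1L
    if (length(ef$beta) != want)
      stop_config("generating_model: effect on %s needs %d coefficient(s)",
                  ef$variable, want)
  }
  structure(list(effects = effects, baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate,
                 admin_censor_time = admin_censor_time,
                 os_hazard_ratio = os_hazard_ratio),
            class = "generating_model")
}

#' Configure the shape of a synthetic cohort
#'
#' Defaults emulate the cohort the pipeline was designed around: 401
#' tamoxifen-treated ER-positive patients, right-skewed biomarker histoscores
#' in `[0, 300]`, ordinal nodal status and Bloom-Richardson grade (1-3),
#' tumour size in cm, age at diagnosis, and treatment duration with median 5
#' years.
#'
#' @param n_patients cohort size (at least 20).
#' @param n_noise_markers number of additional histoscore markers with no
#'   effect on hazard (named `noise1`, `noise2`, ...).
#' @param histoscore_skew gamma shape parameter (> 0) of the histoscore
#'   distribution; smaller is more skewed.
#' @param histoscore_mean target mean histoscore before truncation at 300.
#' @param nodal_probs,grade_probs category probabilities for the two ordinal
#'   clinical variables (levels 1-3).
#' @param size_meanlog,size_sdlog log-normal parameters for tumour size (cm).
#' @param age_mean,age_sd normal parameters for age (years).
#' @param tam_shape gamma shape for tamoxifen duration; the rate is solved so
#'   the median is `tam_median` years.
#' @param tam_median median treatment duration (years).
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 401, n_noise_markers = 0,
                          histoscore_skew = 1.4, histoscore_mean = 90,
                          nodal_probs = c(0.55, 0.30, 0.15),
                          grade_probs = c(0.20, 0.45, 0.35),
                          size_meanlog = log(2.2), size_sdlog = 0.45,
                          age_mean = 61, age_sd = 10,
                          tam_shape = 8, tam_median = 5) {
  if (n_patients < 20) stop_config("cohort_config: n_patients must be >= 20")
  if (histoscore_skew <= 0) stop_config("cohort_config: skew must be > 0")
  stopifnot(length(nodal_probs) == 3, length(grade_probs) == 3,
            all(nodal_probs > 0), all(grade_probs > 0))
  structure(list(n_patients = as.integer(n_patients),
                 n_noise_markers = as.integer(n_noise_markers),
                 histoscore_skew = histoscore_skew,
                 histoscore_mean = histoscore_mean,
                 nodal_probs = nodal_probs / sum(nodal_probs),
                 grade_probs = grade_probs / sum(grade_probs),
                 size_meanlog = size_meanlog, size_sdlog = size_sdlog,
                 age_mean = age_mean, age_sd = age_sd,
                 tam_shape = tam_shape, tam_median = tam_median),
            class = "cohort_config")
}

r_histoscore <- function(n, shape, mean) {
  pmin(rgamma(n, shape = shape, rate = shape / mean), 300)
}

#' Evaluate the true linear predictor of a generating model
#'
#' Sum of the declared effects applied to each patient's (complete)
#' covariates — the ground-truth log relative hazard used for
#' parameter-recovery and concordance checks.
#'
#' @param cohort data frame containing the effect variables, complete for all
#'   variables the model uses.
#' @param model a [generating_model()].
#' @return numeric per-patient score (0 for an empty effect list).
#' @export
true_linear_predictor <- function(cohort, model) {
  stopifnot(inherits(model, "generating_model"))
  lp <- numeric(nrow(cohort))
  for (ef in model$effects) {
    x <- cohort[[ef$variable]]
    if (is.null(x)) stop_config("true_linear_predictor: variable %s absent",
                                ef$variable)
    if (anyNA(x)) stop_config(
      "true_linear_predictor: missing values in %s", ef$variable)
    f <- ef$form
    cols <- if (f$kind %in% c("threshold", "non_ordinal"))
      cbind(form_indicator(x, f)) else fp_transform(x, f)
    lp <- lp + as.numeric(cols %*% ef$beta)
  }
  lp
}

#' Generate a synthetic cohort under a proportional-hazards ground truth
#'
#' Covariates are drawn from `config`; recurrence times come from an
#' exponential baseline under proportional hazards (inverse-transform
#' sampling with hazard `baseline_hazard * exp(lp)`), censored by the minimum
#' of an independent exponential time and the administrative horizon. Death
#' times (overall survival) use the same linear predictor with baseline
#' `os_hazard_ratio * baseline_hazard`. Identical seeds give bit-identical
#' cohorts.
#'
#' @param config a [cohort_config()].
#' @param model a [generating_model()]; effect variables must name clinical
#'   variables or `markerK` / `noiseK` histoscore columns (extra named
#'   markers are created as needed).
#' @param seed integer seed.
#' @param n_markers number of effect-free candidate histoscore markers named
#'   `marker1..K` to generate in addition to any the model's effects demand.
#' @return data frame of class `cohort`: `id`, `time_rfs`, `event_rfs`,
#'   `time_os`, `event_os`, `tam_duration`, clinical columns (`nodal`,
#'   `grade`, `size`, `age`) and marker columns.
#' @export
generate_cohort <- function(config, model, seed, n_markers = 0) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(model, "generating_model"))
  set.seed(as.integer(seed))
  n <- config$n_patients
  clinical <- c("nodal", "grade", "size", "age")
  d <- data.frame(
    id = seq_len(n),
    nodal = sample.int(3, n, replace = TRUE, prob = config$nodal_probs),
    grade = sample.int(3, n, replace = TRUE, prob = config$grade_probs),
    size = rlnorm(n, config$size_meanlog, config$size_sdlog),
    age = pmin(pmax(rnorm(n, config$age_mean, config$age_sd), 25), 95))
  # gamma median ~ (shape - 1/3) / rate, solved for rate
  tam_rate <- (config$tam_shape - 1 / 3) / config$tam_median
  d$tam_duration <- pmin(rgamma(n, config$tam_shape, rate = tam_rate), 10)
  # markers demanded by the model's effects plus requested candidates/noise
  eff_vars <- vapply(model$effects, `[[`, "", "variable")
  marker_names <- unique(c(setdiff(eff_vars, clinical),
                           if (n_markers > 0) paste0("marker", seq_len(n_markers)),
                           if (config$n_noise_markers > 0)
                             paste0("noise", seq_len(config$n_noise_markers))))
  for (v in marker_names)
    d[[v]] <- r_histoscore(n, config$histoscore_skew, config$histoscore_mean)
  lp <- true_linear_predictor(d, model)
  # inverse-transform exponential survival under proportional hazards
  t_rec <- -log(runif(n)) / (model$baseline_hazard * exp(lp))
  t_cen <- pmin(rexp(n, model$censoring_rate), model$admin_censor_time)
  d$time_rfs <- pmin(t_rec, t_cen)
  d$event_rfs <- as.integer(t_rec <= t_cen)
  t_die <- -log(runif(n)) /
    (model$os_hazard_ratio * model$baseline_hazard * exp(lp))
  d$time_os <- pmin(t_die, t_cen)
  d$event_os <- as.integer(t_die <= t_cen)
  d <- d[c("id", "time_rfs", "event_rfs", "time_os", "event_os",
           "tam_duration", clinical, marker_names)]
  attr(d, "true_lp") <- lp
  class(d) <- c("cohort", "data.frame")
  d
}

#' Derive the recurrence-free-on-treatment endpoint
#'
#' Censors recurrence-free survival at tamoxifen cessation: the event counts
#' only if recurrence occurred while still on treatment.
#'
#' @param cohort a cohort data frame with `time_rfs`, `event_rfs`,
#'   `tam_duration`.
#' @return the cohort with `time_rfot`, `event_rfot` columns added; rows with
#'   missing `tam_duration` get `NA` endpoints.
#' @export
derive_rfot <- function(cohort) {
  stopifnot(all(c("time_rfs", "event_rfs", "tam_duration") %in% names(cohort)))
  td <- cohort$tam_duration
  cohort$time_rfot <- pmin(cohort$time_rfs, td)
  cohort$event_rfot <- as.integer(cohort$event_rfs == 1 & cohort$time_rfs <= td)
  cohort
}

#' Missingness specification
#'
#' @param rates named vector of per-variable missingness fractions, each in
#'   `[0, 0.5]`; outcome columns (`time_*`, `event_*`) may not appear.
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param mar_driver for MAR: name of a fully observed variable; missingness
#'   probability follows a logistic model in the standardised driver with the
#'   intercept solved so the marginal rate matches `rates`.
#' @param mar_slope logistic slope on the standardised driver.
#' @return object of class `missingness_spec`.
#' @export
missingness_spec <- function(rates, mechanism = c("MCAR", "MAR"),
                             mar_driver = NULL, mar_slope = 1) {
  mechanism <- match.arg(mechanism)
  stopifnot(is.numeric(rates), length(names(rates)) == length(rates))
  if (any(rates < 0 | rates > 0.5))
    stop_config("missingness_spec: rates must lie in [0, 0.5]")
  bad <- grep("^(time|event)_", names(rates), value = TRUE)
  if (length(bad))
    stop_config("missingness_spec: outcome variables may not be masked: %s",
                paste(bad, collapse = ", "))
  if (mechanism == "MAR" && is.null(mar_driver))
    stop_config("missingness_spec: MAR requires mar_driver")
  structure(list(rates = rates, mechanism = mechanism,
                 mar_driver = mar_driver, mar_slope = mar_slope),
            class = "missingness_spec")
}

#' Mask covariate values according to a missingness specification
#'
#' @param cohort a cohort data frame.
#' @param spec a [missingness_spec()].
#' @param seed integer seed.
#' @return the cohort with `NA`s injected; outcomes untouched. Attribute
#'   `"n_complete"` records the complete-case count over the masked
#'   variables.
#' @export
inject_missingness <- function(cohort, spec, seed) {
  stopifnot(inherits(spec, "missingness_spec"))
  absent <- setdiff(names(spec$rates), names(cohort))
  if (length(absent))
    stop_config("inject_missingness: variables not in cohort: %s",
                paste(absent, collapse = ", "))
  set.seed(as.integer(seed))
  n <- nrow(cohort)
  for (v in names(spec$rates)) {
    r <- spec$rates[[v]]
    if (r == 0) next
    p <- if (spec$mechanism == "MCAR") rep(r, n) else {
      z <- cohort[[spec$mar_driver]]
      if (anyNA(z)) stop_config("inject_missingness: MAR driver has NAs")
      zs <- as.numeric(scale(z))
      a <- uniroot(function(a) mean(plogis(a + spec$mar_slope * zs)) - r,
                   c(-30, 30))$root
      plogis(a + spec$mar_slope * zs)
    }
    cohort[[v]][runif(n) < p] <- NA
  }
  attr(cohort, "n_complete") <-
    sum(stats::complete.cases(cohort[names(spec$rates)]))
  cohort
}

#' Calibrate the baseline hazard to a target event fraction
#'
#' Solves (by large-n simulation and root finding) for the exponential
#' baseline hazard under which a cohort drawn from `config` + `model` has the
#' requested expected event fraction, accounting for the declared effects and
#' the censoring process.
#'
#' @param config a [cohort_config()].
#' @param model a [generating_model()]; its `baseline_hazard` is ignored.
#' @param target_event_fraction desired expected fraction of events.
#' @param n_sim simulation size for the expectation.
#' @param seed integer seed.
#' @return calibrated baseline hazard (rate per year).
#' @export
calibrate_baseline <- function(config, model, target_event_fraction,
                               n_sim = 20000, seed = 1) {
  stopifnot(target_event_fraction > 0, target_event_fraction < 1)
  big <- config; big$n_patients <- as.integer(n_sim)
  probe <- generate_cohort(big, model, seed = seed)
  lp <- attr(probe, "true_lp")
  mu <- model$censoring_rate; tau <- model$admin_censor_time
  evfrac <- function(h0) {
    lam <- h0 * exp(lp)
    mean(lam / (lam + mu) * (1 - exp(-(lam + mu) * tau)))
  }
  uniroot(function(h0) evfrac(h0) - target_event_fraction,
          c(1e-06, 10), tol = 1e-08)$root
}

#' Write / read a cohort as CSV with a key-value sidecar
#'
#' Missing values are written as empty fields; the sidecar (DCF key-value
#' text) records generation parameters when supplied.
#'
#' @param cohort cohort data frame.
#' @param path CSV path.
#' @param sidecar optional named list written to `<path>.meta` as key: value.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sidecar = NULL) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  if (!is.null(sidecar)) {
    meta <- vapply(sidecar, function(v) paste(format(v), collapse = " "), "")
    writeLines(paste0(names(meta), ": ", meta), paste0(path, ".meta"))
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- read.csv(path, na.strings = "")
  class(d) <- c("cohort", "data.frame")
  d
}
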