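# A ready-made synthetic "study world" emulating the data structure the
# pipeline was designed for: ~401 tamoxifen-treated patients, ~28% recurrence
# events over 10 years of follow-up, four clinical variables, 16 candidate
# histoscore biomarkers of which five carry true effects (one of each
# supported risk-function form) plus one true clinical effect, and MCAR
# missingness between 1.2% and 9.2% per biomarker (mean 5.2%).

#' Study-shaped synthetic world with one true effect of each form
#'
#' Returns the cohort configuration, ground-truth generating model and
#' missingness specification used by the package's end-to-end validation: a
#' 401-patient cohort with six strong true effects — linear (`markerLin`),
#' log / FP1(0) (`markerLog`), quadratic U-shape / FP2(1,2) (`markerU`),
#' threshold at histoscore 104 (`markerThr`, log-HR 1.0, i.e. HR ~2.7 as for
#' a nuclear phospho-MAPK-like marker), non-ordinal R3 contrast (`markerNol`)
#' and linear nodal status (log-HR 0.6, HR ~1.8) — plus 11 effect-free noise
#' markers (`noise1..11`). Effect sizes follow published hazard-ratio
#' magnitudes where available and were otherwise fixed so each effect has
#' roughly 90 percent univariate screening power through its own route at
#' n = 401 (~112 events). The baseline hazard (0.0206/y) was calibrated once
#' with [calibrate_baseline()] so the expected event fraction is
#' 112/401 = 0.279 under 0.10/y exponential censoring truncated at 10 years.
#'
#' @param n_patients cohort size.
#' @return list with `cohort_config`, `model`, `missing_spec`, and bookkeeping
#'   (`true_vars`, `noise_vars`).
#' @export
example_world <- function(n_patients = 401) {
  sc <- c(0, 100)   # matches the frozen screening scale for 0-300 histoscores
  q_gen <- qgamma(c(0.25, 0.5, 0.75), shape = 1.4, rate = 1.4 / 90)
  effects <- list(
    list(variable = "markerLin", form = form_linear(scaling = sc),
         beta = 0.55),
    list(variable = "markerLog", form = form_fp1(0, scaling = sc),
         beta = -0.55),
    list(variable = "markerU", form = form_fp2(1, 2, scaling = sc),
         beta = c(-2.4, 0.8)),
    list(variable = "markerThr", form = form_threshold(104), beta = 1.0),
    list(variable = "markerNol", form = form_nonordinal("R3", q_gen),
         beta = -1.0),
    list(variable = "nodal", form = form_linear(), beta = 0.6))
  model <- generating_model(effects, baseline_hazard = 0.0206,
                            censoring_rate = 0.10, admin_censor_time = 10)
  cfg <- cohort_config(n_patients = n_patients, n_noise_markers = 11)
  biomarkers <- c("markerLin", "markerLog", "markerU", "markerThr",
                  "markerNol", paste0("noise", 1:11))
  rates <- setNames(seq(0.012, 0.092, length.out = length(biomarkers)),
                    biomarkers)
  list(cohort_config = cfg, model = model,
       missing_spec = missingness_spec(rates),
       true_vars = vapply(effects, `[[`, "", "variable"),
       noise_vars = paste0("noise", 1:11))
}
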