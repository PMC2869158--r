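null_model <- function(base = 0.05, cens = 0.05, admin = 10)
  generating_model(list(), baseline_hazard = base, censoring_rate = cens,
                   admin_censor_time = admin)

test_that("generate_cohort is deterministic in the seed", {
  cfg <- cohort_config(n_patients = 60)
  gm <- null_model()
  c1 <- generate_cohort(cfg, gm, seed = 42, n_markers = 2)
  c2 <- generate_cohort(cfg, gm, seed = 42, n_markers = 2)
  expect_identical(c1, c2)
  c3 <- generate_cohort(cfg, gm, seed = 43, n_markers = 2)
  expect_false(identical(c1$time_rfs, c3$time_rfs))
})

test_that("null-model event fraction matches an independent exponential simulation", {
  gm <- null_model(base = 0.05, cens = 0.05, admin = 10)
  coh <- generate_cohort(cohort_config(n_patients = 5000), gm, seed = 9)
  # independent direct simulation of the same exponential model
  set.seed(999)
  t_ev <- rexp(2e5, 0.05)
  t_cn <- pmin(rexp(2e5, 0.05), 10)
  p_oracle <- mean(t_ev <= t_cn)
  p_obs <- mean(coh$event_rfs)
  se <- sqrt(p_oracle * (1 - p_oracle) / 5000)
  expect_lt(abs(p_obs - p_oracle), 3.5 * se)
  # and the analytic value lambda/(lambda+mu) (1 - exp(-(lambda+mu) tau))
  p_formula <- 0.5 * (1 - exp(-1))
  expect_lt(abs(p_obs - p_formula), 3.5 * se)
})

test_that("the default cohort shape gives ~401 patients and ~112 events", {
  coh <- generate_cohort(cohort_config(), generating_model(), seed = 5)
  expect_equal(nrow(coh), 401)
  # binomial error around the design target of 112/401
  expect_lt(abs(sum(coh$event_rfs) - 112), 3 * sqrt(401 * 0.28 * 0.72))
})

test_that("cohort structure honours its invariants", {
  cfg <- cohort_config(n_patients = 400, n_noise_markers = 2)
  coh <- generate_cohort(cfg, null_model(), seed = 3, n_markers = 2)
  expect_true(all(coh$time_rfs >= 0))
  expect_true(all(coh$event_rfs %in% 0:1))
  expect_true(all(coh$nodal %in% 1:3) && all(coh$grade %in% 1:3))
  expect_true(all(coh$size > 0))
  mk <- grep("^(marker|noise)", names(coh), value = TRUE)
  expect_length(mk, 4)
  for (v in mk) expect_true(all(coh[[v]] >= 0 & coh[[v]] <= 300))
  # positive skew of histoscores
  x <- coh$marker1
  expect_gt(mean((x - mean(x))^3) / sd(x)^3, 0.5)
  # RFoT endpoint never exceeds RFS time
  r <- derive_rfot(coh)
  expect_true(all(r$time_rfot <= r$time_rfs + 1e-12))
  expect_true(all(r$event_rfot <= r$event_rfs))
  # median treatment duration near 5 years
  expect_lt(abs(median(coh$tam_duration) - 5), 0.5)
})

test_that("generating-model configuration errors are explicit", {
  expect_error(generating_model(baseline_hazard = 0), "positive")
  expect_error(cohort_config(n_patients = 10), ">= 20")
  expect_error(generating_model(list(
    list(variable = "a", form = form_linear(), beta = 0.1),
    list(variable = "a", form = form_linear(), beta = 0.2))), "duplicate")
  expect_error(generating_model(list(
    list(variable = "a", form = form_fp2(1, 2), beta = 0.1))), "2 coefficient")
})

test_that("true_linear_predictor evaluates declared effects exactly", {
  cfg <- cohort_config(n_patients = 30)
  coh <- generate_cohort(cfg, null_model(), seed = 1, n_markers = 2)
  # all-zero coefficients
  gm0 <- generating_model(list(
    list(variable = "marker1", form = form_linear(), beta = 0)))
  expect_equal(true_linear_predictor(coh, gm0), rep(0, 30))
  # single linear effect: hand arithmetic on 3 patients
  gm1 <- generating_model(list(
    list(variable = "marker1", form = form_linear(), beta = 0.01)))
  expect_equal(true_linear_predictor(coh, gm1)[1:3], 0.01 * coh$marker1[1:3])
  # threshold effect: step equals the declared coefficient
  gm2 <- generating_model(list(
    list(variable = "marker1", form = form_threshold(100), beta = 0.8)))
  lp <- true_linear_predictor(coh, gm2)
  above <- which(coh$marker1 >= 100)[1]; below <- which(coh$marker1 < 100)[1]
  expect_equal(lp[above] - lp[below], 0.8)
  # missing covariate is an explicit error
  coh$marker1[1] <- NA
  expect_error(true_linear_predictor(coh, gm1), "missing")
})

test_that("inject_missingness hits its target rates and spares outcomes", {
  cfg <- cohort_config(n_patients = 401)
  coh <- generate_cohort(cfg, null_model(), seed = 2, n_markers = 14)
  mk <- paste0("marker", 1:14)
  spec <- missingness_spec(setNames(rep(0.052, 14), mk))
  out <- inject_missingness(coh, spec, seed = 10)
  rates <- vapply(mk, function(v) mean(is.na(out[[v]])), 0)
  # mean realised rate ~ 5.2% within simulation error of the pooled binomial
  expect_lt(abs(mean(rates) - 0.052),
            3 * sqrt(0.052 * 0.948 / (401 * 14)))
  expect_false(anyNA(out$time_rfs) || anyNA(out$event_rfs))
  # complete-case count equals the brute-force row-wise mask intersection
  cc_oracle <- sum(Reduce(`&`, lapply(mk, function(v) !is.na(out[[v]]))))
  expect_equal(attr(out, "n_complete"), cc_oracle)
  # zero rates: identity
  out0 <- inject_missingness(coh, missingness_spec(c(marker1 = 0)), seed = 1)
  expect_identical(out0$marker1, coh$marker1)
  # determinism
  expect_identical(inject_missingness(coh, spec, seed = 10)$marker3,
                   out$marker3)
})

test_that("missingness_spec rejects invalid configurations", {
  expect_error(missingness_spec(c(marker1 = 0.7)), "0, 0.5")
  expect_error(missingness_spec(c(event_rfs = 0.1)), "outcome")
  expect_error(missingness_spec(c(a = 0.1), mechanism = "MAR"), "mar_driver")
})

test_that("MAR missingness depends on its driver but holds the marginal rate", {
  cfg <- cohort_config(n_patients = 2000)
  coh <- generate_cohort(cfg, null_model(), seed = 4, n_markers = 1)
  spec <- missingness_spec(c(marker1 = 0.2), mechanism = "MAR",
                           mar_driver = "age", mar_slope = 1.5)
  out <- inject_missingness(coh, spec, seed = 5)
  r <- mean(is.na(out$marker1))
  expect_lt(abs(r - 0.2), 3 * sqrt(0.2 * 0.8 / 2000))
  # older patients more often missing (positive slope on age)
  expect_gt(mean(coh$age[is.na(out$marker1)]),
            mean(coh$age[!is.na(out$marker1)]))
})

test_that("calibrate_baseline hits a target event fraction", {
  gm <- generating_model(list(
    list(variable = "marker1", form = form_linear(scaling = c(0, 100)),
         beta = 0.5)))
  cfg <- cohort_config(n_patients = 401)
  h0 <- calibrate_baseline(cfg, gm, target_event_fraction = 112 / 401,
                           n_sim = 20000, seed = 2)
  gm2 <- gm; gm2$baseline_hazard <- h0
  coh <- generate_cohort(cohort_config(n_patients = 8000), gm2, seed = 6)
  expect_lt(abs(mean(coh$event_rfs) - 112 / 401), 0.02)
})

test_that("cohort CSV round-trip preserves data and missingness", {
  cfg <- cohort_config(n_patients = 40)
  coh <- generate_cohort(cfg, null_model(), seed = 12, n_markers = 2)
  coh <- inject_missingness(coh, missingness_spec(c(marker1 = 0.2)), seed = 3)
  f <- tempfile(fileext = ".csv")
  write_cohort(coh, f, sidecar = list(seed = 12, n = 40))
  back <- read_cohort(f)
  expect_equal(as.data.frame(back), as.data.frame(coh),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(file.exists(paste0(f, ".meta")))
  unlink(c(f, paste0(f, ".meta")))
})

test_that("covariate moments at n = 5000 match their specification", {
  cfg <- cohort_config(n_patients = 5000)
  coh <- generate_cohort(cfg, null_model(), seed = 14, n_markers = 1)
  n <- 5000
  # ordinal clinical proportions within 3 binomial SEs
  for (k in 1:3) {
    p <- cfg$nodal_probs[k]
    expect_lt(abs(mean(coh$nodal == k) - p), 3 * sqrt(p * (1 - p) / n))
  }
  # age: normal (truncation at 25/95 is ~4 sigma, negligible)
  expect_lt(abs(mean(coh$age) - cfg$age_mean), 3 * cfg$age_sd / sqrt(n))
  # tumour size: log-normal mean
  mu_size <- exp(cfg$size_meanlog + cfg$size_sdlog^2 / 2)
  sd_size <- mu_size * sqrt(exp(cfg$size_sdlog^2) - 1)
  expect_lt(abs(mean(coh$size) - mu_size), 3 * sd_size / sqrt(n))
  # histoscore: truncated-gamma mean computed by direct integration (oracle)
  sh <- cfg$histoscore_skew; rt <- sh / cfg$histoscore_mean
  mu_tr <- integrate(function(x) x * dgamma(x, sh, rt), 0, 300)$value +
    300 * pgamma(300, sh, rt, lower.tail = FALSE)
  expect_lt(abs(mean(coh$marker1) - mu_tr), 3 * sd(coh$marker1) / sqrt(n))
})

test_that("the full true score outranks every strict sub-model's score", {
  w <- example_world()
  big <- w$cohort_config; big$n_patients <- 4000L
  coh <- generate_cohort(big, w$model, seed = 15)
  c_full <- harrell_c(attr(coh, "true_lp"), coh$time_rfs, coh$event_rfs)
  for (drop in seq_along(w$model$effects)) {
    sub <- w$model; sub$effects <- sub$effects[-drop]
    c_sub <- harrell_c(true_linear_predictor(coh, sub),
                       coh$time_rfs, coh$event_rfs)
    expect_gt(c_full, c_sub)
  }
})
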