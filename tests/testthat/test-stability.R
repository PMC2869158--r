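# cohort with named effects for the multivariate stage
sim_multi_cohort <- function(n, betas = c(strong = 0), n_noise = 3, seed = 1,
                             base = 0.05) {
  set.seed(seed)
  d <- data.frame(id = seq_len(n))
  for (v in names(betas)) d[[v]] <- rnorm(n)
  for (k in seq_len(n_noise)) d[[paste0("nz", k)]] <- rnorm(n)
  lp <- as.matrix(d[names(betas)]) %*% betas
  t_ev <- -log(runif(n)) / (base * exp(lp))
  t_cn <- pmin(rexp(n, 0.08), 10)
  d$time_rfs <- pmin(t_ev, t_cn)
  d$event_rfs <- as.integer(t_ev <= t_cn)
  d
}

lin_forms <- function(vars) setNames(lapply(vars, function(v) form_linear()),
                                     vars)

test_that("mfp_backward retains a strong predictor and drops noise at ~0.05", {
  set.seed(80)
  ret_strong <- ret_noise <- c()
  for (r in 1:30) {
    d <- sim_multi_cohort(400, c(strong = 1.0), n_noise = 3, seed = 100 + r)
    forms <- lin_forms(c("strong", paste0("nz", 1:3)))
    m <- mfp_backward(d, forms, fp_vars = character(0))
    ret_strong <- c(ret_strong, "strong" %in% m$retained)
    ret_noise <- c(ret_noise, paste0("nz", 1:3) %in% m$retained)
  }
  expect_gt(mean(ret_strong), 0.95)
  # per-variable type-I retention ~ alpha_remove = 0.05
  expect_lt(abs(mean(ret_noise) - 0.05), 3 * sqrt(0.05 * 0.95 / 90) + 0.02)
})

test_that("mfp_backward upgrades a truly nonlinear variable to an FP form", {
  set.seed(81)
  hits <- 0
  for (r in 1:10) {
    n <- 500
    d <- data.frame(id = 1:n, x = 20 + pmin(rgamma(n, 1.4, 1.4 / 100), 280),
                    z = rnorm(n))
    lp <- 0.18 * (d$x / 100)^-2 + 0.5 * d$z
    t_ev <- -log(runif(n)) / (0.04 * exp(lp))
    t_cn <- pmin(rexp(n, 0.08), 10)
    d$time_rfs <- pmin(t_ev, t_cn); d$event_rfs <- as.integer(t_ev <= t_cn)
    forms <- list(x = form_linear(scaling = c(0, 100)), z = form_linear())
    m <- mfp_backward(d, forms, fp_vars = "x")
    if ("x" %in% m$retained && m$forms$x$kind %in% c("fp1", "fp2"))
      hits <- hits + 1
  }
  expect_gte(hits, 6)
})

test_that("an empty final model is a valid mfp_backward outcome", {
  d <- sim_multi_cohort(150, c(strong = 0), n_noise = 2, seed = 7)
  forms <- lin_forms(c("strong", "nz1", "nz2"))
  set.seed(1)
  m <- mfp_backward(d, forms, fp_vars = character(0))
  expect_true(is.character(m$retained))   # possibly empty, but well-formed
})

test_that("reassess_special_form confirms real thresholds and rejects noise", {
  set.seed(82)
  n <- 400
  x <- pmin(rgamma(n, 1.4, 1.4 / 110), 300)
  lp <- 1.2 * (x >= 104)
  t_ev <- -log(runif(n)) / (0.05 * exp(lp))
  t_cn <- pmin(rexp(n, 0.08), 10)
  d <- data.frame(x = x, noise = pmin(rgamma(n, 1.4, 1.4 / 110), 300),
                  time = pmin(t_ev, t_cn), event = as.integer(t_ev <= t_cn))
  sf <- form_threshold(104)
  # idempotence on data where the scan selects
  expect_true(reassess_special_form(d$time, d$event, d$x, sf))
  # bootstrap re-selection fraction is high for the real effect
  hit_real <- logical(60)
  for (b in 1:60) {
    rows <- sample.int(n, n, replace = TRUE)
    hit_real[b] <- reassess_special_form(d$time[rows], d$event[rows],
                                         d$x[rows], sf)
  }
  expect_gt(mean(hit_real), 0.5)
  # a pure-noise variable re-selects at about the scan's null rate (~10%,
  # well below 50%) on independent replicates; note that on bootstrap
  # resamples row duplication inflates the log-rank statistic, so the null
  # calibration is only clean on fresh draws
  hit_noise <- logical(60)
  for (b in 1:60) {
    t2_ev <- -log(runif(n)) / (0.05 * exp(lp))
    t2 <- pmin(t2_ev, t_cn); e2 <- as.integer(t2_ev <= t_cn)
    hit_noise[b] <- reassess_special_form(
      t2, e2, pmin(rgamma(n, 1.4, 1.4 / 110), 300), sf)
  }
  expect_lt(mean(hit_noise), 0.5)
  # degenerate sample: no events -> FALSE, not an error
  expect_false(reassess_special_form(d$time, rep(0, n), d$x, sf))
})

test_that("inclusion_frequency counts and verdicts follow the 50% rules", {
  mk <- function(vars) structure(list(retained = vars,
                                      forms = lin_forms(vars)),
                                 class = "sample_model")
  models <- list(mk(c("A", "B")), mk("A"), mk(c("A", "C")), mk("B"))
  rep1 <- inclusion_frequency(models, candidates = c("A", "B", "C"))
  expect_equal(unname(rep1$inclusion_frequency[c("A", "B", "C")]),
               c(0.75, 0.5, 0.25))
  # 0.44 -> unreliable; boundary 0.5 -> retained ("at least 50%")
  expect_equal(unname(rep1$verdict[["B"]]), "reliable-stable")
  expect_equal(unname(rep1$verdict[["C"]]), "unreliable")
  # retained often enough but with an unstable form -> unstable-form
  forms_scr <- list(A = form_linear())
  models2 <- list(mk("A"), mk("A"),
                  structure(list(retained = "A", forms = list(A = form_fp1(2))),
                            class = "sample_model"),
                  structure(list(retained = "A", forms = list(A = form_fp1(0))),
                            class = "sample_model"))
  rep2 <- inclusion_frequency(models2, candidates = "A",
                              screened_forms = forms_scr)
  expect_equal(unname(rep2$form_stability[["A"]]), 0.5)
  expect_equal(unname(rep2$verdict[["A"]]), "reliable-stable")
  models3 <- models2[c(1, 3, 3, 4)]   # linear form manifests in only 25%
  rep3 <- inclusion_frequency(models3, candidates = "A",
                              screened_forms = forms_scr)
  expect_equal(unname(rep3$verdict[["A"]]), "unstable-form")
})

test_that("refine returns exactly the reliable-stable variables", {
  freq <- c(nodal = 0.98, size = 0.952, kras = 0.816, pgr = 0.44, pten = 0.595)
  stab <- c(nodal = 1, size = 1, kras = 0.8, pgr = 1, pten = 0.3)
  verdict <- ifelse(freq < 0.5, "unreliable",
                    ifelse(stab < 0.5, "unstable-form", "reliable-stable"))
  rep_ <- structure(list(inclusion_frequency = freq, form_stability = stab,
                         verdict = verdict, n_models = 1000, threshold = 0.5),
                    class = "stability_report")
  forms <- lin_forms(names(freq))
  out <- refine(rep_, forms)
  expect_setequal(names(out), c("nodal", "size", "kras"))
  # all pass -> identity
  rep_$verdict[] <- "reliable-stable"
  expect_setequal(names(refine(rep_, forms)), names(freq))
  # empty outcome allowed, flagged
  rep_$verdict[] <- "unreliable"
  out0 <- refine(rep_, forms)
  expect_length(out0, 0)
  expect_true(isTRUE(attr(out0, "empty")))
})

test_that("stability report serialises with the verdict key", {
  freq <- c(a1 = 0.9, a2 = 0.4)
  rep_ <- inclusion_frequency(
    list(structure(list(retained = "a1", forms = lin_forms("a1")),
                   class = "sample_model")),
    candidates = c("a1", "a2"))
  f <- tempfile(fileext = ".csv")
  write_stability(rep_, f)
  d <- read.csv(f)
  expect_equal(d$key[d$variable == "a2"], "a")
  expect_equal(d$inclusion_frequency[d$variable == "a1"], 100)
  unlink(f)
})
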