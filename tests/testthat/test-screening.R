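# histoscore-like covariate with a survival outcome driven by a chosen form
sim_marker_surv <- function(n, lp_fun = function(x) 0, base = 0.06,
                            cens = 0.08, admin = 10, skew = 1.4, mean = 90) {
  x <- pmin(rgamma(n, skew, rate = skew / mean), 300)
  t_ev <- -log(runif(n)) / (base * exp(lp_fun(x)))
  t_cn <- pmin(rexp(n, cens), admin)
  list(time = pmin(t_ev, t_cn), event = as.integer(t_ev <= t_cn), x = x)
}

test_that("fp_closed_test selects the linear form for a strong linear effect", {
  set.seed(60)
  hits <- form_kind <- character(20)
  for (r in 1:20) {
    d <- sim_marker_surv(2000, function(x) 0.008 * (x - 90))
    res <- fp_closed_test(d$time, d$event, d$x)
    form_kind[r] <- if (res$selected) res$form$kind else "none"
  }
  expect_gte(mean(form_kind == "linear"), 0.9)
})

test_that("fp_closed_test holds the 0.1 selection rate under the null", {
  set.seed(61)
  reps <- 400
  sel <- logical(reps)
  for (r in seq_len(reps)) {
    d <- sim_marker_surv(120)
    sel[r] <- fp_closed_test(d$time, d$event, d$x)$selected
  }
  expect_lt(abs(mean(sel) - 0.1), 3 * sqrt(0.1 * 0.9 / reps) + 0.01)
})

test_that("fp_closed_test recovers a reciprocal-square (FP1 p=-2) effect", {
  set.seed(62)
  kinds <- character(15); powers <- numeric(15)
  for (r in 1:15) {
    # reciprocal-square effect on a histoscore bounded away from zero (so the
    # generating transform coincides with the frozen screening scale x/100)
    n <- 800
    x <- 20 + pmin(rgamma(n, 1.4, rate = 1.4 / 100), 280)
    lp <- 0.15 * (x / 100)^-2
    t_ev <- -log(runif(n)) / (0.04 * exp(lp))
    t_cn <- pmin(rexp(n, 0.08), 10)
    res <- fp_closed_test(pmin(t_ev, t_cn), as.integer(t_ev <= t_cn), x)
    kinds[r] <- if (res$selected) res$form$kind else "none"
    powers[r] <- if (kinds[r] == "fp1") res$form$powers else NA
  }
  # modal selected form is FP1 with p = -2
  expect_gte(mean(kinds == "fp1"), 0.5)
  expect_equal(as.numeric(names(which.max(table(powers)))), -2)
})

test_that("fp_closed_test skips variables with too few distinct values", {
  set.seed(63)
  d <- sim_surv(100)
  res <- fp_closed_test(d$time, d$event, sample(1:3, 100, replace = TRUE))
  expect_false(res$selected)
  expect_match(res$status, "distinct")
})

test_that("minp_scan equals the exhaustive survdiff scan (oracle equivalence)", {
  set.seed(64)
  cfg <- screening_config()
  n_checked <- 0
  for (r in 1:100) {
    n <- sample(25:70, 1)
    d <- sim_marker_surv(n)
    if (r %% 3 == 0) d$x <- round(d$x)      # induce ties among cutpoints
    if (sum(d$event) < 2) next
    res <- minp_scan(d$time, d$event, d$x, cfg)
    cuts <- attr(res, "scan")$cut
    if (is.null(cuts)) next
    orc <- oracle_minp(d$time, d$event, d$x, cuts)
    expect_equal(attr(res, "best_cut"), orc$cut)
    expect_equal(res$p_value, orc$p, tolerance = 1e-09)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 80)
})

test_that("minp_scan handles degenerate variables and recovers a true cut", {
  set.seed(65)
  d <- sim_surv(60)
  res <- minp_scan(d$time, d$event, rep(5, 60))
  expect_false(res$selected)
  expect_match(res$status, "cutpoints")
  # step effect at histoscore 104: recovered cut near 104 across replicates
  cuts <- numeric(12)
  for (r in 1:12) {
    dd <- sim_marker_surv(500, function(x) 1.1 * (x >= 104), mean = 110)
    rr <- minp_scan(dd$time, dd$event, dd$x)
    cuts[r] <- if (rr$selected) rr$form$cut else NA
  }
  expect_true(all(!is.na(cuts)))
  # within the central 10% of the marker distribution around 104
  dd <- sim_marker_surv(5000, function(x) 0, mean = 110)
  lo <- quantile(dd$x, mean(dd$x <= 104) - 0.05)
  hi <- quantile(dd$x, mean(dd$x <= 104) + 0.05)
  expect_gte(mean(cuts >= lo & cuts <= hi), 0.75)
})

test_that("nonordinal_scan uses the Bonferroni threshold and finds an R3 effect", {
  # threshold arithmetic: 0.1 / 4 comparisons
  expect_equal(screening_config()$alpha_nonordinal, 0.025)
  set.seed(66)
  pats <- character(12)
  for (r in 1:12) {
    d <- sim_marker_surv(600, function(x) {
      q <- quantile(x, c(0.5, 0.75))
      0.9 * (x > q[1] & x <= q[2])   # risk concentrated between Q2 and Q3
    })
    res <- nonordinal_scan(d$time, d$event, d$x)
    pats[r] <- if (res$selected) res$form$pattern else "none"
  }
  expect_equal(names(which.max(table(pats))), "R3")
})

test_that("nonordinal_scan family-wise null rate stays below 0.1", {
  set.seed(67)
  reps <- 300
  sel <- logical(reps)
  for (r in seq_len(reps)) {
    d <- sim_marker_surv(120)
    sel[r] <- nonordinal_scan(d$time, d$event, d$x)$selected
  }
  expect_lte(mean(sel), 0.1 + 3 * sqrt(0.1 * 0.9 / reps))
})

test_that("screen_all runs the cascade exclusively and serialises", {
  set.seed(68)
  n <- 500
  q3 <- qgamma(0.75, 1.4, rate = 1.4 / 90) # upper-quartile-ish region
  coh <- data.frame(id = 1:n)
  coh$lin <- pmin(rgamma(n, 1.4, rate = 1.4 / 90), 300)
  coh$thr <- pmin(rgamma(n, 1.4, rate = 1.4 / 90), 300)
  coh$noise <- pmin(rgamma(n, 1.4, rate = 1.4 / 90), 300)
  coh$nodal <- sample(1:3, n, replace = TRUE)
  lp <- 0.009 * (coh$lin - 90) + 1.4 * (coh$thr >= 104) + 0.55 * (coh$nodal - 2)
  t_ev <- -log(runif(n)) / (0.05 * exp(lp))
  t_cn <- pmin(rexp(n, 0.08), 10)
  coh$time_rfs <- pmin(t_ev, t_cn)
  coh$event_rfs <- as.integer(t_ev <= t_cn)
  tab <- screen_all(coh, c("lin", "thr", "noise", "nodal"))
  df <- as.data.frame(tab)
  # exactly one result per variable, in input order
  expect_equal(df$variable, c("lin", "thr", "noise", "nodal"))
  expect_true(tab$lin$selected)
  expect_equal(tab$lin$form$kind, "linear")
  expect_true(tab$nodal$selected)           # ordinal: linear-only route
  expect_equal(tab$nodal$method, "linear")
  expect_true(tab$thr$selected)
  # cascade exclusivity: a variable selected by fp is never scanned further
  expect_equal(tab$lin$method, "fp")
  f <- tempfile(fileext = ".csv")
  write_screening(tab, f)
  expect_equal(nrow(read.csv(f)), 4)
  unlink(f)
  # empty variable list -> empty result
  expect_length(screen_all(coh, character(0)), 0)
  expect_error(screen_all(coh, "absent"), "absent")
})
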