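# Independent oracles: deliberately naive implementations used to check the
# package's fast paths. They share no code with the implementation.

# Cox partial log-likelihood for a single covariate, untied times (Breslow
# and Efron coincide without ties); brute-force maximiser over beta.
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + x[i] * beta - log(sum(exp(x[risk] * beta)))
  }
  ll
}

oracle_cox_mle <- function(time, event, x, interval = c(-10, 10)) {
  stats::optimize(oracle_cox_loglik, interval, time = time, event = event,
                  x = x, maximum = TRUE, tol = 1e-10)$maximum
}

# score vector of the multivariate partial likelihood (untied data)
oracle_cox_gradient <- function(beta, time, event, X) {
  eta <- as.numeric(X %*% beta)
  U <- numeric(ncol(X))
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    w <- exp(eta[risk])
    U <- U + X[i, ] - colSums(X[risk, , drop = FALSE] * w) / sum(w)
  }
  U
}

# product-limit estimator, direct definition
oracle_km <- function(time, event, at) {
  tj <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(at))
  for (k in seq_along(at)) {
    s <- 1
    for (t in tj[tj <= at[k]]) {
      n_risk <- sum(time >= t)
      d <- sum(time == t & event == 1)
      s <- s * (1 - d / n_risk)
    }
    out[k] <- s
  }
  out
}

# Harrell's C by explicit double loop over all ordered pairs
oracle_harrell_c <- function(scores, time, event) {
  num <- den <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (scores[i] > scores[j]) num <- num + 1
      else if (scores[i] == scores[j]) num <- num + 0.5
    }
  }
  num / den
}

# two-group log-rank chi-square from the O-E / variance table
oracle_logrank_chisq <- function(time, event, group) {
  tj <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in tj) {
    risk <- time >= t
    n <- sum(risk); n1 <- sum(risk & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# exhaustive minimum-p threshold scan via survival::survdiff (independent of
# the package's vectorised accumulation)
oracle_minp <- function(time, event, x, cuts) {
  ps <- vapply(cuts, function(c) {
    g <- as.integer(x >= c)
    if (length(unique(g)) < 2) return(NA_real_)
    sd <- survival::survdiff(survival::Surv(time, event) ~ g)
    pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  }, numeric(1))
  k <- which.min(ps)
  list(cut = cuts[k], p = ps[k], ps = ps)
}

# small survival data generator used across tests
sim_surv <- function(n, beta = 0, x = rnorm(n), base = 0.1, cens = 0.05,
                     admin = 20) {
  t_ev <- -log(runif(n)) / (base * exp(beta * x))
  t_cn <- pmin(rexp(n, cens), admin)
  list(time = pmin(t_ev, t_cn), event = as.integer(t_ev <= t_cn), x = x)
}

# six-subject two-group fixture with distinct times (for the grid oracle)
fixture6 <- function() {
  list(time = c(1, 2, 3, 4, 5, 6),
       event = c(1, 1, 0, 1, 1, 0),
       x = c(1, 0, 1, 0, 1, 0))
}
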