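# Shared scenario builders and naive test-side oracles.

# clean proportional-hazards, log-linear multiplicative data (the same
# conditions under which the PH test calibration is asserted: exponential
# baseline and censoring, moderate effects)
clean_mult_scenario <- function(n = 500) {
  sim_scenario(
    n = n, family = "multiplicative",
    baseline = list(times = 0, rates = 0.5),
    covariates = list(z1 = list(dist = "normal", mean = 0, sd = 1),
                      z2 = list(dist = "bernoulli", p = 0.5)),
    effects = list(z1 = list(coef = 0.5), z2 = list(coef = 0.5)),
    censoring = list(admin = Inf, rate = 0.25), horizon = 20
  )
}

# clean constant-coefficient additive data
clean_add_scenario <- function(n = 800) {
  sim_scenario(
    n = n, family = "additive",
    baseline = list(times = 0, rates = 0.3),
    covariates = list(z1 = list(dist = "uniform", min = 0, max = 2),
                      z2 = list(dist = "bernoulli", p = 0.5)),
    effects = list(z1 = list(coef = 0.15), z2 = list(coef = 0.1)),
    censoring = list(admin = 3, rate = 0.05), horizon = 3
  )
}

# small random censored sample with one covariate
random_small_sample <- function(seed, n = 5, binary = TRUE) {
  set.seed(seed)
  df <- data.frame(
    id = seq_len(n),
    time = round(stats::rexp(n, 0.5) + 0.05, 3) + seq_len(n) * 1e-4,
    event = stats::rbinom(n, 1, 0.7),
    x = if (binary) stats::rbinom(n, 1, 0.5) else round(stats::rnorm(n), 2)
  )
  if (sum(df$event) == 0) df$event[1] <- 1L
  survival_sample(df)
}

# naive Kaplan-Meier / Nelson-Aalen by explicit iteration over event times
naive_km_na <- function(sample, t) {
  et <- sort(unique(sample$time[sample$event == 1]))
  km <- 1; na <- 0
  for (tj in et[et <= t]) {
    d <- sum(sample$time == tj & sample$event == 1)
    y <- sum(sample$time >= tj)
    km <- km * (1 - d / y)
    na <- na + d / y
  }
  c(km = km, na = na)
}

# naive leave-one-out Kaplan-Meier via survfit refits
naive_pseudo <- function(sample, grid) {
  n <- nrow(sample)
  km_at <- function(df, t) {
    f <- survival::survfit(survival::Surv(time, event) ~ 1, data = df)
    vapply(t, function(tt) {
      k <- which(f$time <= tt & f$n.event > 0)
      if (length(k)) prod(1 - f$n.event[k] / f$n.risk[k]) else 1
    }, numeric(1))
  }
  full <- km_at(sample, grid)
  out <- matrix(0, n, length(grid))
  for (i in seq_len(n)) {
    out[i, ] <- n * full - (n - 1) * km_at(sample[-i, ], grid)
  }
  out
}

# naive Lin-Ying estimator: direct O(n^2) evaluation of the estimating
# equation (independent of the package's incremental implementation)
naive_lin <- function(sample, xcols) {
  X <- as.matrix(sample[xcols])
  k <- ncol(X)
  ut <- sort(unique(sample$time))
  A <- matrix(0, k, k); b <- numeric(k)
  prev <- 0
  for (tt in ut) {
    at_risk <- sample$time >= tt
    Xr <- X[at_risk, , drop = FALSE]
    xbar <- colMeans(Xr)
    Xc <- sweep(Xr, 2, xbar)
    A <- A + (tt - prev) * crossprod(Xc)
    ev <- which(sample$time == tt & sample$event == 1)
    for (i in ev) b <- b + (X[i, ] - xbar)
    prev <- tt
  }
  solve(A, b)
}
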