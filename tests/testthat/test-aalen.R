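two_group_sample <- function() {
  survival_sample(data.frame(
    id = 1:4, time = c(1, 3, 2, 3), event = c(1, 0, 1, 1), g = c(0, 0, 1, 1)
  ))
}

test_that("two-group Aalen fit equals group-wise Nelson-Aalen differences", {
  af <- fit_aalen(two_group_sample())
  expect_equal(af$times, c(1, 2, 3))
  expect_equal(unname(af$B[, "g_x"]), c(-0.5, 0, 1))
  expect_equal(unname(af$B[, "(Intercept)"]), c(0.5, 0.5, 0.5))

  # property on random binary datasets: B0 = NA(group 0), B1 = NA(g1)-NA(g0)
  for (sd in 1:8) {
    s <- random_small_sample(sd + 40, n = 10)
    if (length(unique(s$x)) < 2) next
    af <- fit_aalen(s)
    na0 <- nelson_aalen(s[s$x == 0, ])
    na1 <- nelson_aalen(s[s$x == 1, ])
    for (j in seq_along(af$times)) {
      t <- af$times[j]
      expect_equal(unname(af$B[j, "(Intercept)"]), step_eval(na0, t),
                   tolerance = 1e-10)
      expect_equal(unname(af$B[j, "x_x"]),
                   step_eval(na1, t) - step_eval(na0, t), tolerance = 1e-10)
    }
  }
})

test_that("intercept-only Aalen fit is exactly Nelson-Aalen", {
  s <- random_small_sample(9, n = 12)
  af <- fit_aalen(s, terms = list())
  na <- nelson_aalen(s)
  expect_equal(unname(af$B[, 1]), step_eval(na, af$times), tolerance = 1e-12)
})

test_that("Aalen increments agree with survival::aareg", {
  set.seed(77)
  s <- survival_sample(data.frame(
    id = 1:80, time = rexp(80, 0.4) + 0.01, event = rbinom(80, 1, 0.75),
    x = rnorm(80)
  ))
  af <- fit_aalen(s)
  ref <- survival::aareg(survival::Surv(time, event) ~ x, data = s)
  keep <- seq_along(ref$times) # aareg stops at the same rank condition
  expect_equal(af$times[seq_along(keep)], ref$times, tolerance = 1e-10)
  expect_equal(unname(af$increments[seq_along(keep), ]),
               unname(ref$coefficient), tolerance = 1e-8)
})

test_that("negative cumulative effects are legal, rank loss truncates", {
  af <- fit_aalen(two_group_sample())
  expect_lt(min(af$B[, "g_x"]), 0) # not an error
  # all subjects in one group beyond some time: truncation, not failure
  s <- survival_sample(data.frame(
    id = 1:6, time = c(1, 2, 3, 4, 5, 6), event = 1,
    x = c(0, 1, 0, 1, 1, 1)
  ))
  af2 <- fit_aalen(s)
  expect_true(af2$truncated)
  expect_lt(af2$last_time, 6)
  expect_error(fit_aalen(survival_sample(
    data.frame(id = 1:3, time = 1:3, event = c(1, 1, 0), x = 1)
  )), "rank|no estimate")
})

test_that("Lin-Ying estimator matches a naive O(n^2) evaluation", {
  for (sd in 1:5) {
    s <- random_small_sample(sd + 60, n = 30, binary = sd %% 2 == 0)
    lf <- fit_lin(s)
    expect_equal(unname(lf$coefficients), unname(naive_lin(s, "x")),
                 tolerance = 1e-10)
  }
})

test_that("Lin-Ying recovers a constant additive effect with valid CIs", {
  scen <- sim_scenario(
    n = 4000, family = "additive", baseline = list(times = 0, rates = 0.3),
    covariates = list(z = list(dist = "bernoulli", p = 0.5)),
    effects = list(z = list(coef = 0.2)),
    censoring = list(admin = 3, rate = 0), horizon = 3
  )
  s <- simulate_additive(scen, seed = 17)
  lf <- fit_lin(s)
  se <- sqrt(diag(lf$vcov))
  expect_lt(abs(unname(lf$coefficients) - 0.2), 3 * se)
  # null covariate: CI covers 0 most of the time
  scen0 <- sim_scenario(
    n = 800, family = "additive", baseline = list(times = 0, rates = 0.3),
    covariates = list(z = list(dist = "bernoulli", p = 0.5)),
    effects = list(), censoring = list(admin = 3, rate = 0), horizon = 3
  )
  hits <- mean(sapply(1:40, function(r) {
    s0 <- simulate_additive(scen0, seed = 300 + r)
    l0 <- fit_lin(s0)
    abs(unname(l0$coefficients)) < 1.96 * sqrt(diag(l0$vcov))
  }))
  expect_gte(hits, 0.85)
})

test_that("Lin baseline reduces to Nelson-Aalen minus the fitted drift", {
  s <- random_small_sample(71, n = 25)
  lf <- fit_lin(s)
  na <- nelson_aalen(s)
  gam <- unname(lf$coefficients)
  # recompute the drift integral independently
  ut <- sort(unique(s$time))
  drift <- 0; prev <- 0
  drift_at <- numeric(0)
  for (tt in ut) {
    xbar <- mean(s$x[s$time >= tt])
    drift <- drift + (tt - prev) * xbar * gam
    drift_at[as.character(tt)] <- drift
    prev <- tt
  }
  for (tt in lf$baseline$times) {
    expect_equal(step_eval(lf$baseline, tt),
                 unname(step_eval(na, tt) - drift_at[as.character(tt)]),
                 tolerance = 1e-10)
  }
})

test_that("constant-effect check separates constant from transient effects", {
  scenC <- sim_scenario(
    n = 1000, family = "additive", baseline = list(times = 0, rates = 0.3),
    covariates = list(z = list(dist = "bernoulli", p = 0.5)),
    effects = list(z = list(coef = 0.2)),
    censoring = list(admin = 3, rate = 0.05), horizon = 3
  )
  ok <- sapply(1:100, function(r) {
    s <- simulate_additive(scenC, seed = r)
    constant_effect_check(fit_aalen(s), fit_lin(s), "z_x")$constant
  })
  expect_gte(mean(ok), 0.9)

  scenE <- sim_scenario(
    n = 1000, family = "additive", baseline = list(times = 0, rates = 0.3),
    covariates = list(z = list(dist = "bernoulli", p = 0.5)),
    effects = list(z = list(coef = list(times = c(0, 0.499, 0.5, 3),
                                        values = c(0.6, 0.6, 0, 0)))),
    censoring = list(admin = 3, rate = 0.05), horizon = 3
  )
  bad <- sapply(1:60, function(r) {
    s <- simulate_additive(scenE, seed = 300 + r)
    constant_effect_check(fit_aalen(s), fit_lin(s), "z_x")$constant
  })
  expect_gte(mean(!bad), 0.9)

  # degenerate self-comparison: zero-width band, full coverage
  s <- simulate_additive(scenC, seed = 5)
  lf <- fit_lin(s)
  self <- constant_effect_check(lf, lf, "z_x")
  expect_equal(self$coverage, 1)
})

test_that("martingale residual processes are exact zero for saturated strata", {
  s <- simulate_additive(clean_add_scenario(300), seed = 44)
  af <- fit_aalen(s, terms = list(haz_term("z2")))
  mrp <- martingale_residual_process(af, factor(s$z2), resamples = 100,
                                     seed = 1)
  expect_equal(max(abs(mrp$M)), 0)
  tst <- mrp_chisq_test(mrp)
  expect_true(all(tst$table$p == 1))
  expect_false(tst$reject)

  # three-level categorical through dummy encoding
  set.seed(9)
  df <- data.frame(id = 1:150, time = rexp(150, 0.4) + 0.01,
                   event = rbinom(150, 1, 0.7),
                   grp = sample(c("a", "b", "c"), 150, replace = TRUE))
  s3 <- survival_sample(df)
  af3 <- fit_aalen(s3, terms = lapply(covariate_names(s3), haz_term))
  mrp3 <- martingale_residual_process(
    af3, factor(df$grp), resamples = 100, seed = 2
  )
  expect_lt(max(abs(mrp3$M)), 1e-10)
})

test_that("MRP bounds are seeded deterministically and flag empty strata", {
  s <- simulate_additive(clean_add_scenario(200), seed = 45)
  af <- fit_aalen(s)
  st <- strata_by_quantiles(s$z1, 4)
  m1 <- martingale_residual_process(af, st, resamples = 120, seed = 7)
  m2 <- martingale_residual_process(af, st, resamples = 120, seed = 7)
  expect_identical(m1$lower, m2$lower)
  expect_identical(m1$boot_tau, m2$boot_tau)
  expect_error(martingale_residual_process(af, st, resamples = 50, seed = 1),
               "100 resamples")
  # a stratum without events is reported as low-information
  st2 <- factor(ifelse(s$time == max(s$time), "edge", "rest"))
  expect_message(martingale_residual_process(af, st2, resamples = 100,
                                             seed = 3),
                 "low-information")
})

test_that("MRP chi-square rejects a misspecified functional form", {
  scen <- sim_scenario(
    n = 2000, family = "additive", baseline = list(times = 0, rates = 0.1),
    covariates = list(z = list(dist = "normal", mean = 0, sd = 1)),
    effects = list(z = list(coef = 0.12, form = form_exp(1))),
    censoring = list(admin = 3, rate = 0.05), horizon = 3
  )
  s <- simulate_additive(scen, seed = 50)
  st <- strata_by_quantiles(s$z, 4)
  bad <- mrp_chisq_test(
    martingale_residual_process(fit_aalen(s), st, resamples = 300, seed = 4)
  )
  expect_lt(bad$table$p[bad$table$stratum == "global"], 0.05)
  good <- mrp_chisq_test(
    martingale_residual_process(
      fit_aalen(s, list(haz_term("z", form = form_exp(1)))),
      st, resamples = 300, seed = 5
    )
  )
  expect_gt(good$table$p[good$table$stratum == "global"], 0.05)
})
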