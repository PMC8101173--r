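three_subject <- function() {
  survival_sample(data.frame(id = 1:3, time = c(1, 2, 3),
                             event = c(1, 1, 0), x = c(1, 0, 1)))
}

test_that("the partial likelihood and its maximizer match closed forms", {
  cp <- split_episodes(three_subject())
  expect_equal(partial_loglik(cp, "x", 0), -log(6), tolerance = 1e-12)
  expect_equal(partial_loglik(cp, "x", -log(2) / 2), -1.76275,
               tolerance = 1e-4)
  fit <- fit_cox(cp, "x")
  expect_equal(unname(fit$coefficients), -log(2) / 2, tolerance = 1e-6)
  expect_equal(aic(fit), -2 * (-1.762747) + 2, tolerance = 1e-4)
  # null model: sum over events of -log(riskset size)
  expect_equal(partial_loglik(cp, character(0), numeric(0)),
               -log(3) - log(2), tolerance = 1e-12)
})

test_that("fit_cox equals a brute-force maximizer of partial_loglik", {
  for (sd in 1:6) {
    s <- random_small_sample(sd + 100, n = 6, binary = sd %% 2 == 0)
    if (stats::var(s$x) == 0 || sum(s$event) < 2) next
    cp <- split_episodes(s)
    fit <- try(fit_cox(cp, "x"), silent = TRUE)
    if (inherits(fit, "try-error")) next # monotone likelihood draws
    grid <- stats::optimize(function(b) partial_loglik(cp, "x", b),
                            c(-4, 4), maximum = TRUE, tol = 1e-9)
    expect_equal(unname(fit$coefficients), grid$maximum, tolerance = 1e-4)
  }
})

test_that("symmetric event experience gives a zero coefficient", {
  s <- survival_sample(data.frame(
    id = 1:6, time = c(1, 2, 3, 1, 2, 3), event = c(1, 1, 0, 1, 1, 0),
    x = c(0, 0, 0, 1, 1, 1)
  ))
  fit <- fit_cox(split_episodes(s), "x") # Efron correction handles the ties
  expect_equal(unname(fit$coefficients), 0, tolerance = 1e-6)
})

test_that("degenerate designs and monotone likelihoods are reported", {
  s <- survival_sample(data.frame(id = 1:4, time = 1:4,
                                  event = c(1, 1, 1, 0), x = 1))
  expect_error(fit_cox(split_episodes(s), "x"), "degenerate|constant")
  # perfectly separating covariate diverges
  s2 <- survival_sample(data.frame(
    id = 1:8, time = c(1, 2, 3, 4, 11, 12, 13, 14),
    event = c(1, 1, 1, 1, 1, 1, 1, 1), x = c(1, 1, 1, 1, 0, 0, 0, 0)
  ))
  expect_error(fit_cox(split_episodes(s2), "x"), "monotone|diverge")
})

test_that("hazard ratios and AIC are invariant to covariate shifts", {
  s <- simulate_multiplicative(clean_mult_scenario(300), seed = 8)
  f1 <- fit_cox(split_episodes(s), c("z1", "z2"))
  s2 <- s
  s2$z1 <- s2$z1 + 100
  f2 <- fit_cox(split_episodes(s2), c("z1", "z2"))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
  expect_equal(aic(f1), aic(f2), tolerance = 1e-6)
})

test_that("Schoenfeld residuals match the weighted risk-set means", {
  fit <- fit_cox(split_episodes(three_subject()), "x")
  res <- schoenfeld_residuals(fit)
  u <- 2^(-1/2)
  expect_equal(res$x, c(1 - 2 * u / (2 * u + 1), -u / (1 + u)),
               tolerance = 1e-5)
  expect_equal(sum(res$x), 0, tolerance = 1e-6)
  expect_equal(res$rank, 1:2)

  # agreement with the survival package on a larger fit
  s <- simulate_multiplicative(clean_mult_scenario(200), seed = 3)
  f <- fit_cox(split_episodes(s), c("z1", "z2"))
  mine <- schoenfeld_residuals(f)
  ref <- stats::residuals(f$coxph, type = "schoenfeld")
  ord <- order(as.numeric(rownames(ref)))
  expect_equal(unname(as.matrix(mine[c("z1", "z2")])),
               unname(ref[ord, ]), tolerance = 1e-6)
})

test_that("x-constant risk sets give zero residuals and a satisfied verdict", {
  # delayed-entry episodes put each event alone in its risk set; such a
  # design carries no partial-likelihood information, so the degenerate
  # residual path is exercised on a hand-built fit at beta = 0
  cp <- structure(
    data.frame(id = 1:3, start = c(0, 1, 2), stop = c(1, 2, 3),
               status = 1L, x = c(0, 1, 2)),
    class = c("counting_process", "data.frame")
  )
  fit <- structure(
    list(coefficients = c(x = 0), vcov = matrix(Inf, 1, 1), loglik = 0,
         k = 1L, design = "x", data = cp, lp = rep(0, 3),
         baseline = hazoptim:::breslow_baseline(cp, rep(0, 3))),
    class = "cox_fit"
  )
  res <- schoenfeld_residuals(fit)
  expect_equal(res$x, rep(0, 3), tolerance = 1e-12)
  tst <- ph_test(fit)
  expect_equal(tst$p, 1)
  expect_true(tst$satisfied)
})

test_that("ph_test needs at least three events", {
  s <- survival_sample(data.frame(id = 1:4, time = 1:4,
                                  event = c(1, 1, 0, 0), x = c(1, 0, 1, 0)))
  fit <- fit_cox(split_episodes(s), "x")
  expect_error(ph_test(fit), "3 events")
})

test_that("martingale residuals sum to zero and expose functional form", {
  s <- simulate_multiplicative(clean_mult_scenario(400), seed = 5)
  fit <- fit_cox(split_episodes(s), c("z1", "z2"))
  m <- martingale_residuals(fit)
  expect_lt(abs(sum(m$residual)), 1e-8)
  expect_true(all(m$residual <= 1 + 1e-12))

  # null model: subject censored at the first event time
  s0 <- survival_sample(data.frame(id = 1:4, time = c(1, 1.5, 2, 3),
                                   event = c(1, 0, 1, 1)))
  null_fit <- fit_cox(split_episodes(s0), character(0))
  m0 <- martingale_residuals(null_fit)
  expect_equal(m0$residual[m0$id == "2"], -1/4, tolerance = 1e-12)

  # smoothed null-model residuals: convex in x under an exp(x) effect,
  # straight in exp(x)
  scen <- sim_scenario(
    n = 2000, family = "multiplicative",
    baseline = list(times = 0, rates = 0.25),
    covariates = list(z = list(dist = "normal", mean = 0, sd = 1)),
    effects = list(z = list(coef = 0.4, form = form_exp(1))),
    censoring = list(admin = 4, rate = 0.1), horizon = 4
  )
  sE <- simulate_multiplicative(scen, seed = 6)
  nf <- fit_cox(split_episodes(sE), character(0))
  mr <- martingale_residuals(nf)
  sm_x <- residual_smooth(mr, sE, "z")$smooth
  # convex increasing: the secant lies above the curve in the middle
  mid <- which.min(abs(sm_x$x - stats::median(sE$z)))
  sec <- sm_x$y[1] + (sm_x$y[length(sm_x$y)] - sm_x$y[1]) *
    (sm_x$x[mid] - sm_x$x[1]) / (sm_x$x[length(sm_x$x)] - sm_x$x[1])
  expect_gt(sec - sm_x$y[mid], 0.02)
  fit_fz <- fit_cox(build_cox_design(sE, list(haz_term("z", form = form_exp(1)))))
  fl_fit <- residual_smooth(martingale_residuals(fit_fz), sE, "z")$flatness
  fit_id <- fit_cox(build_cox_design(sE, list(haz_term("z"))))
  fl_id <- residual_smooth(martingale_residuals(fit_id), sE, "z")$flatness
  expect_lt(fl_fit, fl_id / 3) # the correct form flattens the smooth
})

test_that("functional_form_scan ranks the data-generating form first", {
  # log-linear truth
  s <- simulate_multiplicative(clean_mult_scenario(1000), seed = 12)
  scan <- functional_form_scan(s, "z1", list(form_identity(), form_exp(1)))
  expect_equal(scan$best$label, "x")
  # scaled-exponential truth
  scen <- sim_scenario(
    n = 1000, family = "multiplicative",
    baseline = list(times = 0, rates = 0.25),
    covariates = list(z = list(dist = "normal", mean = 0, sd = 1)),
    effects = list(z = list(coef = 0.5, form = form_exp(1))),
    censoring = list(admin = 4, rate = 0.1), horizon = 4
  )
  sE <- simulate_multiplicative(scen, seed = 13)
  scanE <- functional_form_scan(sE, "z", list(form_identity(), form_exp(1)))
  expect_equal(scanE$best$label, "exp(x/1)")
  expect_error(functional_form_scan(sE, "z", list(form_identity())),
               "2 candidate")
  # non-finite candidates (here: overflowing exp) are skipped with a warning
  expect_warning(
    functional_form_scan(sE, "z",
                         list(form_identity(), form_exp(1), form_exp(1e-3))),
    "non-finite"
  )
})

test_that("breakpoint_scan recovers a slope break and handles edge grids", {
  scen <- sim_scenario(
    n = 800, family = "multiplicative",
    baseline = list(times = 0, rates = 0.5),
    covariates = list(z = list(dist = "bernoulli", p = 0.5)),
    effects = list(z = list(coef = list(times = c(0, 0.5, 2),
                                        values = c(2, -0.3, -0.3)))),
    censoring = list(admin = 2, rate = 0), horizon = 2
  )
  s <- simulate_multiplicative(scen, seed = 21)
  sc <- breakpoint_scan(s, "z", grid = seq(0.2, 1.0, by = 0.1))
  expect_lte(abs(sc$best_break - 0.5), 0.1)
  expect_equal(nrow(sc$profile), 9)
  # one-point grid returns that point
  sc1 <- breakpoint_scan(s, "z", grid = 0.5)
  expect_equal(sc1$best_break, 0.5)
  # grid points beyond all events are skipped
  expect_warning(breakpoint_scan(s, "z", grid = c(0.5, 5)), "no events")
})

test_that("time-varying designs reduce to ordinary fits on split episodes", {
  scen <- sim_scenario(
    n = 600, family = "multiplicative",
    baseline = list(times = 0, rates = 0.5),
    covariates = list(z = list(dist = "bernoulli", p = 0.5)),
    effects = list(z = list(coef = list(times = c(0, 2), values = c(1.2, -0.4)))),
    censoring = list(admin = 2, rate = 0), horizon = 2
  )
  s <- simulate_multiplicative(scen, seed = 31)
  fit <- fit_cox(build_cox_design(s, list(haz_term("z", tv = tv_linear()))))
  co <- unname(fit$coefficients)
  # beta(t) = 1.2 - 0.8 t
  expect_equal(co[1], 1.2, tolerance = 0.35)
  expect_equal(co[2], -0.8, tolerance = 0.45)
  # matches coxph with a tt() term
  tfit <- survival::coxph(
    survival::Surv(time, event) ~ z + tt(z), data = s,
    tt = function(x, t, ...) x * t
  )
  expect_equal(co, unname(stats::coef(tfit)), tolerance = 1e-6)
})
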