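test_that("survival_sample validates its invariants", {
  ok <- data.frame(id = 1:4, time = c(1, 2, 3, 4), event = c(1, 0, 1, 0),
                   z = c(0.1, 0.2, 0.3, 0.4))
  s <- survival_sample(ok)
  expect_s3_class(s, "survival_sample")
  expect_equal(covariate_names(s), "z")

  expect_error(survival_sample(transform(ok, time = c(1, -2, 3, 4))),
               "strictly positive")
  expect_error(survival_sample(transform(ok, event = c(0, 1, 2, 0))),
               "0.*1|indicator")
  expect_error(survival_sample(transform(ok, id = c(1, 1, 3, 4))),
               "duplicated")
  bad <- ok; bad$z[2] <- NA
  expect_error(survival_sample(bad), "missing values")
})

test_that("categorical covariates are dummy-encoded with recorded reference", {
  df <- data.frame(id = 1:4, time = 1:4, event = c(1, 1, 0, 0),
                   grp = c("a", "b", "c", "a"))
  s <- survival_sample(df)
  expect_setequal(covariate_names(s), c("grp_b", "grp_c"))
  expect_equal(attr(s, "encoding")$grp$reference, "a")
  expect_equal(s$grp_b, c(0, 1, 0, 0))
})

test_that("read_survival_table parses CSV with a column map and flags problems", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pid,fu,dead,z", "1,1.5,1,0.2", "2,2.5,0,0.4",
               "3,0.5,1,0.1", "4,3.5,0,0.9"), p)
  s <- read_survival_table(p, column_map = list(id = "pid", time = "fu",
                                                event = "dead"))
  expect_equal(nrow(s), 4)
  expect_equal(covariate_names(s), "z")
  expect_error(
    read_survival_table(p, column_map = list(id = "pid", time = "fu",
                                             event = "status")),
    "status"
  )
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,time,event", "1,1,0", "2,2,2"), p2)
  expect_error(read_survival_table(p2), "indicator")
})

test_that("risk_set uses the at-risk-at-own-event-time convention", {
  s <- survival_sample(data.frame(id = 1:3, time = c(1, 2, 3),
                                  event = c(1, 1, 0)))
  expect_equal(risk_set(s, 2), c(2, 3))
  expect_equal(risk_set(s, 1), c(1, 2, 3))
  expect_equal(risk_set(s, 3.5), numeric(0))
})

test_that("Kaplan-Meier and Nelson-Aalen match hand computation", {
  s <- survival_sample(data.frame(id = 1:3, time = c(1, 2, 3),
                                  event = c(1, 1, 0)))
  expect_equal(step_eval(kaplan_meier(s), c(1, 2, 3)), c(2/3, 1/3, 1/3))
  expect_equal(step_eval(nelson_aalen(s), 2), 1/3 + 1/2)

  cens <- survival_sample(data.frame(id = 1:3, time = 1:3, event = 0))
  expect_equal(step_eval(kaplan_meier(cens), c(0.5, 2, 3)), c(1, 1, 1))
  expect_length(nelson_aalen(cens)$times, 0)
})

test_that("estimators agree with a brute-force oracle on tiny samples", {
  for (sd in 1:8) {
    s <- random_small_sample(sd, n = 5)
    km <- kaplan_meier(s)
    na <- nelson_aalen(s)
    for (t in c(0.3, 1, 2, max(s$time))) {
      o <- naive_km_na(s, t)
      expect_equal(step_eval(km, t), unname(o["km"]), tolerance = 1e-12)
      expect_equal(step_eval(na, t), unname(o["na"]), tolerance = 1e-12)
    }
    # exp(-NA) dominates KM pointwise
    tt <- sort(unique(s$time))
    expect_true(all(exp(-step_eval(na, tt)) >= step_eval(km, tt) - 1e-12))
  }
})

test_that("Nelson-Aalen recovers the simulating cumulative hazard", {
  scen <- sim_scenario(n = 10000, family = "multiplicative",
                       baseline = list(times = 0, rates = 0.5),
                       covariates = list(), effects = list(),
                       censoring = list(admin = Inf, rate = 0), horizon = 20)
  s <- simulate_multiplicative(scen, seed = 42)
  expect_equal(step_eval(nelson_aalen(s), 1), 0.5, tolerance = 0.05)
  # and the gap to exp(-NA) closes at large n
  km <- kaplan_meier(s)
  na <- nelson_aalen(s)
  expect_lt(max(abs(exp(-step_eval(na, c(0.5, 1, 2))) -
                      step_eval(km, c(0.5, 1, 2)))), 1e-3)
})

test_that("jitter_ties breaks ties reproducibly and preserves order", {
  s <- survival_sample(data.frame(id = 1:3, time = c(1, 1, 2),
                                  event = c(1, 1, 0)))
  j1 <- jitter_ties(s, seed = 4)
  j2 <- jitter_ties(s, seed = 4)
  expect_false(anyDuplicated(j1$time) > 0)
  expect_identical(j1$time, j2$time)
  expect_true(all(j1$time[1:2] < j1$time[3]))
  expect_error(jitter_ties(s, seed = 1, scale = 10), "too large")

  # already-unique times keep their ordering
  u <- survival_sample(data.frame(id = 1:4, time = c(4, 1, 3, 2), event = 1))
  ju <- jitter_ties(u, seed = 9)
  expect_identical(order(ju$time), order(u$time))

  # the KM median moves by less than the jitter scale
  set.seed(11)
  big <- survival_sample(data.frame(
    id = 1:300, time = rep(round(rexp(100, 0.4) + 0.1, 1), 3),
    event = rbinom(300, 1, 0.8)
  ))
  jb <- jitter_ties(big, seed = 2, scale = 0.01)
  m0 <- attr(kaplan_meier(big), "median")["estimate"]
  m1 <- attr(kaplan_meier(jb), "median")["estimate"]
  expect_lt(abs(m1 - m0), 0.01)
})

test_that("split_episodes partitions follow-up and collapse inverts it", {
  s <- survival_sample(data.frame(id = 1L, time = 5, event = 1, z = 2))
  cp <- split_episodes(s, c(1, 3))
  expect_equal(cp$start, c(0, 1, 3))
  expect_equal(cp$stop, c(1, 3, 5))
  expect_equal(cp$status, c(0, 0, 1))
  expect_equal(cp$z, rep(2, 3))

  s2 <- random_small_sample(3, n = 6)
  expect_equal(as.data.frame(split_episodes(s2, numeric(0)))[, c("id", "stop", "status")],
               setNames(as.data.frame(s2)[, c("id", "time", "event")],
                        c("id", "stop", "status")))
  expect_equal(nrow(split_episodes(s2, max(s2$time) + 1)), nrow(s2))

  for (sd in 1:5) {
    s3 <- random_small_sample(sd + 20, n = 8)
    cuts <- sort(runif(3, 0, max(s3$time)))
    back <- collapse_episodes(split_episodes(s3, cuts))
    expect_equal(back$time, s3$time)
    expect_equal(back$event, s3$event)
    expect_equal(back$x, s3$x)
    expect_equal(sum(split_episodes(s3, cuts)$status), sum(s3$event))
  }
})

test_that("step functions evaluate right-continuously and serialize", {
  sf <- haz_step(c(1, 2), c(0.5, 0.2), origin = 1)
  expect_equal(step_eval(sf, c(0, 0.99, 1, 1.5, 2, 3)),
               c(1, 1, 0.5, 0.5, 0.2, 0.2))
  p <- withr::local_tempfile(fileext = ".csv")
  write_step_csv(sf, p)
  back <- utils::read.csv(p)
  expect_equal(back$value, c(1, 0.5, 0.2))
})
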