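# Seeded generators of right-censored survival data with multiplicative or
# additive covariate effects, constant or time-varying coefficient paths,
# and linear or non-linear functional forms.

#' Define a simulation scenario
#'
#' Describes a data-generating hazard. The baseline hazard is
#' piecewise-constant (`rate[i]` on `[time[i], time[i+1])`, last rate
#' extending to the horizon). Each covariate effect couples a
#' single-column functional form `f` with a coefficient path evaluated as a
#' piecewise-linear function of time, giving
#' `lambda_i(t) = lambda0(t) * exp(sum_c f_c(x_ic) beta_c(t))`
#' (multiplicative family) or
#' `lambda_i(t) = lambda0(t) + sum_c f_c(x_ic) alpha_c(t)` (additive
#' family). Event times are drawn by inverse-transform sampling of the
#' cumulative hazard on a fine time grid (piecewise-constant approximation
#' of the coefficient paths; exact for constant paths).
#'
#' @param n sample size.
#' @param family `"multiplicative"` or `"additive"`.
#' @param baseline list with `times` (left endpoints, starting at 0) and
#'   `rates` (same length).
#' @param covariates named list; each element one of
#'   `list(dist = "normal", mean=, sd=)`,
#'   `list(dist = "bernoulli", p=)`, `list(dist = "uniform", min=, max=)`.
#' @param effects named list (names must be covariate names); each element
#'   `list(coef = <constant> | list(times=, values=), form = <haz_form>)`
#'   (`form` defaults to identity and must evaluate to a single column).
#' @param censoring list with `admin` (administrative censoring time,
#'   default the horizon) and `rate` (independent exponential censoring
#'   rate, default 0).
#' @param horizon end of the simulated follow-up window (subjects still
#'   event-free there are censored administratively).
#' @param grid_step time-grid step for the hazard discretization; default
#'   `horizon / 1000`.
#' @return an object of class `sim_scenario`.
#' @export
sim_scenario <- function(n, family = c("multiplicative", "additive"),
                         baseline = list(times = 0, rates = 0.5),
                         covariates = list(),
                         effects = list(),
                         censoring = list(admin = Inf, rate = 0),
                         horizon = NULL, grid_step = NULL) {
  family <- match.arg(family)
  if (is.null(horizon)) {
    horizon <- if (is.finite(censoring$admin %||% Inf)) censoring$admin else 10
  }
  if (is.null(grid_step)) grid_step <- horizon / 1000
  stopifnot(length(baseline$times) == length(baseline$rates),
            baseline$times[1] == 0, all(baseline$rates >= 0))
  if (!all(names(effects) %in% names(covariates))) {
    stop("every effect must name a declared covariate")
  }
  structure(
    list(n = n, family = family, baseline = baseline,
         covariates = covariates, effects = effects,
         censoring = list(admin = censoring$admin %||% Inf,
                          rate = censoring$rate %||% 0),
         horizon = horizon, grid_step = grid_step),
    class = "sim_scenario"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Piecewise-linear coefficient path evaluated at times t.
eval_coef_path <- function(coef, t) {
  if (is.numeric(coef) && length(coef) == 1) return(rep(coef, length(t)))
  stopifnot(is.list(coef), length(coef$times) == length(coef$values))
  stats::approx(coef$times, coef$values, xout = t, rule = 2)$y
}

sample_covariates <- function(scenario) {
  out <- list()
  for (nm in names(scenario$covariates)) {
    sp <- scenario$covariates[[nm]]
    out[[nm]] <- switch(sp$dist,
      normal = stats::rnorm(scenario$n, sp$mean, sp$sd),
      bernoulli = stats::rbinom(scenario$n, 1, sp$p),
      uniform = stats::runif(scenario$n, sp$min, sp$max),
      stop("unknown covariate distribution: ", sp$dist)
    )
  }
  out
}

# n x G matrix of per-subject hazards at grid-cell midpoints.
subject_hazards <- function(scenario, covs, mids) {
  G <- length(mids)
  lam0 <- scenario$baseline$rates[findInterval(mids, scenario$baseline$times)]
  contrib <- matrix(0, scenario$n, G)
  for (nm in names(scenario$effects)) {
    ef <- scenario$effects[[nm]]
    form <- ef$form %||% form_identity()
    fx <- apply_form(form, covs[[nm]])
    if (ncol(fx) != 1) stop("generator effects need single-column forms")
    path <- eval_coef_path(ef$coef, mids)
    contrib <- contrib + outer(as.vector(fx), path)
  }
  if (scenario$family == "multiplicative") {
    sweep(exp(contrib), 2, lam0, "*")
  } else {
    sweep(contrib, 2, lam0, "+")
  }
}

simulate_core <- function(scenario, seed) {
  run_seeded(seed, function() {
    n <- scenario$n
    grid <- seq(0, scenario$horizon, by = scenario$grid_step)
    if (grid[length(grid)] < scenario$horizon) grid <- c(grid, scenario$horizon)
    mids <- (grid[-1] + grid[-length(grid)]) / 2
    dt <- diff(grid)
    covs <- sample_covariates(scenario)
    lam <- subject_hazards(scenario, covs, mids)
    if (scenario$family == "additive" && any(lam < -1e-12)) {
      stop("additive scenario gives a negative total hazard on the ",
           "covariate support; refusing to sample")
    }
    lam[lam < 0] <- 0
    cum <- t(apply(sweep(lam, 2, dt, "*"), 1, cumsum))
    if (n == 1) cum <- matrix(cum, nrow = 1)
    E <- stats::rexp(n)
    Tlat <- rep(scenario$horizon, n)
    hit <- E < cum[, ncol(cum)]
    for (i in which(hit)) {
      j <- which(cum[i, ] >= E[i])[1]
      c0 <- if (j == 1) 0 else cum[i, j - 1]
      Tlat[i] <- grid[j] + (E[i] - c0) / lam[i, j]
    }
    C <- pmin(
      scenario$censoring$admin,
      if (scenario$censoring$rate > 0) stats::rexp(n, scenario$censoring$rate) else Inf,
      scenario$horizon
    )
    time <- pmin(Tlat, C)
    event <- as.integer(hit & Tlat <= C)
    time <- pmax(time, .Machine$double.eps)
    df <- data.frame(id = seq_len(n), time = time, event = event)
    for (nm in names(covs)) df[[nm]] <- covs[[nm]]
    survival_sample(df)
  })
}

#' Simulate right-censored data from a multiplicative hazards model
#'
#' @param scenario a `sim_scenario` with `family = "multiplicative"`.
#' @param seed integer seed; same seed gives an identical sample.
#' @return a [survival_sample].
#' @export
simulate_multiplicative <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (scenario$family != "multiplicative") {
    stop("scenario family is not multiplicative")
  }
  simulate_core(scenario, seed)
}

#' Simulate right-censored data from an additive hazards model
#'
#' Refuses to sample when the realized total hazard is negative anywhere on
#' the time grid for a sampled subject.
#'
#' @param scenario a `sim_scenario` with `family = "additive"`.
#' @param seed integer seed.
#' @return a [survival_sample].
#' @export
simulate_additive <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (scenario$family != "additive") stop("scenario family is not additive")
  simulate_core(scenario, seed)
}

#' Synthetic cohort with the structure of a myocardial-infarction study
#'
#' A 1878-subject sample with one continuous covariate (`age`, normal with
#' mean 67 and sd 11.4) and four binary covariates with prevalences 52.29%
#' (`chf`, clinical heart failure), 69.54% (`sex`), 10.01% (`dia`,
#' diabetes), and 7.24% (`vf`, ventricular fibrillation). Effects on the
#' hazard of death qualitatively mimic the well-known clinical pattern: an
#' exponential effect of age, a linearly decaying effect of chf, a strong
#' but transient early effect of vf (gone after ~0.15 years), and constant
#' effects of sex and dia. Intended for end-to-end strategy exercises; this
#' is a synthetic stand-in, not the real cohort.
#'
#' @param seed integer seed.
#' @return a [survival_sample] with n = 1878.
#' @export
trace_like_fixture <- function(seed = 20210506) {
  # the age effect is exp(age/10) scaled so that beta * exp(67/10) = 0.28,
  # i.e. a hazard multiplier exp(0.28 * exp((age - 67)/10))
  scen <- sim_scenario(
    n = 1878, family = "multiplicative",
    baseline = list(times = c(0, 0.5), rates = c(0.12, 0.030)),
    covariates = list(
      age = list(dist = "normal", mean = 67, sd = 11.4),
      chf = list(dist = "bernoulli", p = 0.5229),
      sex = list(dist = "bernoulli", p = 0.6954),
      dia = list(dist = "bernoulli", p = 0.1001),
      vf = list(dist = "bernoulli", p = 0.0724)
    ),
    effects = list(
      age = list(coef = 0.28 * exp(-6.7), form = form_exp(10)),
      chf = list(coef = list(times = c(0, 8), values = c(0.95, 0.3))),
      sex = list(coef = 0.18),
      dia = list(coef = 0.35),
      vf = list(coef = list(times = c(0, 0.15, 8), values = c(2.3, 0, 0)))
    ),
    censoring = list(admin = 8, rate = 0.02),
    horizon = 8
  )
  simulate_core(scen, seed)
}
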