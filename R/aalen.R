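# Additive-hazards core: Aalen's nonparametric least-squares estimator,
# the Lin-Ying constant-coefficient estimator, the constant-effect check,
# and stratified martingale-residual-process goodness-of-fit machinery.

# Design matrix (without intercept) from a list of haz_term objects; tv
# bases do not apply to the additive fits (regression functions already
# carry the time variation).
build_additive_design <- function(sample, terms = NULL) {
  if (is.null(terms)) {
    terms <- lapply(covariate_names(sample), haz_term)
  }
  if (inherits(terms, "haz_term")) terms <- list(terms)
  cols <- list()
  for (tm in terms) {
    fx <- apply_form(tm$form, sample[[tm$covariate]])
    if (any(!is.finite(fx))) {
      stop("functional form '", tm$form$label, "' is non-finite on the ",
           "observed range of '", tm$covariate, "'")
    }
    colnames(fx) <- paste0(tm$covariate, "_", colnames(fx))
    cols[[length(cols) + 1L]] <- fx
  }
  if (!length(cols)) {
    return(matrix(numeric(0), nrow = nrow(sample), ncol = 0))
  }
  do.call(cbind, cols)
}

#' Aalen's additive hazards model
#'
#' Nonparametric least-squares estimator of the cumulative regression
#' functions `B_k(t) = int_0^t alpha_k(s) ds` of the additive model
#' `lambda_i(t) = lambda_0(t) + x_i' alpha(t)`. At each ordered event time
#' the increment is `(X'X)^{-1} X' dN` over the at-risk design rows, with
#' variance increments `(X'X)^{-1} X' diag(dN) X (X'X)^{-1}`. Estimation
#' stops at the first event time where the at-risk design drops rank
#' (reciprocal condition number below `rcond_tol`); with an intercept-only
#' design the estimator is exactly Nelson-Aalen. Negative cumulative effects
#' are legal output.
#'
#' @param sample a [survival_sample] (jitter tied times first if present).
#' @param terms list of [haz_term] objects selecting covariates and
#'   functional forms; default: every covariate, identity form. An empty
#'   list gives the intercept-only model.
#' @param rcond_tol reciprocal-condition-number threshold for truncation.
#' @return an object of class `aalen_fit`: `times` (event times with
#'   estimates), `increments` and `B` (per-time jump and cumulative, one
#'   column per design column including `(Intercept)`), `var` (pointwise
#'   variance of `B`), `last_time` (last estimable time), `truncated`
#'   (logical), `design`, `X`, `sample`.
#' @export
fit_aalen <- function(sample, terms = NULL, rcond_tol = 1e-10) {
  X <- cbind("(Intercept)" = 1, build_additive_design(sample, terms))
  k <- ncol(X)
  n <- nrow(sample)
  ord <- order(sample$time)
  tms <- sample$time[ord]
  evs <- sample$event[ord]
  Xo <- X[ord, , drop = FALSE]
  et <- unique(tms[evs == 1])
  J <- length(et)
  if (J == 0) stop("at least one event is required")
  XtX <- crossprod(Xo)
  inc <- matrix(0, J, k, dimnames = list(NULL, colnames(X)))
  vinc <- matrix(0, J, k, dimnames = list(NULL, colnames(X)))
  ptr <- 1L # next subject (by time) still in the risk set
  truncated <- FALSE
  jdone <- 0L
  for (j in seq_len(J)) {
    while (ptr <= n && tms[ptr] < et[j]) {
      XtX <- XtX - tcrossprod(Xo[ptr, ])
      ptr <- ptr + 1L
    }
    if (rcond(XtX) < rcond_tol) {
      truncated <- TRUE
      break
    }
    ev_here <- which(tms == et[j] & evs == 1)
    for (i in ev_here) {
      b <- solve(XtX, Xo[i, ])
      inc[j, ] <- inc[j, ] + b
      vinc[j, ] <- vinc[j, ] + b^2
    }
    jdone <- j
  }
  if (jdone == 0L) stop("no estimate: design rank-deficient at the first event time")
  times <- et[seq_len(jdone)]
  inc <- inc[seq_len(jdone), , drop = FALSE]
  vinc <- vinc[seq_len(jdone), , drop = FALSE]
  cum_cols <- function(m) {
    out <- apply(m, 2, cumsum)
    matrix(out, nrow = nrow(m), dimnames = dimnames(m))
  }
  structure(
    list(
      times = times,
      increments = inc,
      B = cum_cols(inc),
      var = cum_cols(vinc),
      last_time = times[jdone],
      truncated = truncated,
      design = colnames(X), X = X, sample = sample, terms = terms
    ),
    class = "aalen_fit"
  )
}

#' @export
print.aalen_fit <- function(x, ...) {
  cat("<aalen_fit> ", length(x$design), " cumulative regression function(s), ",
      length(x$times), " event times",
      if (x$truncated) paste0(" (truncated at t=", format(x$last_time), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Cumulative regression function of an Aalen fit as a step function
#'
#' @param fit an `aalen_fit`.
#' @param column design column name (e.g. `"(Intercept)"`).
#' @return a [haz_step].
#' @export
aalen_cumulative <- function(fit, column) {
  j <- match(column, fit$design)
  if (is.na(j)) stop("no design column '", column, "'")
  haz_step(fit$times, fit$B[, j], origin = 0)
}

#' Lin-Ying constant-coefficient additive hazards model
#'
#' The additive model `lambda_i(t) = lambda_0(t) + x_i' gamma` with
#' time-constant coefficients, estimated by the closed-form Lin-Ying
#' estimating equation: `gamma_hat = A^{-1} b` with
#' `A = sum_i int Y_i(t) (x_i - xbar(t))^{x2} dt` and
#' `b = sum_i int (x_i - xbar(t)) dN_i(t)`, where `xbar(t)` is the at-risk
#' mean. Covariance is the sandwich `A^{-1} M A^{-1}` with
#' `M = sum_events (x - xbar)^{x2}`. The baseline cumulative hazard is the
#' Nelson-Aalen increment sum minus the integrated at-risk-mean drift
#' `int_0^t xbar(s)' gamma_hat ds`, recorded at event times.
#'
#' @param sample a [survival_sample].
#' @param terms list of [haz_term] objects; default all covariates, identity.
#' @return an object of class `lin_fit`: `coefficients`, `vcov`,
#'   `baseline` (a [haz_step]), `design`, `X`, `sample`.
#' @export
fit_lin <- function(sample, terms = NULL) {
  X <- build_additive_design(sample, terms)
  if (ncol(X) == 0) stop("Lin's model needs at least one covariate")
  k <- ncol(X)
  n <- nrow(sample)
  ord <- order(sample$time)
  tms <- sample$time[ord]
  evs <- sample$event[ord]
  Xo <- X[ord, , drop = FALSE]
  ut <- unique(tms)
  A <- matrix(0, k, k)
  bvec <- numeric(k)
  Mmid <- matrix(0, k, k)
  # suffix sums over subjects ordered by time give the at-risk aggregates
  S0 <- rev(cumsum(rev(rep(1, n))))
  S1 <- apply(Xo[n:1, , drop = FALSE], 2, cumsum)[n:1, , drop = FALSE]
  first_idx <- match(ut, tms) # first subject with time == ut[m]
  prev <- 0
  base_t <- numeric(0)
  base_v <- numeric(0)
  cumbase <- 0
  for (m in seq_along(ut)) {
    i0 <- first_idx[m]
    s0 <- S0[i0]
    s1 <- S1[i0, ]
    xbar <- s1 / s0
    risk_rows <- i0:n
    S2 <- crossprod(Xo[risk_rows, , drop = FALSE])
    dt <- ut[m] - prev
    A <- A + dt * (S2 - tcrossprod(s1) / s0)
    ev_here <- which(tms == ut[m] & evs == 1)
    for (i in ev_here) {
      dx <- Xo[i, ] - xbar
      bvec <- bvec + dx
      Mmid <- Mmid + tcrossprod(dx)
    }
    prev <- ut[m]
  }
  Ainv <- tryCatch(solve(A), error = function(e) {
    stop("degenerate design: singular Lin-Ying estimating matrix")
  })
  gamma <- as.vector(Ainv %*% bvec)
  names(gamma) <- colnames(X)
  vc <- Ainv %*% Mmid %*% Ainv
  dimnames(vc) <- list(colnames(X), colnames(X))
  # baseline at event times: Nelson-Aalen increments minus integrated drift
  prev <- 0
  cum <- 0
  for (m in seq_along(ut)) {
    i0 <- first_idx[m]
    xbar <- S1[i0, ] / S0[i0]
    cum <- cum - (ut[m] - prev) * sum(xbar * gamma)
    d <- sum(tms == ut[m] & evs == 1)
    if (d > 0) {
      cum <- cum + d / S0[i0]
      base_t <- c(base_t, ut[m])
      base_v <- c(base_v, cum)
    }
    prev <- ut[m]
  }
  structure(
    list(
      coefficients = gamma, vcov = vc,
      baseline = haz_step(base_t, base_v, origin = 0),
      design = colnames(X), X = X, sample = sample, terms = terms
    ),
    class = "lin_fit"
  )
}

#' @export
print.lin_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  tab <- data.frame(
    gamma = x$coefficients, se = se,
    p = 2 * stats::pnorm(-abs(x$coefficients / se))
  )
  cat("<lin_fit> constant additive effects\n")
  print(tab, digits = 4)
  invisible(x)
}

#' Check whether a covariate's additive effect is constant over time
#'
#' Overlays the Lin straight line `gamma_k * t` on the pointwise 95%
#' confidence band of the Aalen cumulative regression function `B_k(t)` and
#' reports the fraction of the event-time grid (up to the last estimable
#' time) where the line lies inside the band. Verdict `"constant"` when the
#' fraction reaches `threshold` (an operationalization of the visual rule of
#' judging whether the cumulative curve has constant slope).
#'
#' @param aalen an `aalen_fit` (a `lin_fit` is accepted for the degenerate
#'   self-comparison, giving a band of width zero).
#' @param lin a `lin_fit` on the same design.
#' @param covariate design column name present in both fits.
#' @param threshold coverage fraction required, default 0.95.
#' @param conf_level band level, default 0.95.
#' @return list with `coverage`, `constant` (logical), `table` (time, line,
#'   band), `threshold`.
#' @export
constant_effect_check <- function(aalen, lin, covariate, threshold = 0.95,
                                  conf_level = 0.95) {
  kL <- match(covariate, lin$design)
  if (is.na(kL)) stop("no design column '", covariate, "' in the Lin fit")
  gam <- lin$coefficients[kL]
  if (inherits(aalen, "lin_fit")) {
    tms <- aalen$baseline$times
    j <- match(covariate, aalen$design)
    B <- aalen$coefficients[j] * tms
    V <- rep(0, length(tms))
  } else {
    j <- match(covariate, aalen$design)
    if (is.na(j)) stop("no design column '", covariate, "' in the Aalen fit")
    tms <- aalen$times
    B <- aalen$B[, j]
    V <- aalen$var[, j]
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lower <- B - z * sqrt(V)
  upper <- B + z * sqrt(V)
  line <- gam * tms
  tol <- 1e-12 * (1 + abs(B))
  inside <- line >= lower - tol & line <= upper + tol
  coverage <- mean(inside)
  list(
    coverage = coverage, constant = coverage >= threshold,
    threshold = threshold,
    table = data.frame(time = tms, line = line, B = B,
                       lower = lower, upper = upper, inside = inside)
  )
}

# Observed and expected per-stratum event-count increments at each
# estimable event time of an Aalen fit. Expected increment for stratum g at
# t_j is s_g(t_j)' dB(t_j) with s_g the sum of at-risk design rows in g.
aalen_stratum_increments <- function(fit, strata) {
  sample <- fit$sample
  stopifnot(length(strata) == nrow(sample))
  strata <- as.factor(strata)
  G <- nlevels(strata)
  ord <- order(sample$time)
  tms <- sample$time[ord]
  evs <- sample$event[ord]
  Xo <- fit$X[ord, , drop = FALSE]
  go <- as.integer(strata)[ord]
  k <- ncol(Xo)
  J <- length(fit$times)
  Sg <- matrix(0, G, k)
  rs <- rowsum(Xo, group = go)
  Sg[as.integer(rownames(rs)), ] <- rs
  dObs <- matrix(0, J, G, dimnames = list(NULL, levels(strata)))
  dExp <- matrix(0, J, G, dimnames = list(NULL, levels(strata)))
  ptr <- 1L
  n <- length(tms)
  for (j in seq_len(J)) {
    while (ptr <= n && tms[ptr] < fit$times[j]) {
      Sg[go[ptr], ] <- Sg[go[ptr], ] - Xo[ptr, ]
      ptr <- ptr + 1L
    }
    ev_here <- which(tms == fit$times[j] & evs == 1)
    for (i in ev_here) dObs[j, go[i]] <- dObs[j, go[i]] + 1
    dExp[j, ] <- as.vector(Sg %*% fit$increments[j, ])
  }
  list(times = fit$times, dObs = dObs, dExp = dExp, strata = strata)
}

#' Stratified martingale residual processes of an Aalen fit
#'
#' For each stratum `g`, the cumulative observed-minus-expected event count
#' `M_g(t) = sum_{i in g} [N_i(t) - int_0^t Y_i(s) x_i' dB(s)]`, with
#' pointwise confidence bounds obtained by wild-bootstrap resampling of the
#' per-event-time increments with standard normal multipliers (multipliers
#' shared across strata, preserving the sum-to-zero constraint). When the
#' strata are the levels of a categorical covariate whose dummies are in the
#' design, every process is identically zero.
#'
#' @param fit an `aalen_fit`.
#' @param strata group labels, one per subject (same row order as the
#'   sample the model was fitted on).
#' @param resamples number of wild-bootstrap replicates (>= 100).
#' @param seed integer seed for the multipliers.
#' @param conf_level pointwise bound level.
#' @return an object of class `mrp_set`: `times`, `M` (J x G), `lower`,
#'   `upper`, `M_tau`, `boot_tau` (resamples x G), `events` (per-stratum
#'   event counts, zero-event strata are flagged low-information).
#' @export
martingale_residual_process <- function(fit, strata, resamples = 500,
                                        seed = 1, conf_level = 0.95) {
  if (resamples < 100) stop("at least 100 resamples are required")
  incs <- aalen_stratum_increments(fit, strata)
  dM <- incs$dObs - incs$dExp
  J <- nrow(dM); G <- ncol(dM)
  M <- apply(dM, 2, cumsum)
  M <- matrix(M, nrow = J, dimnames = dimnames(dM))
  eps <- run_seeded(seed, function() {
    matrix(stats::rnorm(resamples * J), nrow = resamples)
  })
  alpha2 <- (1 - conf_level) / 2
  lower <- matrix(0, J, G, dimnames = dimnames(dM))
  upper <- lower
  boot_tau <- matrix(0, resamples, G, dimnames = list(NULL, colnames(dM)))
  for (g in seq_len(G)) {
    scaled <- sweep(eps, 2, dM[, g], "*")
    paths <- t(apply(scaled, 1, cumsum)) # resamples x J cumulative paths
    if (J == 1) paths <- t(paths)
    lower[, g] <- apply(paths, 2, stats::quantile, probs = alpha2)
    upper[, g] <- apply(paths, 2, stats::quantile, probs = 1 - alpha2)
    boot_tau[, g] <- paths[, J]
  }
  ev_counts <- colSums(incs$dObs)
  if (any(ev_counts == 0)) {
    message("low-information stratum with zero events: ",
            paste(colnames(dM)[ev_counts == 0], collapse = ", "))
  }
  structure(
    list(times = incs$times, M = M, lower = lower, upper = upper,
         M_tau = M[J, ], boot_tau = boot_tau, events = ev_counts,
         resamples = resamples, seed = seed, strata = incs$strata),
    class = "mrp_set"
  )
}

#' @export
print.mrp_set <- function(x, ...) {
  cat("<mrp_set> ", ncol(x$M), " strata, ", nrow(x$M), " event times, ",
      x$resamples, " resamples\n", sep = "")
  print(data.frame(stratum = colnames(x$M), events = x$events,
                   M_tau = x$M_tau), digits = 4)
  invisible(x)
}

#' @export
plot.mrp_set <- function(x, ...) {
  G <- ncol(x$M)
  oldpar <- graphics::par(mfrow = grDevices::n2mfrow(G))
  on.exit(graphics::par(oldpar))
  for (g in seq_len(G)) {
    rng <- range(x$lower[, g], x$upper[, g], x$M[, g], 0)
    graphics::plot(x$times, x$M[, g], type = "s", ylim = rng,
                   xlab = "time", ylab = "observed - expected",
                   main = colnames(x$M)[g], ...)
    graphics::lines(x$times, x$lower[, g], lty = 2, type = "s")
    graphics::lines(x$times, x$upper[, g], lty = 2, type = "s")
    graphics::abline(h = 0, col = "grey")
  }
  invisible(x)
}

#' Chi-square tests on martingale residual processes at end of follow-up
#'
#' Per stratum, `M_g(tau)^2 / Var[M_g(tau)]` referred to chi-square(1), with
#' the variance estimated from the wild-bootstrap replicates; globally, the
#' quadratic form `M' Sigma^- M` over strata with the bootstrap covariance
#' and its Moore-Penrose generalized inverse (the processes sum to zero over
#' strata, so Sigma is singular with df = rank). A stratum with zero
#' resampling variance is reported with `p = 1` and a warning. The fitted
#' functional form is rejected when any p-value falls below `alpha`.
#'
#' @param processes an `mrp_set`.
#' @param alpha rejection threshold, default 0.05.
#' @return list with `table` (stratum, statistic, df, p; last row `global`)
#'   and `reject` (logical).
#' @export
mrp_chisq_test <- function(processes, alpha = 0.05) {
  M_tau <- processes$M_tau
  boot <- processes$boot_tau
  G <- length(M_tau)
  rows <- vector("list", G + 1L)
  for (g in seq_len(G)) {
    v <- stats::var(boot[, g])
    if (v <= .Machine$double.eps * 100) {
      if (abs(M_tau[g]) > 1e-8) {
        warning("zero resampling variance in stratum ", names(M_tau)[g],
                "; p reported as 1")
      }
      rows[[g]] <- data.frame(stratum = names(M_tau)[g],
                              statistic = 0, df = 1, p = 1)
    } else {
      st <- M_tau[g]^2 / v
      rows[[g]] <- data.frame(stratum = names(M_tau)[g], statistic = st,
                              df = 1, p = stats::pchisq(st, 1, lower.tail = FALSE))
    }
  }
  Sig <- stats::cov(boot)
  ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
  rank <- if (max(ev, 0) < 1e-14) 0L else sum(ev > max(ev) * 1e-8)
  if (rank == 0) {
    if (max(abs(M_tau)) > 1e-8) warning("zero global resampling covariance; p reported as 1")
    rows[[G + 1L]] <- data.frame(stratum = "global", statistic = 0, df = 0, p = 1)
  } else {
    st <- as.vector(t(M_tau) %*% MASS::ginv(Sig) %*% M_tau)
    rows[[G + 1L]] <- data.frame(
      stratum = "global", statistic = st, df = rank,
      p = stats::pchisq(st, rank, lower.tail = FALSE)
    )
  }
  tab <- do.call(rbind, rows)
  list(table = tab, reject = any(tab$p < alpha))
}
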