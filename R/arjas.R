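# Arjas-style observed-versus-expected goodness-of-fit curves.

#' Quantile-based strata for a continuous covariate
#'
#' Splits subjects into `k` groups at the empirical quantile cutpoints
#' (linear-interpolation convention); values equal to a cutpoint go to the
#' lower stratum.
#'
#' @param covariate numeric values.
#' @param k number of strata (>= 2), default 4 (quartiles).
#' @return a factor of group labels with attribute `cutpoints`.
#' @export
strata_by_quantiles <- function(covariate, k = 4) {
  if (k < 2) stop("need at least 2 strata")
  if (length(unique(covariate)) < k) {
    stop("fewer distinct covariate values than strata")
  }
  cuts <- unname(stats::quantile(covariate, probs = seq_len(k - 1) / k, type = 7))
  if (anyDuplicated(cuts)) stop("tied quantile cutpoints: too few distinct values")
  idx <- findInterval(covariate, cuts, left.open = TRUE) + 1L
  labs <- c(
    sprintf("<=%.3g", cuts[1]),
    if (k > 2) sprintf("(%.3g,%.3g]", cuts[-(k - 1)], cuts[-1]),
    sprintf(">%.3g", cuts[k - 1])
  )
  labs <- make.unique(labs)
  out <- factor(labs[idx], levels = labs)
  attr(out, "cutpoints") <- cuts
  out
}

# Per-stratum observed and expected event-count increments at each event
# time of a Cox fit; expected increment at t_j for stratum g is
# dLambda0(t_j) * sum_{rows in g at risk} exp(lp). Also returns the
# ingredients of the estimation-effect correction used by the wild
# bootstrap: the cumulative derivative C_g(t) = dExp_g / dbeta, the score
# increments (summed Schoenfeld residuals per event time), and the
# coefficient covariance, so that resampled processes
# sum_j eps_j dD_g(j) - C_g(t)' V sum_j eps_j r_j reflect the variability
# of beta-hat as well as of the increments.
cox_stratum_increments <- function(fit, strata) {
  cp <- fit$data
  sample_ids <- unique(cp$id)
  stopifnot(length(strata) == length(sample_ids))
  strata <- as.factor(strata)
  G <- nlevels(strata)
  row_g <- as.integer(strata)[match(cp$id, sample_ids)]
  w <- exp(fit$lp)
  rs_all <- risk_sums(cp, w)
  et <- rs_all$times
  J <- length(et)
  dL <- rs_all$d / rs_all$S
  k <- fit$k
  X <- if (k > 0) as.matrix(cp[fit$design]) else NULL
  Sx <- if (k > 0) {
    matrix(vapply(seq_len(k), function(l) risk_sums_at(cp, w * X[, l], et),
                  numeric(J)), nrow = J)
  } else NULL
  dObs <- matrix(0, J, G, dimnames = list(NULL, levels(strata)))
  dExp <- matrix(0, J, G, dimnames = list(NULL, levels(strata)))
  Carr <- if (k > 0) array(0, dim = c(J, G, k)) else NULL
  for (g in seq_len(G)) {
    sel <- row_g == g
    cpg <- cp[sel, , drop = FALSE]
    Sg <- risk_sums_at(cpg, w[sel], et)
    dExp[, g] <- dL * Sg
    evt_g <- cpg$stop[cpg$status == 1]
    if (length(evt_g)) {
      tb <- table(factor(evt_g, levels = et))
      dObs[, g] <- as.vector(tb)
    }
    if (k > 0) {
      for (l in seq_len(k)) {
        Sgx <- risk_sums_at(cpg, w[sel] * X[sel, l], et)
        dC <- rs_all$d * (Sgx / rs_all$S - Sg * Sx[, l] / rs_all$S^2)
        Carr[, g, l] <- cumsum(dC)
      }
    }
  }
  score <- NULL
  if (k > 0) {
    score <- matrix(0, J, k)
    ev <- cp$status == 1
    xev <- rowsum(X[ev, , drop = FALSE], group = match(cp$stop[ev], et))
    score[as.integer(rownames(xev)), ] <- xev
    score <- score - (rs_all$d / rs_all$S) * matrix(Sx, nrow = J)
  }
  list(times = et, dObs = dObs, dExp = dExp, strata = strata,
       C = Carr, score = score, V = if (k > 0) fit$vcov else NULL)
}

# Risk-set sums of w at externally supplied event times.
risk_sums_at <- function(cp, w, et) {
  J <- length(et)
  a <- findInterval(cp$start, et)
  b <- findInterval(cp$stop, et)
  acc <- numeric(J + 1L)
  inc <- rowsum(w, group = a + 1L)
  acc[as.integer(rownames(inc))] <- inc[, 1]
  dec <- rowsum(w, group = pmin(b + 1L, J + 1L))
  acc[as.integer(rownames(dec))] <- acc[as.integer(rownames(dec))] - dec[, 1]
  cumsum(acc)[seq_len(J)]
}

new_arjas <- function(times, dObs, dExp, strata, resamples, seed,
                      correction = NULL) {
  Obs <- apply(dObs, 2, cumsum)
  Exp <- apply(dExp, 2, cumsum)
  J <- nrow(dObs)
  Obs <- matrix(Obs, nrow = J, dimnames = dimnames(dObs))
  Exp <- matrix(Exp, nrow = J, dimnames = dimnames(dExp))
  # advisory deviation statistic: mean vertical gap observed - expected,
  # calibrated per stratum by wild-bootstrap multipliers on the increments
  # (plus, for Cox fits, the resampled score term carrying the effect of
  # coefficient estimation on the expected counts)
  dD <- dObs - dExp
  area <- colMeans(Obs - Exp)
  eps <- run_seeded(seed, function() {
    matrix(stats::rnorm(resamples * J), nrow = resamples)
  })
  score_term <- NULL
  if (!is.null(correction) && !is.null(correction$score)) {
    # resamples x k matrix of resampled scores times the covariance
    score_term <- (eps %*% correction$score) %*% correction$V
  }
  boot_area <- matrix(0, resamples, ncol(dD))
  for (g in seq_len(ncol(dD))) {
    scaled <- sweep(eps, 2, dD[, g], "*")
    paths <- t(apply(scaled, 1, cumsum))
    if (J == 1) paths <- t(paths)
    if (!is.null(score_term)) {
      Cg <- matrix(correction$C[, g, ], nrow = J) # J x k cumulative dExp/dbeta
      paths <- paths - score_term %*% t(Cg)
    }
    boot_area[, g] <- rowMeans(paths)
  }
  # family-wise threshold: 95th percentile of the max over strata, so the
  # verdict has ~5% false-flag rate regardless of the number of strata
  thresh <- stats::quantile(apply(abs(boot_area), 1, max), 0.95)
  structure(
    list(times = times, observed = Obs, expected = Exp,
         strata = strata, area = area,
         area_threshold = rep(unname(thresh), ncol(dD)),
         lack_of_fit = any(abs(area) > thresh + 1e-12)),
    class = "arjas_curves"
  )
}

#' Arjas curves for a Cox model
#'
#' Per stratum, the points (expected cumulative events, observed cumulative
#' events) indexed by event time, where the expected count accumulates
#' `exp(x_i' beta(s)) dLambda0(s)` over at-risk subjects of the stratum.
#' Summed over all strata the expected count at the end of follow-up equals
#' the observed total exactly (Breslow baseline identity). A curve along the
#' diagonal indicates goodness-of-fit; the advisory verdict flags a stratum
#' whose mean signed deviation from the diagonal exceeds a
#' wild-bootstrap-calibrated 95% threshold.
#'
#' @param fit a `cox_fit` (plain or extended).
#' @param strata group labels, one per subject (order of the original
#'   sample / unique ids of the counting-process data).
#' @param resamples wild-bootstrap replicates for the calibration.
#' @param seed seed for the multipliers.
#' @return an object of class `arjas_curves`.
#' @export
arjas_curves_cox <- function(fit, strata, resamples = 200, seed = 1) {
  stopifnot(inherits(fit, "cox_fit"))
  incs <- cox_stratum_increments(fit, strata)
  new_arjas(incs$times, incs$dObs, incs$dExp, incs$strata, resamples, seed,
            correction = list(C = incs$C, score = incs$score, V = incs$V))
}

#' Arjas curves for an Aalen additive model
#'
#' As [arjas_curves_cox], with the expected count accumulating
#' `dB0 + x_i' dB` over at-risk subjects. When the strata are the levels of
#' a categorical covariate whose dummies are in the design, observed and
#' expected counts coincide at every event time and the curves lie exactly
#' on the diagonal.
#'
#' @param fit an `aalen_fit`.
#' @param strata group labels, one per subject (sample row order).
#' @param resamples wild-bootstrap replicates for the calibration.
#' @param seed seed for the multipliers.
#' @return an object of class `arjas_curves`.
#' @export
arjas_curves_aalen <- function(fit, strata, resamples = 200, seed = 1) {
  stopifnot(inherits(fit, "aalen_fit"))
  incs <- aalen_stratum_increments(fit, strata)
  new_arjas(incs$times, incs$dObs, incs$dExp, incs$strata, resamples, seed)
}

#' @export
print.arjas_curves <- function(x, ...) {
  cat("<arjas_curves> ", ncol(x$observed), " strata, ",
      nrow(x$observed), " event times; verdict: ",
      if (x$lack_of_fit) "lack of fit (advisory)" else "fit (advisory)",
      "\n", sep = "")
  print(data.frame(
    stratum = colnames(x$observed),
    observed_tau = x$observed[nrow(x$observed), ],
    expected_tau = x$expected[nrow(x$expected), ],
    mean_deviation = x$area, threshold = x$area_threshold
  ), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
plot.arjas_curves <- function(x, ...) {
  G <- ncol(x$observed)
  oldpar <- graphics::par(mfrow = grDevices::n2mfrow(G))
  on.exit(graphics::par(oldpar))
  for (g in seq_len(G)) {
    rng <- c(0, max(x$observed[, g], x$expected[, g]))
    graphics::plot(x$expected[, g], x$observed[, g], type = "s",
                   xlim = rng, ylim = rng, xlab = "expected events",
                   ylab = "observed events", main = colnames(x$observed)[g],
                   ...)
    graphics::abline(0, 1, col = "grey")
  }
  invisible(x)
}
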