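# Jackknife pseudo-observations of survival and their transformed,
# smoothed diagnostic curves.

#' Jackknife pseudo-observations of the survival function
#'
#' For subject `i` and grid time `t`, the pseudo-observation is
#' `S_i(t) = n * S(t) - (n - 1) * S^{-i}(t)`, with `S` the Kaplan-Meier
#' estimate on the whole sample and `S^{-i}` the estimate after leaving out
#' subject `i`. The leave-one-out curves are recomputed incrementally by
#' adjusting each event time's death count and risk-set size, which equals
#' the naive n-refit computation exactly. Column means reproduce the
#' full-sample Kaplan-Meier exactly, and with no censoring before `t` the
#' pseudo-values are exactly the survival indicators `I(time_i > t)`;
#' values outside [0, 1] are legal.
#'
#' @param sample a [survival_sample] with `n >= 2`.
#' @param timegrid evaluation times within the follow-up range; default
#'   [event_time_deciles].
#' @return an `n x length(timegrid)` matrix of class `pseudo_matrix` with
#'   attributes `times`, `id`, and `km` (the full-sample Kaplan-Meier values
#'   at the grid).
#' @export
pseudo_observations <- function(sample, timegrid = NULL) {
  n <- nrow(sample)
  if (n < 2) stop("pseudo-observations need at least 2 subjects")
  if (is.null(timegrid)) timegrid <- event_time_deciles(sample)
  et <- sort(unique(sample$time[sample$event == 1]))
  J <- length(et)
  d <- vapply(et, function(t) sum(sample$time == t & sample$event == 1), numeric(1))
  y <- vapply(et, function(t) sum(sample$time >= t), numeric(1))
  fac <- 1 - d / y
  grid_idx <- findInterval(timegrid, et) # factors 1..grid_idx enter S(t)
  km <- c(1, cumprod(fac))[grid_idx + 1L]
  out <- matrix(0, n, length(timegrid))
  for (i in seq_len(n)) {
    ti <- sample$time[i]
    di <- sample$event[i]
    atrisk <- et <= ti
    yi <- y - atrisk
    di_j <- d - (et == ti & di == 1)
    fi <- ifelse(yi > 0, 1 - di_j / yi, 1)
    fi[!atrisk] <- fac[!atrisk]
    smi <- c(1, cumprod(fi))[grid_idx + 1L]
    out[i, ] <- n * km - (n - 1) * smi
  }
  structure(out, times = timegrid, id = sample$id, km = km,
            class = "pseudo_matrix")
}

#' Deciles of the event-time distribution
#'
#' The 10%, ..., 90% empirical quantiles (linear-interpolation convention,
#' `h = (n - 1) p + 1` indexing) of the uncensored event times; the default
#' evaluation grid for pseudo-observation curves.
#'
#' @param sample a [survival_sample] with at least 10 events.
#' @return strictly increasing numeric vector (duplicate quantiles are
#'   collapsed with a warning).
#' @export
event_time_deciles <- function(sample) {
  evt <- sample$time[sample$event == 1]
  if (length(evt) < 10) stop("event-time deciles need at least 10 events")
  q <- unname(stats::quantile(evt, probs = seq(0.1, 0.9, by = 0.1), type = 7))
  uq <- unique(q)
  if (length(uq) < 2) stop("degenerate event-time grid: all deciles identical")
  if (length(uq) < length(q)) {
    warning("collapsed ", length(q) - length(uq), " duplicated decile(s)")
  }
  uq
}

#' Transformed smoothed pseudo-observation curves against a covariate
#'
#' For each grid time, the pseudo-values are first lowess-smoothed against
#' the continuous covariate, the smoothed values are clamped to
#' `[eps, 1 - eps]`, and the transform is applied: `cloglog` gives
#' `log(-log s)` (linear in the covariate with common slope beta under a
#' proportional-hazards log-linear effect), `scaled_log` gives `-log(s)/t`
#' (linear with common slope gamma under a constant additive effect).
#' The smoother is non-robust lowess (span 2/3, no robustness iterations:
#' the extreme pseudo-values carry the event information and must not be
#' downweighted as outliers). Scores are computed on the central covariate
#' region (between its 10% and 90% quantiles), where the smooth is
#' supported by data: each curve's linearity score is the maximum deviation
#' of the transformed smooth from its secant, scaled by the curve's range,
#' and `linearity_summary` averages the per-curve scores weighted by curve
#' range (near-flat curves carry little evidence). The cross-curve
#' parallelism score is `mad(slopes) / (1 + |median(slopes)|)`, with slopes
#' from per-curve least squares on the central region. All scores are
#' advisory operationalizations of a visual judgement, with suggested
#' threshold 0.1.
#'
#' @param pseudo a `pseudo_matrix`.
#' @param covariate numeric covariate values, one per subject (same order).
#' @param transform `"cloglog"` or `"scaled_log"`.
#' @param eps clamp bound, default `1e-6`.
#' @return an object of class `pseudo_curves`: `curves` (one data frame
#'   `x`, `y` per grid time, full covariate range), `times`, `slopes`,
#'   `linearity` (per curve), `linearity_summary`, `parallelism`, `clamped`
#'   (count of clamped smooth values).
#' @export
covariate_effect_curves <- function(pseudo, covariate,
                                    transform = c("cloglog", "scaled_log"),
                                    eps = 1e-6) {
  transform <- match.arg(transform)
  times <- attr(pseudo, "times")
  stopifnot(length(covariate) == nrow(pseudo))
  qs <- stats::quantile(covariate, c(0.1, 0.9))
  curves <- vector("list", length(times))
  slopes <- numeric(length(times))
  linearity <- numeric(length(times))
  ranges <- numeric(length(times))
  clamped <- 0L
  for (j in seq_along(times)) {
    sm <- stats::lowess(covariate, pseudo[, j], f = 2 / 3, iter = 0)
    s <- sm$y
    clamped <- clamped + sum(s < eps | s > 1 - eps)
    s <- pmin(pmax(s, eps), 1 - eps)
    y <- switch(transform,
      cloglog = log(-log(s)),
      scaled_log = -log(s) / times[j]
    )
    x <- sm$x
    curves[[j]] <- data.frame(x = x, y = y)
    ctr <- x >= qs[1] & x <= qs[2]
    if (sum(ctr) < 3) ctr <- rep(TRUE, length(x))
    xx <- x[ctr]; yy <- y[ctr]
    slopes[j] <- if (stats::var(xx) > 0) stats::cov(xx, yy) / stats::var(xx) else 0
    rng <- max(yy) - min(yy)
    ranges[j] <- rng
    if (rng > 0 && xx[length(xx)] > xx[1]) {
      secant <- yy[1] + (yy[length(yy)] - yy[1]) * (xx - xx[1]) /
        (xx[length(xx)] - xx[1])
      linearity[j] <- max(abs(yy - secant)) / rng
    } else {
      linearity[j] <- 0
    }
  }
  w <- if (sum(ranges) > 0) ranges / sum(ranges) else rep(1 / length(ranges), length(ranges))
  structure(
    list(curves = curves, times = times, slopes = slopes,
         linearity = linearity,
         linearity_summary = sum(w * linearity),
         parallelism = stats::mad(slopes) / (1 + abs(stats::median(slopes))),
         clamped = clamped, transform = transform),
    class = "pseudo_curves"
  )
}

#' @export
print.pseudo_curves <- function(x, ...) {
  cat("<pseudo_curves> ", x$transform, " transform, ", length(x$curves),
      " grid times\n", sep = "")
  print(data.frame(time = x$times, slope = x$slopes,
                   linearity = x$linearity), digits = 3)
  cat("parallelism score:", format(x$parallelism, digits = 3),
      "| clamped smooth values:", x$clamped, "\n")
  invisible(x)
}

#' @export
plot.pseudo_curves <- function(x, ..., xlab = "covariate") {
  ylim <- range(unlist(lapply(x$curves, function(cv) cv$y)))
  ylab <- if (x$transform == "cloglog") "log(-log S)" else "-log(S)/t"
  graphics::plot(NULL, xlim = range(x$curves[[1]]$x), ylim = ylim,
                 xlab = xlab, ylab = ylab, ...)
  for (j in seq_along(x$curves)) {
    graphics::lines(x$curves[[j]], col = j)
  }
  graphics::legend("topleft", legend = format(x$times, digits = 2),
                   col = seq_along(x$curves), lty = 1, cex = 0.6,
                   title = "time")
  invisible(x)
}
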