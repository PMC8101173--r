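#' Specify one covariate term of a hazard model
#'
#' Couples a covariate name with a functional form and (for multiplicative
#' models) a time-varying coefficient basis.
#'
#' @param covariate covariate column name in the sample.
#' @param form a [functional_forms] object; default identity.
#' @param tv a [time_varying] basis; default constant coefficient.
#' @return an object of class `haz_term`.
#' @export
haz_term <- function(covariate, form = form_identity(), tv = tv_constant()) {
  stopifnot(is.character(covariate), inherits(form, "haz_form"),
            inherits(tv, "haz_tv"))
  structure(list(covariate = covariate, form = form, tv = tv),
            class = "haz_term")
}

tv_suffixes <- c("", "_t", "_tbrk")

#' Build a counting-process design for an (extended) Cox model
#'
#' When every term has a constant coefficient the sample is carried over as
#' one episode per subject. As soon as one term has a time-varying basis,
#' follow-up is split at every distinct event time and each
#' covariate-by-time-basis interaction becomes an ordinary design column
#' evaluated at the episode's stop time, so the extended model reduces to a
#' standard Cox fit on counting-process data.
#'
#' @param sample a [survival_sample].
#' @param terms list of [haz_term] objects.
#' @return a `counting_process` data frame with attributes `design` (design
#'   column names) and `terms`.
#' @export
build_cox_design <- function(sample, terms) {
  if (inherits(terms, "haz_term")) terms <- list(terms)
  any_tv <- any(vapply(terms, function(tm) tm$tv$basis != "constant", logical(1)))
  cuts <- if (any_tv) sort(unique(sample$time[sample$event == 1])) else numeric(0)
  cuts <- cuts[cuts < max(sample$time)]
  cp <- split_episodes(sample, cuts)
  design <- character(0)
  for (tm in terms) {
    if (!tm$covariate %in% names(cp)) {
      stop("covariate '", tm$covariate, "' not found in sample")
    }
    fx <- apply_form(tm$form, cp[[tm$covariate]])
    if (any(!is.finite(fx))) {
      stop("functional form '", tm$form$label, "' is non-finite on the ",
           "observed range of '", tm$covariate, "'")
    }
    bt <- tv_basis_eval(tm$tv, cp$stop)
    for (a in seq_len(ncol(fx))) {
      base <- paste0(tm$covariate, "_", colnames(fx)[a])
      for (b in seq_len(ncol(bt))) {
        nm <- paste0(base, tv_suffixes[b])
        cp[[nm]] <- fx[, a] * bt[, b]
        design <- c(design, nm)
      }
    }
  }
  attr(cp, "design") <- design
  attr(cp, "terms") <- terms
  cp
}

#' Fit a Cox model on counting-process data
#'
#' Maximizes the partial likelihood over the given design columns (Efron tie
#' correction by default; identical to Breslow when event times are unique)
#' and computes the Breslow baseline cumulative hazard
#' `Lambda0(t) = sum_{t_j <= t} d_j / sum_{risk(t_j)} exp(x' beta)`.
#'
#' @param cp a `counting_process` data frame (see [build_cox_design] or
#'   [split_episodes]); a [survival_sample] is accepted and converted.
#' @param design character vector of design column names; defaults to
#'   `attr(cp, "design")`. May be empty, giving the null model.
#' @param ties `"efron"` or `"breslow"`.
#' @return an object of class `cox_fit` with elements `coefficients`,
#'   `vcov`, `loglik`, `k`, `baseline` (a [haz_step]), `design`, `data`.
#' @export
fit_cox <- function(cp, design = attr(cp, "design"), ties = "efron") {
  if (inherits(cp, "survival_sample")) cp <- split_episodes(cp, numeric(0))
  if (is.null(design)) design <- character(0)
  if (sum(cp$status) < 1) stop("at least one event is required")
  if (length(design)) {
    X <- as.matrix(cp[design])
    if (any(apply(X, 2, stats::var) == 0)) {
      stop("degenerate design: column constant across all risk sets")
    }
    fml <- stats::as.formula(paste(
      "survival::Surv(start, stop, status) ~",
      paste(sprintf("`%s`", design), collapse = " + ")
    ))
    fit <- withCallingHandlers(
      # timefix off: episode boundaries are exact by construction and must
      # not be merged by the near-tie heuristic
      survival::coxph(fml, data = cp, ties = ties,
                      control = survival::coxph.control(iter.max = 50,
                                                        timefix = FALSE)),
      warning = function(w) {
        if (grepl("infinite", conditionMessage(w))) {
          stop("monotone partial likelihood: coefficient diverges", call. = FALSE)
        }
        invokeRestart("muffleWarning")
      }
    )
    beta <- stats::coef(fit)
    if (any(is.na(beta))) stop("degenerate design: singular information matrix")
    names(beta) <- design
    vc <- stats::vcov(fit)
    dimnames(vc) <- list(design, design)
    ll <- fit$loglik[2]
    lp <- as.vector(X %*% beta)
  } else {
    X <- matrix(numeric(0), nrow = nrow(cp), ncol = 0)
    fit <- NULL
    beta <- numeric(0)
    vc <- matrix(numeric(0), 0, 0)
    lp <- rep(0, nrow(cp))
    ll <- partial_loglik(cp, character(0), numeric(0))
  }
  structure(
    list(
      coefficients = beta, vcov = vc, loglik = ll, k = length(beta),
      baseline = breslow_baseline(cp, lp), design = design, data = cp,
      lp = lp, ties = ties, terms = attr(cp, "terms"), coxph = fit
    ),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit> ", x$k, " coefficient(s), partial loglik ",
      format(x$loglik), "\n", sep = "")
  if (x$k > 0) {
    se <- sqrt(diag(x$vcov))
    tab <- data.frame(
      coef = x$coefficients, HR = exp(x$coefficients), se = se,
      p = 2 * stats::pnorm(-abs(x$coefficients / se))
    )
    print(tab, digits = 4)
  }
  invisible(x)
}

# Unique event times, event counts, and per-event risk-set sums of w over
# counting-process rows (row at risk at t iff start < t <= stop).
risk_sums <- function(cp, w) {
  et <- sort(unique(cp$stop[cp$status == 1]))
  J <- length(et)
  d <- as.vector(table(factor(cp$stop[cp$status == 1], levels = et)))
  a <- findInterval(cp$start, et) # event times <= start: excluded
  b <- findInterval(cp$stop, et) # event times <= stop: included
  acc <- numeric(J + 1L)
  inc <- rowsum(w, group = a + 1L)
  acc[as.integer(rownames(inc))] <- inc[, 1]
  dec <- rowsum(w, group = b + 1L)
  keep <- as.integer(rownames(dec)) <= J + 1L
  acc[as.integer(rownames(dec))[keep]] <- acc[as.integer(rownames(dec))[keep]] - dec[keep, 1]
  list(times = et, d = d, S = cumsum(acc)[seq_len(J)])
}

# Breslow baseline cumulative hazard given linear predictors.
breslow_baseline <- function(cp, lp) {
  rs <- risk_sums(cp, exp(lp))
  haz_step(rs$times, cumsum(rs$d / rs$S), origin = 0)
}

#' Cox partial log-likelihood at a supplied coefficient vector
#'
#' Breslow form `sum_events [x'beta - log sum_risk exp(x'beta)]`, guarded
#' against overflow by a max-shift; equals the Efron version when event times
#' are unique. With an empty design this is the null-model value
#' `sum_events -log(Y_j)`.
#'
#' @param cp counting-process data (or a [survival_sample]).
#' @param design design column names (possibly empty).
#' @param beta coefficient vector of matching length.
#' @return a finite scalar.
#' @export
partial_loglik <- function(cp, design, beta) {
  if (inherits(cp, "survival_sample")) cp <- split_episodes(cp, numeric(0))
  stopifnot(length(design) == length(beta))
  lp <- if (length(design)) as.vector(as.matrix(cp[design]) %*% beta) else rep(0, nrow(cp))
  m <- max(lp)
  rs <- risk_sums(cp, exp(lp - m))
  # per tied event time, Breslow counts the full risk set d_j times
  sum(lp[cp$status == 1]) - sum(rs$d * (m + log(rs$S)))
}

#' Akaike information criterion of a Cox fit
#'
#' `-2 * partial loglik + 2 * k` with `k` the number of regression
#' coefficients; used to rank non-nested candidate functional forms.
#'
#' @param fit a `cox_fit` (or `lin_fit`-like object with `loglik` and `k`).
#' @return a scalar.
#' @export
aic <- function(fit) -2 * fit$loglik + 2 * fit$k

#' Schoenfeld residuals of a Cox fit
#'
#' One row per event: the event subject's design-column values minus the
#' `exp(x'beta)`-weighted mean over the risk set at that event time.
#'
#' @param fit a `cox_fit` with at least one design column.
#' @return a data frame of class `schoenfeld_set` with columns `time`,
#'   `rank`, and one residual column per design column.
#' @export
schoenfeld_residuals <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  if (fit$k == 0) stop("Schoenfeld residuals require at least one covariate")
  cp <- fit$data
  ev <- which(cp$status == 1)
  tms <- cp$stop[ev]
  X <- as.matrix(cp[fit$design])
  w <- exp(fit$lp)
  # risk-set weighted means per event time via the interval trick
  sw <- risk_sums(cp, w)
  et <- sw$times
  xbar <- matrix(0, length(et), fit$k)
  for (j in seq_len(fit$k)) {
    xbar[, j] <- risk_sums(cp, w * X[, j])$S / sw$S
  }
  jidx <- match(tms, et)
  res <- X[ev, , drop = FALSE] - xbar[jidx, , drop = FALSE]
  ord <- order(tms)
  out <- data.frame(time = tms[ord], rank = seq_along(tms))
  for (j in seq_len(fit$k)) out[[fit$design[j]]] <- res[ord, j]
  structure(out, class = c("schoenfeld_set", "data.frame"))
}

#' Correlation test of the proportional hazards assumption
#'
#' For each design column, the Pearson correlation between the Schoenfeld
#' residuals and the rank order of event times, with its two-sided t-test
#' p-value. The assumption is taken as satisfied when `p > alpha`. Residual
#' columns with zero variance (e.g. a covariate identical across every risk
#' set) give a degenerate correlation, reported as satisfied with `p = 1`.
#'
#' @param fit a `cox_fit`.
#' @param alpha significance threshold, default 0.05.
#' @return data frame with columns `term`, `rho`, `p`, `satisfied`.
#' @export
ph_test <- function(fit, alpha = 0.05) {
  res <- schoenfeld_residuals(fit)
  if (nrow(res) < 3) stop("proportional hazards test needs at least 3 events")
  rk <- res$rank
  out <- lapply(fit$design, function(nm) {
    r <- res[[nm]]
    if (stats::sd(r) == 0 || stats::sd(rk) == 0) {
      data.frame(term = nm, rho = 0, p = 1, satisfied = TRUE)
    } else {
      ct <- stats::cor.test(r, rk, method = "pearson")
      data.frame(term = nm, rho = unname(ct$estimate), p = ct$p.value,
                 satisfied = ct$p.value > alpha)
    }
  })
  do.call(rbind, out)
}

#' Martingale residuals of a Cox fit
#'
#' Per subject, the observed event count minus the model-estimated cumulative
#' intensity `Lambda0(t_i) * exp(x_i' beta)` accumulated over the subject's
#' episodes (null model: Nelson-Aalen at the follow-up time). Residuals sum
#' to zero by the Breslow baseline identity.
#'
#' @param fit a `cox_fit` (possibly the null model).
#' @return data frame of class `martingale_set` with columns `id`, `residual`.
#' @export
martingale_residuals <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  cp <- fit$data
  L <- fit$baseline
  expect <- exp(fit$lp) * (step_eval(L, cp$stop) - step_eval(L, cp$start))
  per_row <- cp$status - expect
  rs <- rowsum(per_row, group = cp$id)
  structure(
    data.frame(id = rownames(rs), residual = rs[, 1], row.names = NULL),
    class = c("martingale_set", "data.frame")
  )
}

#' Lowess smooth of residuals against a covariate, with flatness score
#'
#' @param residuals a `martingale_set` (or any data frame with columns `id`,
#'   `residual`).
#' @param sample the [survival_sample] the model was fitted on.
#' @param covariate name of a continuous covariate.
#' @return list with the lowess `smooth` (components `x`, `y`) and
#'   `flatness`, the maximum absolute deviation of the smooth from its mean.
#' @export
residual_smooth <- function(residuals, sample, covariate) {
  x <- sample[[covariate]][match(residuals$id, sample$id)]
  sm <- haz_lowess(x, residuals$residual)
  list(smooth = sm, flatness = max(abs(sm$y - mean(sm$y))))
}

#' Rank candidate functional forms of a continuous covariate
#'
#' Fits a univariate Cox model per candidate form, ranks candidates by AIC
#' (ascending), and reports alongside each the flatness score of the lowess
#' smooth of that model's martingale residuals against the untransformed
#' covariate. Candidates that are non-finite on the observed covariate range
#' are skipped with a warning. The flatness score is advisory; AIC decides.
#'
#' @param sample a [survival_sample].
#' @param covariate continuous covariate name.
#' @param candidates list of [functional_forms] objects (at least 2).
#' @return list of class `form_scan`: `table` (label, k, aic, flatness, in
#'   AIC order), `forms` (candidate objects in the same order), `best` (the
#'   AIC-minimizing form).
#' @export
functional_form_scan <- function(sample, covariate, candidates) {
  if (length(candidates) < 2) stop("need at least 2 candidate forms")
  rows <- list(); forms <- list()
  for (fo in candidates) {
    fx <- try(apply_form(fo, sample[[covariate]]), silent = TRUE)
    if (inherits(fx, "try-error") || any(!is.finite(fx))) {
      warning("skipping candidate '", fo$label, "': non-finite on observed range")
      next
    }
    fit <- fit_cox(build_cox_design(sample, list(haz_term(covariate, form = fo))))
    fl <- residual_smooth(martingale_residuals(fit), sample, covariate)$flatness
    rows[[length(rows) + 1L]] <- data.frame(
      label = fo$label, k = fit$k, aic = aic(fit), flatness = fl
    )
    forms[[length(forms) + 1L]] <- fo
  }
  if (!length(rows)) stop("no admissible candidate functional form")
  tab <- do.call(rbind, rows)
  ord <- order(tab$aic)
  structure(
    list(table = tab[ord, , drop = FALSE], forms = forms[ord],
         best = forms[[ord[1]]]),
    class = "form_scan"
  )
}

#' Scan slope-break times for a time-varying coefficient
#'
#' For each candidate break time `c`, fits the extended model with basis
#' `beta + beta_t t + beta_t2 (t - c) I(t > c)` for the covariate (episodes
#' split at event times) and records the AIC. Grid points with no event on
#' one side of `c` are skipped with a warning; AIC ties break toward the
#' smaller `c`.
#'
#' @param sample a [survival_sample].
#' @param covariate covariate name.
#' @param grid candidate break times within the follow-up range.
#' @param form functional form for the covariate, default identity.
#' @return list with `best_break`, `profile` (data frame `break_time`,
#'   `aic`), and `best_fit`.
#' @export
breakpoint_scan <- function(sample, covariate, grid, form = form_identity()) {
  evt <- sample$time[sample$event == 1]
  grid <- sort(grid)
  # split episodes once; only the (t - c)+ interaction column changes with c
  cp <- build_cox_design(
    sample, list(haz_term(covariate, form = form, tv = tv_linear_break(grid[1])))
  )
  design <- attr(cp, "design")
  brk_cols <- design[endsWith(design, "_tbrk")]
  base_cols <- sub("_tbrk$", "", brk_cols)
  rows <- list(); fits <- list()
  for (cc in grid) {
    if (!any(evt <= cc) || !any(evt > cc)) {
      warning("skipping break time ", cc, ": no events on one side")
      next
    }
    for (i in seq_along(brk_cols)) {
      cp[[brk_cols[i]]] <- cp[[base_cols[i]]] * pmax(cp$stop - cc, 0)
    }
    fit <- try(fit_cox(cp, design), silent = TRUE)
    if (inherits(fit, "try-error")) {
      warning("skipping break time ", cc, ": fit failed")
      next
    }
    fit$terms <- list(haz_term(covariate, form = form,
                               tv = tv_linear_break(cc)))
    rows[[length(rows) + 1L]] <- data.frame(break_time = cc, aic = aic(fit))
    fits[[length(fits) + 1L]] <- fit
  }
  if (!length(rows)) stop("no admissible break time in grid")
  prof <- do.call(rbind, rows)
  best <- which.min(prof$aic) # which.min takes the first, i.e. smallest c
  list(best_break = prof$break_time[best], profile = prof,
       best_fit = fits[[best]])
}
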