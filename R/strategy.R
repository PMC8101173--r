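# Orchestration of the two step-by-step model-fitting strategies:
# iterate diagnostics -> model refinement until the model assumptions hold,
# logging every decision with the diagnostic values that justified it.

#' Configuration for the fitting strategies
#'
#' @param ph_alpha p-value threshold below which an assumption test flags a
#'   violation (proportional hazards correlation test, martingale residual
#'   process chi-square test); default 0.05.
#' @param forms named list: continuous covariate -> list of candidate
#'   [functional_forms]. A covariate absent from the list (or with a single
#'   candidate) keeps the identity form and its log-linearity diagnostic is
#'   advisory only.
#' @param tv_bases escalation order of time-varying coefficient bases for
#'   the multiplicative arm; subset of `c("linear", "linear_with_break")`.
#' @param break_grids named list: covariate -> candidate break times for
#'   `linear_with_break` (required for that basis to be reachable).
#' @param pseudo_grid_size number of event-time quantiles at which
#'   pseudo-observation curves are drawn (9 gives the deciles).
#' @param n_strata strata count for quantile-based goodness-of-fit strata.
#' @param resamples wild-bootstrap replicates for residual-process bounds
#'   and Arjas calibration.
#' @param seed master seed; all resampling seeds derive from it.
#' @param max_iter refinement iteration cap.
#' @param linearity_threshold,parallelism_threshold advisory thresholds on
#'   the pseudo-observation curve scores.
#' @param flatness_threshold advisory threshold on the martingale-residual
#'   smooth flatness score when no candidate forms are configured.
#' @param constant_coverage coverage fraction of the Aalen band required to
#'   call an additive effect constant.
#' @return an object of class `strategy_config`.
#' @export
strategy_config <- function(ph_alpha = 0.05, forms = list(),
                            tv_bases = c("linear", "linear_with_break"),
                            break_grids = list(), pseudo_grid_size = 9,
                            n_strata = 4, resamples = 200, seed = 1,
                            max_iter = 5, linearity_threshold = 0.1,
                            parallelism_threshold = 0.1,
                            flatness_threshold = 0.1,
                            constant_coverage = 0.95) {
  stopifnot(ph_alpha > 0, ph_alpha < 1, max_iter >= 1)
  structure(
    list(ph_alpha = ph_alpha, forms = forms, tv_bases = tv_bases,
         break_grids = break_grids, pseudo_grid_size = pseudo_grid_size,
         n_strata = n_strata, resamples = resamples, seed = seed,
         max_iter = max_iter, linearity_threshold = linearity_threshold,
         parallelism_threshold = parallelism_threshold,
         flatness_threshold = flatness_threshold,
         constant_coverage = constant_coverage),
    class = "strategy_config"
  )
}

is_continuous <- function(x) !all(x %in% c(0, 1))

pseudo_time_grid <- function(sample, m) {
  evt <- sample$time[sample$event == 1]
  if (length(evt) < m + 1) stop("too few events for a ", m, "-point grid")
  uq <- unique(unname(stats::quantile(evt, probs = seq_len(m) / (m + 1), type = 7)))
  uq
}

# design columns contributed by covariate `cov`
cols_of <- function(cov, design) design[startsWith(design, paste0(cov, "_"))]

# next time-varying basis in the escalation order, or NULL when exhausted
next_tv <- function(sample, term, config) {
  order_all <- c("constant", config$tv_bases)
  pos <- match(term$tv$basis, order_all)
  while (pos < length(order_all)) {
    pos <- pos + 1
    cand <- order_all[pos]
    if (cand == "linear") return(tv_linear())
    if (cand == "linear_with_break") {
      grid <- config$break_grids[[term$covariate]]
      if (is.null(grid)) next
      sc <- breakpoint_scan(sample, term$covariate, grid, form = term$form)
      return(tv_linear_break(sc$best_break))
    }
  }
  NULL
}

new_log <- function() new.env(parent = emptyenv())

log_entry <- function(env, iter, step, covariate, diagnostic, values,
                      decision, change = FALSE) {
  e <- list(iter = iter, step = step, covariate = covariate,
            diagnostic = diagnostic, values = values, decision = decision,
            change = change)
  env$entries <- c(env$entries, list(e))
}

finish_report <- function(arm, log, terms, fits, converged, iterations,
                          config, violations) {
  structure(
    list(arm = arm, log = log$entries, terms = terms, fits = fits,
         converged = converged, iterations = iterations, config = config,
         violations = violations),
    class = "strategy_report"
  )
}

#' @export
print.strategy_report <- function(x, ...) {
  cat("<strategy_report> ", x$arm, " arm, ", x$iterations, " iteration(s), ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  for (e in x$log) {
    cat(sprintf("  [iter %d | step %d | %s] %s: %s%s\n", e$iter, e$step,
                e$covariate, e$diagnostic, e$decision,
                if (e$change) "  *model revised*" else ""))
  }
  if (length(x$violations)) {
    cat("  unresolved:", paste(x$violations, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Final model terms of a strategy report, refitted
#'
#' Re-executes the final fit recorded in the report's audit trail; used to
#' verify that the trail alone reproduces the delivered model.
#'
#' @param report a `strategy_report`.
#' @param sample the [survival_sample] the strategy ran on.
#' @return the refitted final model (a `cox_fit` for the multiplicative
#'   arm; a list with `aalen`, `lin`, `choice` for the additive arm).
#' @export
refit_from_report <- function(report, sample) {
  if (report$arm == "multiplicative") {
    fit_cox(build_cox_design(sample, unname(report$terms)))
  } else {
    list(
      aalen = fit_aalen(sample, unname(report$terms)),
      lin = fit_lin(sample, unname(report$terms)),
      choice = report$fits$choice
    )
  }
}

#' Step-by-step optimal fitting of a multiplicative hazards model
#'
#' Runs the five-step multiplicative strategy: (1) check log-linearity of
#' each continuous covariate via martingale residuals, selecting the best
#' functional form by AIC among the configured candidates; (2) check
#' proportional hazards per covariate via the Schoenfeld correlation test,
#' escalating to a time-varying coefficient basis (linear in t first, then
#' linear with an AIC-selected slope break) when flagged; (3) check both
#' assumptions simultaneously via cloglog-transformed smoothed
#' pseudo-observation curves; (4) assess goodness-of-fit per covariate with
#' Arjas curves; (5) re-check proportional hazards and goodness-of-fit on
#' the multivariate model with all covariates. Steps repeat until every
#' assumption holds or nothing changes, up to `max_iter` iterations;
#' non-convergence is reported in the result, not raised.
#'
#' @param sample a [survival_sample] with at least one covariate.
#' @param config a [strategy_config].
#' @return a `strategy_report` whose `fits$final` is the multivariate
#'   `cox_fit`.
#' @export
run_multiplicative_strategy <- function(sample, config = strategy_config()) {
  covs <- covariate_names(sample)
  if (!length(covs)) stop("at least one covariate is required")
  cont <- covs[vapply(covs, function(cv) is_continuous(sample[[cv]]), logical(1))]
  terms <- stats::setNames(lapply(covs, haz_term), covs)
  log <- new_log()
  violations <- character(0)
  sd_ctr <- 0
  nseed <- function() {
    sd_ctr <<- sd_ctr + 1
    child_seed(config$seed, sd_ctr)
  }
  grid <- pseudo_time_grid(sample, config$pseudo_grid_size)
  pseudo <- pseudo_observations(sample, grid)
  iter <- 0
  repeat {
    iter <- iter + 1
    changed <- FALSE
    violations <- character(0)

    # Step 1: log-linearity of continuous covariates
    for (cv in cont) {
      cands <- config$forms[[cv]]
      if (length(cands) >= 2) {
        scan <- functional_form_scan(sample, cv, cands)
        adopt <- scan$best$label != terms[[cv]]$form$label
        if (adopt) terms[[cv]]$form <- scan$best
        log_entry(log, iter, 1L, cv, "functional form scan (AIC)",
                  scan$table,
                  paste0("best form: ", scan$best$label), change = adopt)
        changed <- changed || adopt
      } else {
        fit0 <- fit_cox(split_episodes(sample), character(0))
        fl <- residual_smooth(martingale_residuals(fit0), sample, cv)$flatness
        ok <- fl <= config$flatness_threshold
        log_entry(log, iter, 1L, cv, "null-model residual smooth flatness",
                  c(flatness = fl),
                  if (ok) "log-linearity satisfied" else
                    "non-log-linear but no candidate forms configured")
        if (!ok) violations <- c(violations, paste0("step1:", cv))
      }
    }

    # Step 2: proportional hazards per covariate, with tv escalation
    for (cv in covs) {
      repeat {
        fit <- fit_cox(build_cox_design(sample, list(terms[[cv]])))
        pht <- ph_test(fit, config$ph_alpha)
        ok <- all(pht$satisfied)
        if (ok) {
          log_entry(log, iter, 2L, cv, "Schoenfeld rank correlation test",
                    pht, "proportional hazards satisfied")
          break
        }
        nxt <- next_tv(sample, terms[[cv]], config)
        if (is.null(nxt)) {
          log_entry(log, iter, 2L, cv, "Schoenfeld rank correlation test",
                    pht, "non-proportional; no further basis available")
          violations <- c(violations, paste0("step2:", cv))
          break
        }
        terms[[cv]]$tv <- nxt
        changed <- TRUE
        log_entry(log, iter, 2L, cv, "Schoenfeld rank correlation test",
                  pht, paste0("non-proportional; adopting basis: ", nxt$label),
                  change = TRUE)
      }
    }

    # Step 3: simultaneous check via cloglog pseudo-observation curves
    for (cv in cont) {
      curves <- covariate_effect_curves(pseudo, sample[[cv]], "cloglog")
      lin_bad <- curves$linearity_summary > config$linearity_threshold
      par_bad <- curves$parallelism > config$parallelism_threshold
      vals <- c(linearity = curves$linearity_summary,
                parallelism = curves$parallelism)
      if (lin_bad && par_bad) {
        old_form <- terms[[cv]]$form$label
        old_tv <- terms[[cv]]$tv$basis
        cands <- config$forms[[cv]]
        if (length(cands) >= 2) {
          scan <- functional_form_scan(sample, cv, cands)
          terms[[cv]]$form <- scan$best
        }
        esc <- next_tv(sample, terms[[cv]], config)
        if (!is.null(esc)) terms[[cv]]$tv <- esc
        revised <- terms[[cv]]$form$label != old_form ||
          terms[[cv]]$tv$basis != old_tv
        changed <- changed || revised
        if (revised) {
          log_entry(log, iter, 3L, cv, "cloglog pseudo-observation curves",
                    vals, "both assumptions doubtful; extended model adopted",
                    change = TRUE)
        } else {
          log_entry(log, iter, 3L, cv, "cloglog pseudo-observation curves",
                    vals, "both assumptions doubtful; no refinement available")
          violations <- c(violations, paste0("step3:", cv))
        }
      } else {
        log_entry(log, iter, 3L, cv, "cloglog pseudo-observation curves",
                  vals, "simultaneous check passed")
      }
    }

    # Step 4: Arjas goodness-of-fit per covariate (univariate fits)
    for (cv in covs) {
      fit <- fit_cox(build_cox_design(sample, list(terms[[cv]])))
      strat <- if (cv %in% cont) {
        strata_by_quantiles(sample[[cv]], config$n_strata)
      } else {
        factor(sample[[cv]])
      }
      av <- arjas_curves_cox(fit, strat, resamples = config$resamples,
                             seed = nseed())
      log_entry(log, iter, 4L, cv, "Arjas observed-vs-expected curves",
                data.frame(stratum = colnames(av$observed),
                           mean_deviation = av$area,
                           threshold = av$area_threshold),
                if (av$lack_of_fit) "systematic deviation; assumptions to recheck"
                else "goodness-of-fit")
      if (av$lack_of_fit) violations <- c(violations, paste0("step4:", cv))
    }

    # Step 5: multivariate proportional hazards + goodness-of-fit
    mfit <- fit_cox(build_cox_design(sample, unname(terms)))
    pht <- ph_test(mfit, config$ph_alpha)
    for (cv in covs) {
      sub <- pht[pht$term %in% cols_of(cv, mfit$design), , drop = FALSE]
      if (all(sub$satisfied)) next
      nxt <- next_tv(sample, terms[[cv]], config)
      if (is.null(nxt)) {
        log_entry(log, iter, 5L, cv, "multivariate Schoenfeld test", sub,
                  "non-proportional; no further basis available")
        violations <- c(violations, paste0("step5:", cv))
      } else {
        terms[[cv]]$tv <- nxt
        changed <- TRUE
        log_entry(log, iter, 5L, cv, "multivariate Schoenfeld test", sub,
                  paste0("non-proportional; adopting basis: ", nxt$label),
                  change = TRUE)
      }
    }
    if (!any(!pht$satisfied)) {
      log_entry(log, iter, 5L, "(all)", "multivariate Schoenfeld test", pht,
                "proportional hazards satisfied for the multivariate model")
    }

    if (!changed || iter >= config$max_iter) break
  }
  mfit <- fit_cox(build_cox_design(sample, unname(terms)))
  finish_report("multiplicative", log, terms, list(final = mfit),
                converged = length(violations) == 0, iterations = iter,
                config = config, violations = violations)
}

#' Step-by-step optimal fitting of an additive hazards model
#'
#' Runs the four-step additive strategy: (1) check linearity of each
#' continuous covariate via scaled-log-transformed smoothed
#' pseudo-observation curves and the martingale-residual-process chi-square
#' test, selecting among candidate functional forms the one with the
#' largest global p-value when flagged; (2) check the constant-effect
#' assumption per covariate by overlaying the Lin line on the Aalen
#' confidence band, choosing Lin's model when every effect is constant and
#' Aalen's otherwise; (3) assess goodness-of-fit with Arjas curves for
#' continuous covariates (unnecessary for categorical covariates, whose
#' observed and expected counts agree exactly); (4) re-check linearity on
#' the multivariate model. Iterates to `max_iter`; non-convergence is
#' reported, not raised.
#'
#' @param sample a [survival_sample] with at least one covariate.
#' @param config a [strategy_config].
#' @return a `strategy_report` whose `fits` contains the multivariate
#'   `aalen` and `lin` fits and the model `choice`.
#' @export
run_additive_strategy <- function(sample, config = strategy_config()) {
  covs <- covariate_names(sample)
  if (!length(covs)) stop("at least one covariate is required")
  cont <- covs[vapply(covs, function(cv) is_continuous(sample[[cv]]), logical(1))]
  terms <- stats::setNames(lapply(covs, haz_term), covs)
  log <- new_log()
  violations <- character(0)
  sd_ctr <- 0
  nseed <- function() {
    sd_ctr <<- sd_ctr + 1
    child_seed(config$seed + 1L, sd_ctr)
  }
  grid <- pseudo_time_grid(sample, config$pseudo_grid_size)
  pseudo <- pseudo_observations(sample, grid)
  iter <- 0
  choice <- "lin"

  mrp_p <- function(trm) {
    af <- fit_aalen(sample, list(trm))
    strat <- strata_by_quantiles(sample[[trm$covariate]], config$n_strata)
    mrp <- martingale_residual_process(af, strat, resamples = config$resamples,
                                       seed = nseed())
    mrp_chisq_test(mrp, config$ph_alpha)
  }

  repeat {
    iter <- iter + 1
    changed <- FALSE
    violations <- character(0)

    # Step 1: linearity per continuous covariate
    for (cv in cont) {
      curves <- covariate_effect_curves(pseudo, sample[[cv]], "scaled_log")
      tst <- mrp_p(terms[[cv]])
      gp1 <- tst$table$p[tst$table$stratum == "global"]
      vals <- c(linearity = curves$linearity_summary,
                parallelism = curves$parallelism,
                mrp_global_p = gp1)
      if (gp1 > config$ph_alpha) {
        log_entry(log, iter, 1L, cv,
                  "scaled-log pseudo-observation curves + MRP chi-square",
                  vals, "linearity satisfied")
        next
      }
      cands <- config$forms[[cv]]
      if (length(cands) < 2) {
        log_entry(log, iter, 1L, cv,
                  "scaled-log pseudo-observation curves + MRP chi-square",
                  vals, "non-linear; no candidate forms configured")
        violations <- c(violations, paste0("step1:", cv))
        next
      }
      best_p <- -1; best_form <- NULL
      for (fo in cands) {
        tst_f <- mrp_p(haz_term(cv, form = fo))
        p_f <- tst_f$table$p[tst_f$table$stratum == "global"]
        if (p_f > best_p) {
          best_p <- p_f
          best_form <- fo
        }
      }
      if (best_form$label != terms[[cv]]$form$label) {
        terms[[cv]]$form <- best_form
        changed <- TRUE
        log_entry(log, iter, 1L, cv,
                  "scaled-log pseudo-observation curves + MRP chi-square",
                  vals, paste0("non-linear; adopting form: ", best_form$label),
                  change = TRUE)
      } else {
        log_entry(log, iter, 1L, cv,
                  "scaled-log pseudo-observation curves + MRP chi-square",
                  vals, "non-linear but no better candidate form")
        violations <- c(violations, paste0("step1:", cv))
      }
    }

    # Step 2: constant effects (multivariate Aalen vs Lin overlay)
    afit <- fit_aalen(sample, unname(terms))
    lfit <- fit_lin(sample, unname(terms))
    consts <- logical(0)
    for (cv in covs) {
      cls <- cols_of(cv, lfit$design)
      cov_const <- TRUE
      covg <- numeric(0)
      for (cl in cls) {
        chk <- constant_effect_check(afit, lfit, cl,
                                     threshold = config$constant_coverage)
        cov_const <- cov_const && chk$constant
        covg[cl] <- chk$coverage
      }
      consts[cv] <- cov_const
      log_entry(log, iter, 2L, cv, "Lin line inside Aalen band", covg,
                if (cov_const) "effect constant over time"
                else "effect varies over time")
    }
    choice <- if (all(consts)) "lin" else "aalen"
    log_entry(log, iter, 2L, "(all)", "model family choice",
              c(n_constant = sum(consts)),
              paste0("use ", if (choice == "lin") "Lin's" else "Aalen's",
                     " model"))

    # Step 3: Arjas goodness-of-fit for continuous covariates
    for (cv in covs) {
      if (!(cv %in% cont)) {
        log_entry(log, iter, 3L, cv, "Arjas curves", numeric(0),
                  paste0("skipped: unnecessary for a categorical covariate ",
                         "(observed equals estimated events at all times)"))
        next
      }
      strat <- strata_by_quantiles(sample[[cv]], config$n_strata)
      av <- arjas_curves_aalen(afit, strat, resamples = config$resamples,
                               seed = nseed())
      log_entry(log, iter, 3L, cv, "Arjas observed-vs-expected curves",
                data.frame(stratum = colnames(av$observed),
                           mean_deviation = av$area,
                           threshold = av$area_threshold),
                if (av$lack_of_fit) "systematic deviation; assumptions to recheck"
                else "goodness-of-fit")
      if (av$lack_of_fit) violations <- c(violations, paste0("step3:", cv))
    }

    # Step 4: multivariate linearity via MRP on the full model
    for (cv in cont) {
      strat <- strata_by_quantiles(sample[[cv]], config$n_strata)
      mrp <- martingale_residual_process(afit, strat,
                                         resamples = config$resamples,
                                         seed = nseed())
      tst <- mrp_chisq_test(mrp, config$ph_alpha)
      gp <- tst$table$p[tst$table$stratum == "global"]
      if (gp > config$ph_alpha) {
        log_entry(log, iter, 4L, cv, "multivariate MRP chi-square",
                  c(global_p = gp), "linearity satisfied for the full model")
        next
      }
      cands <- config$forms[[cv]]
      alt <- Filter(function(fo) fo$label != terms[[cv]]$form$label,
                    if (length(cands)) cands else list())
      if (length(alt)) {
        best_p <- -1; best_form <- NULL
        for (fo in alt) {
          tst_f <- mrp_p(haz_term(cv, form = fo))
          p_f <- tst_f$table$p[tst_f$table$stratum == "global"]
          if (p_f > best_p) { best_p <- p_f; best_form <- fo }
        }
        terms[[cv]]$form <- best_form
        changed <- TRUE
        log_entry(log, iter, 4L, cv, "multivariate MRP chi-square",
                  c(global_p = gp),
                  paste0("non-linear; adopting form: ", best_form$label),
                  change = TRUE)
      } else {
        log_entry(log, iter, 4L, cv, "multivariate MRP chi-square",
                  c(global_p = gp), "non-linear; no alternative form")
        violations <- c(violations, paste0("step4:", cv))
      }
    }

    if (!changed || iter >= config$max_iter) break
  }
  afit <- fit_aalen(sample, unname(terms))
  lfit <- fit_lin(sample, unname(terms))
  finish_report("additive", log, terms,
                list(aalen = afit, lin = lfit, choice = choice),
                converged = length(violations) == 0, iterations = iter,
                config = config, violations = violations)
}
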