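#' Subject-level right-censored survival data
#'
#' Validates and wraps a data frame of one row per subject with a strictly
#' positive follow-up time, a 0/1 event indicator, and covariate columns
#' without missing values. Categorical covariates (factor or character) are
#' dummy-encoded with the first observed level as the reference; the encoding
#' is recorded in `attr(x, "encoding")` so reports can name levels.
#'
#' @param df data frame with columns `id`, `time`, `event`, plus covariates.
#' @return the validated data frame with class `survival_sample` and
#'   attribute `covariates` (character vector of covariate column names).
#' @export
survival_sample <- function(df) {
  df <- as.data.frame(df)
  for (col in c("id", "time", "event")) {
    if (!col %in% names(df)) stop("missing required column: ", col)
  }
  if (anyDuplicated(df$id)) stop("duplicated subject id: one row per subject required")
  if (!is.numeric(df$time) || any(!is.finite(df$time)) || any(df$time <= 0)) {
    stop("all follow-up times must be strictly positive and finite")
  }
  if (any(!df$event %in% c(0, 1))) {
    stop("event indicator must be 0 (censored) or 1 (event) for every row")
  }
  df$event <- as.integer(df$event)
  covs <- setdiff(names(df), c("id", "time", "event"))
  encoding <- list()
  out <- df[c("id", "time", "event")]
  for (cv in covs) {
    x <- df[[cv]]
    if (anyNA(x)) stop("covariate '", cv, "' has missing values")
    if (is.character(x) || is.factor(x) || is.logical(x)) {
      x <- factor(x, levels = unique(as.character(x)))
      lev <- levels(x)
      encoding[[cv]] <- list(reference = lev[1], levels = lev)
      for (l in lev[-1]) out[[paste0(cv, "_", l)]] <- as.numeric(x == l)
    } else {
      if (!is.numeric(x)) stop("covariate '", cv, "' is neither numeric nor categorical")
      out[[cv]] <- as.numeric(x)
    }
  }
  structure(
    out,
    covariates = setdiff(names(out), c("id", "time", "event")),
    encoding = encoding,
    class = c("survival_sample", "data.frame")
  )
}

#' Covariate column names of a survival sample
#' @param sample a [survival_sample].
#' @return character vector.
#' @export
covariate_names <- function(sample) attr(sample, "covariates")

#' Read a subject-level survival table from CSV
#'
#' @param path CSV file with a header row.
#' @param column_map named list/vector mapping the canonical names `id`,
#'   `time`, `event` (and optionally covariates) to column names in the file;
#'   defaults to identity. File columns not mentioned are taken as covariates
#'   under their own names.
#' @param covariates optional character vector restricting which file columns
#'   are kept as covariates.
#' @param sep field separator, default comma.
#' @return a [survival_sample].
#' @export
read_survival_table <- function(path, column_map = NULL, covariates = NULL, sep = ",") {
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  cmap <- list(id = "id", time = "time", event = "event")
  if (!is.null(column_map)) cmap[names(column_map)] <- unlist(column_map)
  for (canon in names(cmap)) {
    if (!cmap[[canon]] %in% names(raw)) {
      stop("column '", cmap[[canon]], "' (mapped to '", canon, "') not found in ", path)
    }
  }
  df <- data.frame(
    id = raw[[cmap$id]], time = raw[[cmap$time]], event = raw[[cmap$event]]
  )
  used <- unlist(cmap[c("id", "time", "event")])
  covcols <- setdiff(names(raw), used)
  if (!is.null(covariates)) covcols <- intersect(covcols, covariates)
  for (cv in covcols) df[[cv]] <- raw[[cv]]
  survival_sample(df)
}

#' At-risk subject ids at a time point
#'
#' Uses the left-continuous at-risk convention: a subject with follow-up time
#' `T` is at risk at every `t <= T`, in particular at its own event time.
#'
#' @param sample a [survival_sample].
#' @param t a single positive time.
#' @return the ids of at-risk subjects.
#' @export
risk_set <- function(sample, t) {
  stopifnot(length(t) == 1L, t > 0)
  sample$id[sample$time >= t]
}

#' Kaplan-Meier estimator
#'
#' Product-limit estimate of the survival function, with the median survival
#' time (first time where the curve drops to 0.5 or below) and its
#' log-transform based confidence interval.
#'
#' @param sample a [survival_sample].
#' @param conf_level confidence level for the median interval.
#' @return a [haz_step] with extra attributes `median` (named vector:
#'   `estimate`, `lower`, `upper`) and `n`.
#' @export
kaplan_meier <- function(sample, conf_level = 0.95) {
  fit <- survival::survfit(
    survival::Surv(sample$time, sample$event) ~ 1,
    conf.type = "log", conf.int = conf_level
  )
  keep <- fit$n.event > 0
  sf <- haz_step(fit$time[keep], fit$surv[keep], origin = 1)
  qm <- stats::quantile(fit, probs = 0.5)
  med <- c(
    estimate = unname(qm$quantile), lower = unname(qm$lower),
    upper = unname(qm$upper)
  )
  attr(sf, "median") <- med
  attr(sf, "n") <- nrow(sample)
  sf
}

#' Nelson-Aalen estimator of the cumulative hazard
#'
#' @param sample a [survival_sample].
#' @return a [haz_step] starting at 0 with a jump `d_j / Y_j` at each distinct
#'   event time.
#' @export
nelson_aalen <- function(sample) {
  evt <- sort(unique(sample$time[sample$event == 1]))
  if (length(evt) == 0L) return(haz_step(numeric(0), numeric(0), origin = 0))
  d <- vapply(evt, function(t) sum(sample$time == t & sample$event == 1), numeric(1))
  y <- vapply(evt, function(t) sum(sample$time >= t), numeric(1))
  haz_step(evt, cumsum(d / y), origin = 0)
}

#' Break tied survival times by random jitter
#'
#' Adds an independent uniform(0, `scale`) perturbation to every follow-up
#' time so that no two times coincide, while preserving the ordering of
#' originally distinct times. The additive estimators assume no ties.
#'
#' @param sample a [survival_sample].
#' @param seed integer seed making the jitter reproducible.
#' @param scale upper bound of the uniform perturbation; must be smaller than
#'   half the minimum gap between distinct times. Default `1e-6 * max(time)`.
#' @return a [survival_sample] with unique times.
#' @export
jitter_ties <- function(sample, seed, scale = NULL) {
  tms <- sample$time
  gaps <- diff(sort(unique(tms)))
  max_scale <- if (length(gaps)) min(gaps) / 2 else Inf
  if (is.null(scale)) scale <- min(1e-6 * max(tms), max_scale / 2)
  if (scale <= 0) stop("'scale' must be positive")
  if (scale >= max_scale) {
    stop(
      "'scale' too large to preserve the ordering of distinct times ",
      "(must be < ", format(max_scale), ")"
    )
  }
  out <- sample
  repeat {
    jit <- run_seeded(seed, function() stats::runif(length(tms), 0, scale))
    out$time <- tms + jit
    if (!anyDuplicated(out$time)) break
    seed <- seed + 1L # astronomically unlikely; keep determinism anyway
  }
  out
}

#' Split follow-up into counting-process episodes
#'
#' Partitions each subject's `(0, time]` interval at the interior cutpoints,
#' producing one row per episode with columns `id`, `start`, `stop`,
#' `status` and the (time-fixed) covariates copied onto every episode. Only
#' the final episode of a subject can carry `status = 1`.
#'
#' @param sample a [survival_sample].
#' @param cutpoints strictly increasing positive times (may be empty).
#' @return a data frame of class `counting_process`.
#' @export
split_episodes <- function(sample, cutpoints = numeric(0)) {
  cutpoints <- as.numeric(cutpoints)
  if (length(cutpoints)) {
    if (any(cutpoints <= 0) || (length(cutpoints) > 1 && any(diff(cutpoints) <= 0))) {
      stop("cutpoints must be strictly increasing and positive")
    }
  }
  n <- nrow(sample)
  ncut <- findInterval(sample$time, cutpoints, left.open = TRUE)
  reps <- ncut + 1L
  idx <- rep.int(seq_len(n), reps)
  # episode k of subject i spans (cut[k-1], min(cut[k], T_i)]
  epi <- sequence(reps)
  start <- c(0, cutpoints)[epi]
  stop_ <- pmin(c(cutpoints, Inf)[epi], sample$time[idx])
  last <- epi == reps[idx]
  out <- data.frame(
    id = sample$id[idx], start = start, stop = stop_,
    status = ifelse(last, sample$event[idx], 0L)
  )
  for (cv in covariate_names(sample)) out[[cv]] <- sample[[cv]][idx]
  structure(
    out,
    covariates = covariate_names(sample),
    class = c("counting_process", "data.frame")
  )
}

#' Collapse counting-process episodes back to one row per subject
#'
#' Inverse of [split_episodes] for time-fixed covariates.
#'
#' @param cp a `counting_process` data frame.
#' @return a [survival_sample].
#' @export
collapse_episodes <- function(cp) {
  ord <- order(cp$id, cp$stop)
  cp <- cp[ord, ]
  lastrow <- !duplicated(cp$id, fromLast = TRUE)
  rs <- rowsum(cp$status, group = cp$id)
  df <- data.frame(
    id = cp$id[lastrow], time = cp$stop[lastrow],
    event = as.integer(rs[as.character(cp$id[lastrow]), 1])
  )
  for (cv in attr(cp, "covariates")) df[[cv]] <- cp[[cv]][lastrow]
  survival_sample(df)
}
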