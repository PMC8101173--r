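#' Right-continuous step functions over time
#'
#' Container for the step estimators used throughout the package: the
#' Kaplan-Meier survival curve, the Nelson-Aalen cumulative hazard, Breslow
#' baseline cumulative hazards and Aalen cumulative regression functions. The
#' function takes the value `origin` on `[0, times[1])` and, for `t >=
#' times[j]`, the value attached to the last jump time not exceeding `t`
#' (right-continuous convention).
#'
#' @param times strictly increasing jump times (may be empty).
#' @param values value taken from each jump time onwards; same length as
#'   `times`.
#' @param origin value on `[0, times[1])`.
#' @return an object of class `haz_step`.
#' @export
haz_step <- function(times, values, origin) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("'times' and 'values' must have equal length")
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("jump times must be strictly increasing")
  }
  structure(
    list(times = times, values = values, origin = as.numeric(origin)),
    class = "haz_step"
  )
}

#' Evaluate a step function
#'
#' @param sf a [haz_step] object.
#' @param t numeric vector of evaluation times.
#' @return numeric vector of the same length as `t`.
#' @export
step_eval <- function(sf, t) {
  stopifnot(inherits(sf, "haz_step"))
  if (length(sf$times) == 0L) {
    return(rep(sf$origin, length(t)))
  }
  idx <- findInterval(t, sf$times)
  out <- c(sf$origin, sf$values)[idx + 1L]
  out
}

#' @export
print.haz_step <- function(x, ...) {
  cat(
    "<haz_step> ", length(x$times), " jumps, origin ", format(x$origin),
    if (length(x$times)) {
      paste0(", range [", format(min(x$times)), ", ", format(max(x$times)), "]")
    } else "",
    "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
as.data.frame.haz_step <- function(x, ...) {
  data.frame(time = c(0, x$times), value = c(x$origin, x$values))
}

#' @export
plot.haz_step <- function(x, ..., xlab = "time", ylab = "value") {
  df <- as.data.frame(x)
  graphics::plot(
    stats::stepfun(x$times, c(x$origin, x$values)),
    do.points = FALSE, xlab = xlab, ylab = ylab, ...
  )
  invisible(df)
}

#' Write a step function to a two-column CSV
#'
#' @param sf a [haz_step] object.
#' @param path output file path.
#' @export
write_step_csv <- function(sf, path) {
  utils::write.csv(as.data.frame(sf), path, row.names = FALSE)
  invisible(path)
}
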