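#' Functional forms for continuous covariates
#'
#' A functional form maps an observed covariate x to the design column(s) it
#' contributes to a hazard model: the identity, a scaled exponential
#' `exp(x / c)` (pre-scaling avoids overflow for covariates like age),
#' polynomials, fractional polynomials with powers from
#' \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\} (power 0 meaning `log x`), natural cubic
#' spline bases, and a threshold form that adds a supplementary term active
#' only beyond a cutoff (e.g. `exp(x/10)` plus `exp(x/10 - 7) * (x > 70)`).
#'
#' @param scale divisor `c` in `exp(x / c)`.
#' @param powers numeric powers; for `form_poly`, plain powers of x; for
#'   `form_fracpoly`, a subset of the fractional-polynomial power set.
#' @param knots interior knot locations for the spline basis.
#' @param base a `haz_form` evaluated everywhere.
#' @param extra a `haz_form` whose columns are zeroed below `cutoff`.
#' @param cutoff threshold above which `extra` becomes active.
#' @return an object of class `haz_form`.
#' @name functional_forms
NULL

new_form <- function(kind, label, ...) {
  structure(list(kind = kind, label = label, ...), class = "haz_form")
}

#' @rdname functional_forms
#' @export
form_identity <- function() new_form("identity", "x")

#' @rdname functional_forms
#' @export
form_exp <- function(scale = 1) {
  new_form("scaled_exponential", sprintf("exp(x/%g)", scale), scale = scale)
}

#' @rdname functional_forms
#' @export
form_poly <- function(powers = c(1, 2)) {
  new_form("polynomial", paste0("x^(", paste(powers, collapse = ","), ")"),
           powers = powers)
}

#' @rdname functional_forms
#' @export
form_fracpoly <- function(powers) {
  allowed <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)
  if (!all(powers %in% allowed)) {
    stop("fractional-polynomial powers must come from {-2,-1,-0.5,0,0.5,1,2,3}")
  }
  new_form("fractional_polynomial",
           paste0("fp(", paste(powers, collapse = ","), ")"), powers = powers)
}

#' @rdname functional_forms
#' @export
form_spline <- function(knots) {
  new_form("spline", paste0("ns(", length(knots), " knots)"), knots = knots)
}

#' @rdname functional_forms
#' @export
form_threshold <- function(base, extra, cutoff) {
  stopifnot(inherits(base, "haz_form"), inherits(extra, "haz_form"))
  new_form("piecewise_threshold",
           sprintf("%s + [%s](x>%g)", base$label, extra$label, cutoff),
           base = base, extra = extra, cutoff = cutoff)
}

#' @export
print.haz_form <- function(x, ...) {
  cat("<haz_form> ", x$label, "\n", sep = "")
  invisible(x)
}

#' Evaluate a functional form on covariate values
#'
#' @param form a `haz_form`.
#' @param x numeric covariate values.
#' @return a numeric matrix with one column per design term; deterministic
#'   and finite wherever the form is defined on the observed range.
#' @export
apply_form <- function(form, x) {
  stopifnot(inherits(form, "haz_form"))
  out <- switch(form$kind,
    identity = matrix(x, ncol = 1),
    scaled_exponential = matrix(exp(x / form$scale), ncol = 1),
    polynomial = vapply(form$powers, function(p) x^p, numeric(length(x))),
    fractional_polynomial = vapply(
      form$powers,
      function(p) if (p == 0) log(x) else x^p,
      numeric(length(x))
    ),
    spline = ns_basis(x, form$knots),
    piecewise_threshold = {
      b <- apply_form(form$base, x)
      e <- apply_form(form$extra, x) * as.numeric(x > form$cutoff)
      cbind(b, e)
    },
    stop("unknown functional form kind: ", form$kind)
  )
  out <- matrix(out, nrow = length(x))
  colnames(out) <- form_colnames(form)
  out
}

form_colnames <- function(form) {
  switch(form$kind,
    identity = "x",
    scaled_exponential = sprintf("exp_x_%g", form$scale),
    polynomial = paste0("x_pow_", gsub("-", "m", form$powers)),
    fractional_polynomial = paste0("x_fp_", gsub("-", "m", gsub("\\.", "p", form$powers))),
    spline = paste0("x_ns_", seq_len(max(length(form$knots) - 1, 1))),
    piecewise_threshold = c(
      form_colnames(form$base),
      paste0(form_colnames(form$extra), "_gt")
    )
  )
}

# Natural cubic spline basis without pulling in extra dependencies:
# truncated-power representation restricted to be linear beyond the
# boundary knots (Hastie-Tibshirani construction).
ns_basis <- function(x, knots) {
  knots <- sort(knots)
  k <- length(knots)
  if (k < 2) stop("spline form needs at least 2 knots")
  dfun <- function(z, kn) pmax(z - kn, 0)^3
  kk <- knots[k]
  kk1 <- knots[k - 1]
  dk <- function(z, kn) (dfun(z, kn) - dfun(z, kk)) / (kk - kn)
  cols <- lapply(knots[seq_len(k - 2)], function(kn) dk(x, kn) - dk(x, kk1))
  out <- cbind(x, if (length(cols)) do.call(cbind, cols))
  matrix(out, nrow = length(x))
}

#' Time-varying coefficient bases
#'
#' Describe how a covariate's log-hazard coefficient varies with time in the
#' extended multiplicative model: constant (`beta`), linear in time
#' (`beta + beta_t * t`), or linear with a slope break at time `c`
#' (`beta + beta_t * t + beta_t2 * (t - c) * I(t > c)`).
#'
#' @param break_time the slope-break time `c` (same unit as follow-up).
#' @return an object of class `haz_tv`.
#' @name time_varying
NULL

#' @rdname time_varying
#' @export
tv_constant <- function() {
  structure(list(basis = "constant", label = "constant"), class = "haz_tv")
}

#' @rdname time_varying
#' @export
tv_linear <- function() {
  structure(list(basis = "linear", label = "linear in t"), class = "haz_tv")
}

#' @rdname time_varying
#' @export
tv_linear_break <- function(break_time) {
  structure(
    list(basis = "linear_with_break", break_time = break_time,
         label = sprintf("linear in t, break at %g", break_time)),
    class = "haz_tv"
  )
}

#' @export
print.haz_tv <- function(x, ...) {
  cat("<haz_tv> ", x$label, "\n", sep = "")
  invisible(x)
}

# Number of coefficients a tv basis contributes per design column.
tv_dim <- function(tv) {
  switch(tv$basis, constant = 1L, linear = 2L, linear_with_break = 3L)
}

# Evaluate the time basis functions at times t: a matrix whose columns
# multiply the covariate column (first column is the constant 1).
tv_basis_eval <- function(tv, t) {
  switch(tv$basis,
    constant = matrix(1, nrow = length(t), ncol = 1),
    linear = cbind(1, t),
    linear_with_break = cbind(1, t, pmax(t - tv$break_time, 0))
  )
}
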