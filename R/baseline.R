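#' Baseline distribution contract
#'
#' A baseline model supplies the cdf \eqn{G(x;\tau)}, density \eqn{g(x;\tau)}
#' and quantile function of the parent distribution that a generator family
#' (Marshall-Olkin, Weibull-G, exponentiated-G, or their composition) is
#' wrapped around.  The support is the positive half line: the cdf returns 0
#' and the density 0 for `x <= 0`, so empirical-cdf code needs no special
#' casing.
#'
#' In addition to the classical triple, a baseline may supply its cumulative
#' hazard \eqn{H(x) = -\log(1 - G(x))} and its inverse.  The Weibull-G
#' transform acts on \eqn{H}, so having it in closed form avoids
#' catastrophic cancellation deep in the tails; when omitted, both are
#' derived from the cdf/quantile pair.
#'
#' @param name identifier used in printing and the model registry.
#' @param tau named numeric vector of (positive) baseline parameters.
#' @param cdf,pdf,quantile functions of `(x, tau)` (resp. `(p, tau)`).
#' @param logpdf optional log-density; defaults to `log(pdf)`.
#' @param cumhaz,cumhaz_inv optional cumulative hazard and inverse.
#' @return an object of class `mowg_baseline`.
#' @export
baseline_model <- function(name, tau, cdf, pdf, quantile,
                           logpdf = NULL, cumhaz = NULL, cumhaz_inv = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (is.null(names(tau)) || any(names(tau) == ""))
    stop("baseline parameters 'tau' must be named")
  for (nm in names(tau)) check_positive(tau[[nm]], nm)
  if (is.null(logpdf)) logpdf <- function(x, tau) log(pdf(x, tau))
  if (is.null(cumhaz)) cumhaz <- function(x, tau) -log1p(-cdf(x, tau))
  if (is.null(cumhaz_inv))
    cumhaz_inv <- function(w, tau) quantile(-expm1(-w), tau)
  structure(
    list(name = name, tau = tau, cdf = cdf, pdf = pdf, quantile = quantile,
         logpdf = logpdf, cumhaz = cumhaz, cumhaz_inv = cumhaz_inv),
    class = "mowg_baseline")
}

#' @export
print.mowg_baseline <- function(x, ...) {
  cat("<baseline:", x$name, "> ",
      paste(names(x$tau), signif(unlist(x$tau), 5), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Exponential baseline, rate parameterization
#'
#' @param rate positive rate \eqn{\lambda}; `cdf(x) = 1 - exp(-rate * x)`.
#' @export
baseline_exponential <- function(rate) {
  check_positive(rate, "rate")
  baseline_model(
    name = "exponential",
    tau = c(rate = rate),
    cdf = function(x, tau) ifelse(x > 0, -expm1(-tau[["rate"]] * x), 0),
    pdf = function(x, tau) ifelse(x > 0, tau[["rate"]] * exp(-tau[["rate"]] * x),
                                  ifelse(x == 0, tau[["rate"]], 0)),
    quantile = function(p, tau) stats::qexp(p, rate = tau[["rate"]]),
    logpdf = function(x, tau) ifelse(x >= 0, log(tau[["rate"]]) - tau[["rate"]] * x, -Inf),
    cumhaz = function(x, tau) pmax(x, 0) * tau[["rate"]],
    cumhaz_inv = function(w, tau) w / tau[["rate"]])
}

#' Weibull baseline, shape/scale parameterization
#'
#' `cdf(x) = 1 - exp(-(x / scale)^shape)`.  For `shape < 1` the density
#' diverges at the origin; the limit value `Inf` is returned at exactly 0.
#'
#' @param shape,scale positive Weibull parameters \eqn{\gamma}, \eqn{\delta}.
#' @export
baseline_weibull <- function(shape, scale) {
  check_positive(shape, "shape")
  check_positive(scale, "scale")
  baseline_model(
    name = "weibull",
    tau = c(shape = shape, scale = scale),
    cdf = function(x, tau) ifelse(x > 0,
                                  -expm1(-(x / tau[["scale"]])^tau[["shape"]]), 0),
    pdf = function(x, tau) ifelse(x >= 0,
                                  stats::dweibull(x, tau[["shape"]], tau[["scale"]]), 0),
    quantile = function(p, tau) stats::qweibull(p, tau[["shape"]], tau[["scale"]]),
    logpdf = function(x, tau) ifelse(x >= 0,
                                     stats::dweibull(x, tau[["shape"]], tau[["scale"]], log = TRUE),
                                     -Inf),
    cumhaz = function(x, tau) (pmax(x, 0) / tau[["scale"]])^tau[["shape"]],
    cumhaz_inv = function(w, tau) tau[["scale"]] * w^(1 / tau[["shape"]]))
}
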