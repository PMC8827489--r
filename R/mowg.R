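#' Generator parameters of the MOW-G family
#'
#' The triple \eqn{(\alpha, c, \beta)} shared by every member of the family:
#' \eqn{\alpha > 0} is the Marshall-Olkin tilt, \eqn{c > 0} and
#' \eqn{\beta > 0} are the shape and scale of the Weibull generator.
#' \eqn{\bar\alpha = 1 - \alpha} is derived, never stored.
#'
#' @param alpha,c,beta positive reals.
#' @return a named list of class `mowg_params`.
#' @export
generator_params <- function(alpha, c, beta) {
  cc <- c; rm(c)
  check_positive(alpha, "alpha")
  check_positive(cc, "c")
  check_positive(beta, "beta")
  structure(list(alpha = alpha, c = cc, beta = beta), class = "mowg_params")
}

#' @rdname generator_params
#' @param params a `mowg_params` object.
#' @export
alpha_bar <- function(params) 1 - params$alpha

#' Marshall-Olkin tilt of a cdf value
#'
#' Maps a baseline cdf value \eqn{G} to \eqn{G / (\alpha + \bar\alpha G)}.
#' The tilt is the identity at \eqn{\alpha = 1} and preserves the endpoints
#' 0 and 1 for every \eqn{\alpha > 0}.
#'
#' @param alpha positive tilt parameter.
#' @param g cdf value(s) in \[0, 1\].
#' @export
mo_cdf <- function(alpha, g) {
  check_positive(alpha, "alpha")
  check_probability(g, "g")
  g / (alpha + (1 - alpha) * g)
}

#' Weibull-G transform of a cdf value
#'
#' Maps a baseline cdf value \eqn{G} to
#' \eqn{1 - \exp[-((-\log(1-G))/\beta)^c]}, i.e. pushes the baseline
#' cumulative hazard through a Weibull cdf with shape `c` and scale `beta`.
#' `g = 1` returns 1 exactly (the limit), not an error.
#'
#' @param c,beta positive Weibull generator shape and scale.
#' @param g cdf value(s) in \[0, 1\].
#' @export
weibullg_cdf <- function(c, beta, g) {
  cc <- c; rm(c)
  check_positive(cc, "c")
  check_positive(beta, "beta")
  check_probability(g, "g")
  w <- -log1p(-g)                       # baseline cumulative hazard
  ifelse(g >= 1, 1, -expm1(-(w / beta)^cc))
}

#' MOW-G distribution object
#'
#' Composes the Marshall-Olkin tilt with the Weibull-G transform of a
#' baseline: \eqn{F(x) = W / (1 - \bar\alpha (1 - W))} with
#' \eqn{W = 1 - \exp[-(H(x)/\beta)^c]} and \eqn{H} the baseline cumulative
#' hazard.  Evaluation at the support boundaries returns 0 and 1.
#'
#' @param alpha,c,beta generator parameters (see [generator_params()]).
#' @param baseline a [baseline_model()] object.
#' @return an object of class `mowg`.
#' @examples
#' d <- mowg_dist(2, 1, 1, baseline_exponential(1))
#' pmowg(1, d)        # (1 - e^-1) / (1 + e^-1)
#' qmowg(0.5, d)      # median
#' @export
mowg_dist <- function(alpha, c, beta, baseline) {
  gen <- generator_params(alpha, c, beta)
  if (!inherits(baseline, "mowg_baseline"))
    stop("'baseline' must be a baseline_model()")
  structure(list(gen = gen, baseline = baseline), class = "mowg")
}

#' @export
print.mowg <- function(x, ...) {
  cat(sprintf("<MOW-G: alpha=%g, c=%g, beta=%g; baseline %s(%s)>\n",
              x$gen$alpha, x$gen$c, x$gen$beta, x$baseline$name,
              paste(names(x$baseline$tau), signif(unlist(x$baseline$tau), 5),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

# t = (H(x)/beta)^c, the Weibull-G transformed cumulative hazard
.mowg_t <- function(dist, x) {
  H <- dist$baseline$cumhaz(x, dist$baseline$tau)
  (H / dist$gen$beta)^dist$gen$c
}

#' Distribution function of a MOW-G distribution
#'
#' @param q vector of quantiles.
#' @param dist a [mowg_dist()] object.
#' @param lower.tail,log.p as in [stats::pweibull()].
#' @export
pmowg <- function(q, dist, lower.tail = TRUE, log.p = FALSE) {
  a <- dist$gen$alpha
  t <- .mowg_t(dist, pmax(q, 0))
  t[q <= 0] <- 0
  E <- exp(-t)
  if (lower.tail) {
    W <- -expm1(-t)
    val <- W / (a + (1 - a) * W)
    if (log.p) log(val) else val
  } else {
    # survival = alpha * E / (1 - (1-alpha) E), stable in log space
    ls <- log(a) - t - log1p(-(1 - a) * E)
    if (log.p) ls else exp(ls)
  }
}

#' Density of a MOW-G distribution
#'
#' Computed in log space from the baseline log-density and cumulative
#' hazard; the linear-scale value exponentiates the log form, so very large
#' \eqn{(H/\beta)^c} underflow to 0 instead of overflowing.  At `x = 0` the
#' density limit is returned (`Inf` when the effective power is below 1).
#'
#' @param x vector of evaluation points.
#' @param dist a [mowg_dist()] object.
#' @param log logical; return the log-density.
#' @export
dmowg <- function(x, dist, log = FALSE) {
  a <- dist$gen$alpha; cc <- dist$gen$c; b <- dist$gen$beta
  bl <- dist$baseline
  out <- rep(-Inf, length(x))
  ok <- x >= 0
  if (any(ok)) {
    xs <- x[ok]
    H <- bl$cumhaz(xs, bl$tau)
    t <- (H / b)^cc
    lg <- bl$logpdf(xs, bl$tau)
    # (c-1) * log(H/beta), with the c = 1 case handled so 0 * -Inf = 0
    pow <- if (cc == 1) 0 else (cc - 1) * (log(H) - log(b))
    lf <- log(a) + log(cc) - log(b) + lg + H + pow - t -
      2 * log1p(-(1 - a) * exp(-t))
    lf[!is.finite(lf) & H == 0 & cc < 1] <- Inf   # density pole at the origin
    out[ok] <- lf
  }
  if (log) out else exp(out)
}

#' Quantile function of a MOW-G distribution
#'
#' Inverts the family cdf:
#' \eqn{Q(p) = G^{-1}\{1 - \exp[-\beta(-\log\frac{1-p}{1-\bar\alpha p})^{1/c}]\}}.
#' This is the algebraic inversion of the family cdf; the version sometimes
#' quoted with numerator \eqn{1-\alpha p} is a misprint (it produces
#' \eqn{\log 0} at \eqn{p = 1/2}, \eqn{\alpha = 2}) -- see the methods
#' vignette.  `p = 0` returns the support infimum.
#'
#' @param p probabilities in \[0, 1).
#' @param dist a [mowg_dist()] object.
#' @export
qmowg <- function(p, dist) {
  check_probability(p, "p", allow_one = FALSE)
  a <- dist$gen$alpha; cc <- dist$gen$c; b <- dist$gen$beta
  # t = -log[(1-p)/(1 - (1-a) p)] = log1p(a p / (1-p)), always >= 0
  t <- log1p(a * p / (1 - p))
  H <- b * t^(1 / cc)
  out <- dist$baseline$cumhaz_inv(H, dist$baseline$tau)
  out[p == 0] <- 0
  out
}

#' Median of a MOW-G distribution
#' @param dist a [mowg_dist()] object.
#' @export
mowg_median <- function(dist) qmowg(0.5, dist)

#' Hazard rate of a MOW-G distribution
#'
#' \eqn{h(x) = f(x) / S(x)}, computed from the log-density and log-survival.
#' Where the survival underflows to zero the hazard is `Inf` with a warning.
#'
#' @inheritParams dmowg
#' @export
hmowg <- function(x, dist) {
  ls <- pmowg(x, dist, lower.tail = FALSE, log.p = TRUE)
  if (any(is.infinite(ls) & ls < 0))
    warning("survival underflow: hazard returned as Inf")
  exp(dmowg(x, dist, log = TRUE) - ls)
}

#' Random variates from a MOW-G distribution
#'
#' Inversion sampling: seeded uniforms pushed through [qmowg()], so the same
#' seed reproduces the same sample on every platform.
#'
#' @param n number of draws.
#' @param dist a [mowg_dist()] object.
#' @param seed optional integer seed; `NULL` uses (and advances) the
#'   caller's RNG stream.
#' @export
rmowg <- function(n, dist, seed = NULL) {
  stopifnot(n >= 1)
  u <- with_seed(seed, stats::runif(n))
  qmowg(u, dist)
}
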