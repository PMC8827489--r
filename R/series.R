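# Series expansion machinery and distributional properties:
# the linear representation of the family density as an infinite mixture of
# exponentiated-G densities, and quadrature-based moments, mgf, incomplete
# moments, Renyi entropy and order statistics.
#
# The production evaluation path for moments/entropy is quantile-domain
# quadrature; the truncated series is a cross-check oracle for the direct
# density, not the default evaluator (the nested sums converge slowly and
# involve generalized binomial coefficients with non-integer upper index).

.ptm_cache <- new.env(parent = emptyenv())

#' Power-log expansion constants P(t, m)
#'
#' The recursively defined constants appearing in the power-series
#' expansion of \eqn{(-\log(1-x))^{a-1}}:
#' \deqn{P_{t,0} = 1, \quad
#'   P_{t,m} = m^{-1}\sum_{l=1}^{m} (-1)^l \frac{l(t+1)-m}{l+1} P_{t,m-l}.}
#' Values are memoized.
#'
#' @param t,m nonnegative integers.
#' @export
ptm <- function(t, m) {
  if (t < 0 || m < 0 || t != round(t) || m != round(m))
    stop("t and m must be nonnegative integers")
  if (m == 0) return(1)
  key <- paste(t, m)
  hit <- .ptm_cache[[key]]
  if (!is.null(hit)) return(hit)
  l <- seq_len(m)
  val <- sum((-1)^l * (l * (t + 1) - m) / (l + 1) *
               vapply(m - l, function(mm) ptm(t, mm), numeric(1))) / m
  .ptm_cache[[key]] <- val
  val
}

# binom(m - a1, m) * a1 / (a1 - t) with the t >= 1 pole removed
# algebraically: for t in [1, m] the factor (y - (m - t)) of the falling
# factorial equals -(a1 - t), so the ratio simplifies exactly.
.series_zpart <- function(a1, m, t) {
  y <- m - a1
  if (t == 0) return(gchoose(y, m))           # ratio a1/(a1-0) == 1 by convention
  k <- 0:(m - 1)
  -a1 * prod(y - k[k != (m - t)]) / factorial(m)
}

#' Truncation bounds for the series density
#'
#' @param J,I,R,M nonnegative truncation orders of the j, i, r, m sums;
#'   `K` bounds the extra k sum of the `alpha > 1` regime (defaults to `J`).
#' @export
series_truncation <- function(J = 10, I = 10, R = 10, M = 10, K = J) {
  for (v in c(J = J, I = I, R = R, M = M, K = K))
    if (v < 0 || v != round(v)) stop("truncations must be nonnegative integers")
  list(J = J, I = I, R = R, M = M, K = K)
}

#' Truncated mixture-series density of a MOW-G distribution
#'
#' Evaluates the finite truncation of the exponentiated-G mixture
#' representation of the family density.  Two regimes exist, for tilt
#' below and above one; the untilted case `alpha = 1` is excluded (the
#' direct density [dmowg()] applies there unchanged).  As the truncation
#' orders grow the partial sum converges to [dmowg()].
#'
#' @param dist a [mowg_dist()] object with `alpha != 1`.
#' @param x evaluation points (interior of the support).
#' @param trunc a [series_truncation()] list.
#' @export
series_pdf <- function(dist, x, trunc = series_truncation()) {
  a <- dist$gen$alpha; cc <- dist$gen$c; b <- dist$gen$beta
  if (a == 1)
    stop("series representation needs alpha != 1; use dmowg() directly")
  bl <- dist$baseline
  G <- bl$cdf(x, bl$tau)
  g <- bl$pdf(x, bl$tau)
  r_sum <- Reduce(`+`, lapply(0:trunc$R, function(r) G^r))
  i_weight <- if (a < 1) {
    j <- 0:trunc$J
    function(i) sum((j + 1)^(i + 1) * a * (1 - a)^j)
  } else {
    # sum k first with its complete inner j-sum: the alternating binomial
    # sum over j is a k-th finite difference of the degree-i polynomial
    # (j+1)^i and vanishes identically for k > i, so the k-sum terminates
    # on its own; truncating in the interchanged (j-outer) order instead
    # leaves enormous unbalanced cancellation.
    function(i) {
      tot <- 0
      for (k in 0:min(trunc$K, i)) {
        j <- 0:k
        tot <- tot + (k + 1) * (1 - 1 / a)^k / a *
          sum((-1)^j * choose(k, j) * (j + 1)^i)
      }
      tot
    }
  }
  out <- numeric(length(x))
  for (i in 0:trunc$I) {
    a1 <- cc * (i + 1) - 1
    mt <- 0
    for (m in 0:trunc$M) {
      tv <- 0
      for (t in 0:m)
        tv <- tv + (-1)^(t + m) * .series_zpart(a1, m, t) * choose(m, t) * ptm(t, m)
      mt <- mt + tv * G^m
    }
    out <- out + (-1)^i / factorial(i) * i_weight(i) * b^(-cc * (i + 1)) *
      G^(cc * (i + 1) - 1) * mt
  }
  cc * g * r_sum * out
}

# dispatch helpers: properties accept either a composed mowg object or an
# instantiated registry model
.qfun <- function(dist) {
  if (inherits(dist, "mowg")) function(p) qmowg(p, dist)
  else if (inherits(dist, "mowg_model")) dist$quantile
  else stop("need a 'mowg' or 'mowg_model' object")
}
.cfun <- function(dist) {
  if (inherits(dist, "mowg")) function(q) pmowg(q, dist)
  else if (inherits(dist, "mowg_model")) dist$cdf
  else stop("need a 'mowg' or 'mowg_model' object")
}
.lfun <- function(dist) {
  if (inherits(dist, "mowg")) function(x) dmowg(x, dist, log = TRUE)
  else if (inherits(dist, "mowg_model")) dist$logpdf
  else stop("need a 'mowg' or 'mowg_model' object")
}

.quad <- function(f, lower, upper, what, rel.tol = 1e-9) {
  res <- tryCatch(stats::integrate(f, lower, upper, rel.tol = rel.tol,
                                   subdivisions = 500L),
                  error = function(e) e)
  if (inherits(res, "error") || res$message != "OK" || !is.finite(res$value)) {
    warning(sprintf("%s quadrature did not converge (%s)", what,
                    if (inherits(res, "error")) conditionMessage(res) else res$message))
    return(NaN)
  }
  res$value
}

#' Raw moments by quantile-domain quadrature
#'
#' \eqn{E[X^r] = \int_0^1 Q(p)^r\,dp}; integrating in the probability
#' domain avoids truncating the infinite support.  Non-convergent
#' quadrature (heavy tails) yields `NaN` with a warning.
#'
#' @param dist a `mowg` or `mowg_model` object.
#' @param r_ord nonnegative integer moment order.
#' @export
raw_moment <- function(dist, r_ord) {
  if (r_ord < 0 || r_ord != round(r_ord)) stop("r_ord must be a nonnegative integer")
  if (r_ord == 0) return(1)
  Q <- .qfun(dist)
  .quad(function(p) Q(p)^r_ord, 0, 1, "moment")
}

#' Incomplete moments
#'
#' \eqn{\int_0^z x^s f(x)\,dx}, computed as \eqn{\int_0^{F(z)} Q(p)^s\,dp}.
#'
#' @inheritParams raw_moment
#' @param s_ord positive integer order.
#' @param z_upper upper limit; values at or below the support infimum give 0.
#' @export
incomplete_moment <- function(dist, s_ord, z_upper) {
  if (s_ord < 1 || s_ord != round(s_ord)) stop("s_ord must be a positive integer")
  if (z_upper <= 0) return(0)
  Q <- .qfun(dist); Fz <- .cfun(dist)(z_upper)
  if (Fz == 0) return(0)
  .quad(function(p) Q(p)^s_ord, 0, Fz, "incomplete moment")
}

#' Moment generating function
#'
#' \eqn{M(t) = \int_0^1 e^{tQ(p)}dp}.  Beyond the exponential-tail
#' abscissa of convergence the integral diverges; a warning is raised and
#' `NaN` returned rather than an error.
#'
#' @inheritParams raw_moment
#' @param t_arg evaluation point.
#' @export
mowg_mgf <- function(dist, t_arg) {
  if (t_arg == 0) return(1)
  Q <- .qfun(dist)
  .quad(function(p) exp(t_arg * Q(p)), 0, 1, "mgf")
}

#' Renyi entropy
#'
#' \eqn{H_R = (1-R)^{-1}\log\int f(x)^R dx}, evaluated as
#' \eqn{\int_0^1 f(Q(p))^{R-1}dp} in the probability domain.  `R = 1` is a
#' domain error; the Shannon limit is available as [shannon_entropy()].
#'
#' @inheritParams raw_moment
#' @param R_ord positive order, different from 1.
#' @export
renyi_entropy <- function(dist, R_ord) {
  if (!is.finite(R_ord) || R_ord <= 0)
    stop("R_ord must be positive")
  if (R_ord == 1)
    stop("R_ord = 1 is the Shannon limit; use shannon_entropy()")
  Q <- .qfun(dist); lf <- .lfun(dist)
  val <- .quad(function(p) exp((R_ord - 1) * lf(Q(p))), 0, 1, "entropy")
  log(val) / (1 - R_ord)
}

#' @rdname renyi_entropy
#' @export
shannon_entropy <- function(dist) {
  Q <- .qfun(dist); lf <- .lfun(dist)
  -.quad(function(p) lf(Q(p)), 0, 1, "entropy")
}

#' Order-statistic density
#'
#' Density of the q-th order statistic of an i.i.d. sample of size n,
#' \eqn{\frac{n!}{(q-1)!(n-q)!} f(x) F(x)^{q-1} (1-F(x))^{n-q}},
#' computed in log space.
#'
#' @inheritParams raw_moment
#' @param q_idx,n_total integer rank and sample size, `1 <= q_idx <= n_total`.
#' @param x evaluation points.
#' @export
order_stat_pdf <- function(dist, q_idx, n_total, x) {
  if (q_idx < 1 || q_idx > n_total || q_idx != round(q_idx) || n_total != round(n_total))
    stop("need integer 1 <= q_idx <= n_total")
  lf <- .lfun(dist)(x)
  FF <- .cfun(dist)(x)
  mult0 <- function(k, lx) if (k == 0) 0 else k * lx
  lc <- lgamma(n_total + 1) - lgamma(q_idx) - lgamma(n_total - q_idx + 1)
  exp(lc + lf + mult0(q_idx - 1, log(FF)) + mult0(n_total - q_idx, log1p(-FF)))
}
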