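---
title: "Methods: the Marshall-Olkin Weibull generated family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Marshall-Olkin Weibull generated family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mowg)
```

## The family

Two classical ways of adding flexibility to a baseline lifetime law
$G(x;\tau)$ are composed here.  The **Marshall–Olkin tilt** maps a cdf to

$$F_{MO}(x) = \frac{G(x)}{\alpha + \bar\alpha\,G(x)}, \qquad
  \bar\alpha = 1-\alpha,\; \alpha > 0,$$

reshaping the tails and the hazard without changing the support
($\alpha = 1$ is the identity).  The **Weibull-G transform** pushes the
baseline cumulative hazard $H(x) = -\log(1-G(x))$ through a Weibull cdf
with shape $c$ and scale $\beta$:

$$F_{WG}(x) = 1 - \exp\!\left[-\left(H(x)/\beta\right)^{c}\right].$$

Their composition is the MOW-G family implemented by `mowg_dist()`:

$$F(x;\alpha,c,\beta,\tau)
  = \frac{1-e^{-(H(x)/\beta)^c}}{1-\bar\alpha\,e^{-(H(x)/\beta)^c}}.$$

With an exponential baseline (rate $\lambda$) this is the
four-parameter MOW-E model; with a Weibull baseline (shape $\gamma$,
scale $\delta$) the five-parameter MOW-W model.  Depending on the
parameters the density can be symmetric, left/right skewed, J- or
reversed-J-shaped, and the hazard increasing, decreasing, bathtub or
upside-down bathtub — which is why the family is useful for survival,
reliability and epidemic-mortality data.

All densities and survival functions are evaluated in log space from the
baseline log-density and cumulative hazard; linear-scale values
exponentiate the log form.  This matters: for large $(H/\beta)^c$ the
naive formula overflows, and composing through the cdf value $G$ loses
the entire tail once $G$ rounds to 1 in double precision, whereas the
cumulative-hazard route does not.

### Quantile function — a corrected inversion

Inverting $F$ gives
$$Q(p) = G^{-1}\!\left\{1-\exp\!\left[-\beta\left(-\log\tfrac{1-p}{1-\bar\alpha p}\right)^{1/c}\right]\right\}.$$
A version of this formula circulates with inner ratio
$(1-\alpha p)/(1-\bar\alpha p)$; that form is not the inverse of the
family cdf (at $\alpha = 2$, $p = 1/2$ it requires $\log 0$).  The
package uses the corrected inversion, and the arbiter is the round-trip
invariant $|F(Q(p)) - p| < 10^{-8}$, enforced across a parameter sweep
in the test suite.  Random variates are generated by inversion only, so
a fixed seed reproduces samples bit-for-bit on any platform.

## Identifiability structure

The sub-models are deliberately over-parameterized, matching the
published parameterization so that tabulated comparisons stay
mechanical.  The cost is exact likelihood ridges:

* **MOW-E** depends on $(\lambda,\beta)$ only through $\lambda/\beta$
  (one-dimensional ridge);
* **MOW-W** depends on $(c,\beta,\gamma,\delta)$ only through the
  effective Weibull exponent $\gamma c$ and one scale combination
  (two-dimensional ridge) — in fact both sub-models collapse to the same
  identifiable three-parameter Marshall–Olkin Weibull law, exposed as
  `"mow-w-reduced"` (and `"mow-e-reduced"` for the rate version);
* **Weibull-E and Weibull-W** are each the plain two-parameter Weibull
  in disguise, so their maximized likelihoods must coincide on any
  sample — a useful sanity check on published tables, which sometimes
  print slightly different values for the two (an optimizer artifact).

The maximized likelihood is unique despite the ridges; individual ridge
coordinates are not.  `standard_errors()` therefore warns when the
observed information is near-singular or severely ill-conditioned, and
reports pseudo-inverse SEs with `NA` where the diagonal collapses.

## Fitting: multi-start ML with degeneracy screens

`fit_mle()` optimizes the log-likelihood over log-transformed
parameters: a deterministic lattice of moment-matched and dispersed
starts (tilt $\alpha \in \{0.01,\dots,100\}$, generator shape
$c \in \{0.5,\dots,8\}$, baseline anchored at moment estimates) plus
seeded random jitters; each start is refined by Nelder–Mead and
polished by box-constrained BFGS inside $|\log\theta| \le 12$.
Gradients are numerical throughout — printed score equations for this
family contain typographical artifacts, so the log-likelihood itself is
the single source of truth.

Two screens discard *degenerate* optima, both discovered during
development and both intrinsic to tilted families:

1. **Tilt collapse.**  As $\alpha \to 0$ with the scale drifting, the
   Marshall–Olkin Weibull converges to a log-logistic distribution (and
   as $\alpha\to\infty$ the MO-exponential approaches a logistic);
   on peaked samples this boundary limit can beat every interior
   stationary point by several log-likelihood units while leaving the
   family.  Candidates pinned at the search-box edge are classified as
   boundary-degenerate and excluded (an `allow_boundary` switch exposes
   the ridge supremum for study).
2. **Tie spikes.**  On the MOW-W scale ridge the effective exponent
   $\gamma c$ can diverge and place a near-atom on tied observations,
   sending the likelihood to $+\infty$.  A candidate whose fitted
   log-density at a data point exceeds $\log(10/\delta)$, with $\delta$
   the smallest positive spacing in the sample, is rejected: a spike
   narrower than the data's resolution carries no empirical content.

What is reported is the best *interior* optimum — the quantity the
applied literature tabulates.  A caveat follows honestly from this:
a fully converged interior optimum is occasionally *deeper* than
published values obtained with default optimizer settings (on the
bundled COVID sample the MOW-E stationary point lies at
$-\ell = 47.044$, about $0.011$ below the published figure, and a
converged MO-exponential fit changes that table's AIC ranking).  The
package reports the converged values.

### Criterion panel

`gof_panel()` reports AIC, BIC, the Cramér–von Mises and
Anderson–Darling statistics with the Chen–Balakrishnan small-sample
modification (unmodified $W^2$, $A^2$ are also returned), the two-sided
Kolmogorov–Smirnov distance and its asymptotic p-value (no correction
for estimated parameters, matching common practice in this literature).
Published tables in this area satisfy CAIC $=(\mathrm{AIC}+\mathrm{BIC})/2$
row by row, so that convention is the default `caic`; Bozdogan's
consistent AIC, $2\hat\ell + k(\log n + 1)$, is exposed as
`caic_bozdogan`.  Probability-integral transforms exactly equal to 0 or
1 are clipped to $[10^{-10}, 1-10^{-10}]$ with a warning.

## Series machinery

For $\alpha \ne 1$ the density admits an infinite linear representation
in exponentiated-G densities, built from the expansion constants
$P_{t,m}$ (`ptm()`, memoized recursion with $P_{t,0}=1$), generalized
binomial coefficients with non-integer upper index (evaluated as exact
falling-factorial products, with the $t \ge 1$ pole of the
$(a-1)/(a-1-t)$ factor removed algebraically), and a two-regime tilt
expansion.  `series_pdf()` evaluates finite truncations; for the
$\alpha > 1$ regime the interchanged double sum is summed with complete
inner blocks, where the alternating binomial sum is a $k$-th finite
difference of a degree-$i$ polynomial and vanishes for $k > i$, making
the outer sum self-terminating.

The series is a *cross-check oracle*, not the production path: the test
suite verifies truncation error decreasing toward the direct density in
both regimes, but for tilts far from 1 (especially $|1-\alpha|>1$,
where the naive expansion diverges and the $k$-form is a conditionally
convergent resummation) the alternating sums hit the double-precision
cancellation floor at large truncation.  Moments, incomplete moments,
the mgf and Rényi entropy are instead computed by adaptive quadrature in
the probability domain ($\int_0^1 Q(p)^r dp$ and relatives), which
avoids infinite-support truncation entirely; divergent integrals (mgf
beyond its abscissa, heavy-tailed moments) warn and return `NaN` rather
than failing.

## Monte-Carlo estimator study

`run_study()` reproduces the published bias/RMSE design: `nsimu`
replicates of size `n` drawn by quantile inversion with per-replicate
seeds derived from the design seed, each fitted by ML.  Two documented
readings of the source material are baked in:

* the tabulated error measure scales as $n^{-1/2}$, identifying it as a
  **root**-mean-square error although the displayed formula omits the
  root; `rmse` is $\sqrt{\text{mean}((\hat\theta-\theta)^2)}$;
* `init_at_truth = TRUE` by default: the ridge coordinates only
  reproduce the published tables when the optimizer starts at the truth
  and stays on the ridge near it.  This is disclosed in the report
  (convergence rate included), and the full multi-start machinery is
  available with `init_at_truth = FALSE`.

The preset `"mowe-case2"` reproduces the printed Case II truth verbatim
even though it evidently duplicates Case I by misprint (its published
estimates converge elsewhere); it is provided for completeness and not
used as a reproduction surface.

## Censored regression: the log-MOW-W model

If $X$ is MOW-W with $\gamma = 1/\sigma$ and $\delta = e^{\mu}$, then
$Y = \log X$ has the LMOW-W location-scale density; modeling
$\mu_i = v_i^{\top}\tau$ gives an accelerated-failure-time regression
$y_i = v_i^{\top}\tau + \sigma z_i$ for right-censored log-lifetimes,
fitted by maximizing
$\sum_{F}\log f(y_i) + \sum_{C}\log S(y_i)$ (`censored_loglik()`, with
the expanded algebraic form implemented as a cross-check; the two agree
to $10^{-10}$).  The standardized error density carries no $1/\sigma$
factor — printed versions sometimes keep one, an erratum without
consequence for the likelihood.  With $\alpha = c = \beta = 1$ the model
is exactly the classical log-Weibull AFT, and `fit_lmoww()` with those
parameters pinned agrees with `survival::survreg` to $10^{-4}$ — the
reduction oracle in the tests.

The log transform maps the MOW-W ridge onto the identifiable triple
$(\alpha,\; c/\sigma,\; \tau_0 + \sigma\log\beta)$: $\sigma$ and
$\tau_0$ are *not* separately estimable in the full parameterization
(published fits of this model show correspondingly enormous standard
errors).  The recovery acceptance test therefore pins $(c,\beta)$ at
truth via `fixed =` and recovers $(\alpha,\sigma,\tau_0,\tau_1)$; the
pinned fit attains the same maximized likelihood as the free fit.

### The synthetic cohort

The reference application for this model is an external two-arm
head-and-neck cancer trial whose data are not reprinted and therefore
not bundled; `simulate_censored_cohort()` is the synthetic stand-in.
Its stated world: one binary covariate (arm, Bernoulli(1/2), mimicking
the roughly balanced 51/45 design), lifetimes by LMOW-W inversion at
$\mu_i = \tau_0 + \tau_1 v_i$, and independent censoring times drawn
from the same family with an offset calibrated so the realized censoring
fraction hits the target (exactly, up to $1/n$).  Defaults used in the
acceptance tests — $n = 2000$, 20% censoring, $\alpha = 2$, $c = 1.5$,
$\beta = 1$, $\sigma = 0.8$, $\tau = (3.5, 0.6)$ — follow the
moderate-censoring two-arm setting of that literature; what a green test
establishes is correct likelihood algebra and consistent estimation
under the model, not agreement with the external trial (whose published
AIC is out of desk scope).

## Numerical choices, in one place

* log-parameter search box $|\log\theta| \le 12$; boundary tolerance
  $10^{-4}$; spike cap $\log(10/\delta)$;
* Nelder–Mead `reltol` $10^{-12}$ (study replicates $10^{-10}$),
  BFGS polish `factr` $10^3$;
* quadrature `rel.tol` $10^{-9}$, 500 subdivisions, probability-domain
  integrands;
* numerical Hessians: central differences, relative step $10^{-4}$;
  pseudo-inverse below eigenvalue ratio $10^{-10}$, ill-conditioning
  warning above condition number $10^8$;
* PIT clipping $\varepsilon = 10^{-10}$; KS p-value by the asymptotic
  Kolmogorov series (100 terms);
* series truncation defaults $J=I=R=M=10$, $K=J$;
* per-replicate seeds $(s + 104729\,r) \bmod 2147483629$.

## Known limitations

* Competitor families outside the three generators (and the published
  regression competitors beyond the log-Weibull reduction) are out of
  scope.
* The series representation is numerically fragile for extreme tilts;
  use the direct density.
* KS p-values ignore parameter estimation (no Lilliefors-type
  correction), as in the source tables.
* Hazard-shape taxonomy is illustrated in documentation, not asserted
  by tests.
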