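# mowg — the Marshall–Olkin Weibull generated family of distributions

`mowg` implements a flexible family of lifetime distributions obtained by
composing two classical generators: the Marshall–Olkin tilt

    F_MO(x) = G(x) / (α + (1 − α) G(x)),          α > 0,

and the Weibull-G transform of the baseline cumulative hazard
H(x) = −log(1 − G(x)),

    F_WG(x) = 1 − exp[ −(H(x)/β)^c ],             c, β > 0.

Their composition, the MOW-G family,

    F(x; α, c, β, τ) = (1 − e^{−(H(x)/β)^c}) / (1 − (1−α) e^{−(H(x)/β)^c}),

accommodates symmetric, skewed, J- and reversed-J densities and
increasing / decreasing / bathtub / upside-down-bathtub hazards, which
makes it useful for survival analysis, industrial reliability and
epidemic-mortality data.  The exponential and Weibull baselines give the
four-parameter MOW-E and five-parameter MOW-W members.

The package is aimed at biostatisticians and reliability analysts who
need to *fit and compare* such models, not just evaluate them:

* **Distribution toolkit** — `mowg_dist()`, `dmowg()`/`pmowg()`/
  `qmowg()`/`rmowg()`, hazard, median; any baseline satisfying a small
  contract plugs in (`baseline_model()`); all tail arithmetic in log
  space; sampling by seeded inversion (bit-reproducible).
* **Sub-model registry** — `make_model()` with keys `mow-e`, `mow-w`,
  `mo-e`, `mo-w`, `weibull-e`, `weibull-w`, `exp-e`, `exp-w`, plus the
  identifiable reduced parameterizations `mow-e-reduced`,
  `mow-w-reduced`.
* **Mathematical properties** — exponentiated-G series machinery
  (`ptm()`, `series_pdf()`) as a cross-check oracle; quadrature-based
  moments, incomplete moments, mgf, Rényi/Shannon entropy,
  order-statistic densities.
* **Inference** — `fit_mle()`: multi-start maximum likelihood on log
  parameters with screens against the family's two degenerate likelihood
  modes (tilt collapse to a log-logistic limit, tie-induced density
  spikes); observed-information standard errors with ridge diagnostics;
  full criterion panel (AIC, CAIC, BIC, Cramér–von Mises W\*,
  Anderson–Darling A\*, Kolmogorov–Smirnov with asymptotic p-value);
  `compare_models()` ranking tables.
* **Monte-Carlo estimator studies** — `run_study()`/`sim_preset()`
  bias/RMSE tables for the MOW-E and MOW-W designs.
* **Censored AFT regression** — the log-MOW-W location-scale model for
  right-censored log-lifetimes: `fit_lmoww()`, `censored_loglik()`,
  and a synthetic two-arm cohort generator
  `simulate_censored_cohort()`.
* **Data & CLI** — four classical samples (`load_dataset()`:
  `covid_canada`, `aircon_failures`, `carbon_fibers`, `glass_fibers`),
  CSV readers, and a command-line interface (`cli_main()`; script in
  `inst/cli/mowg`) with `fit`, `compare`, `simulate`, `regress`,
  `datasets` subcommands.

## Worked example

```r
library(mowg)
x <- load_dataset("covid_canada")      # 36 daily mortality rates
fit <- fit_mle(x, "mow-e", seed = 1)
print(fit)
```

```
Model mow-e fitted to x (n = 36)
            alpha       c      beta   lambda
estimate 0.005561 6.34920   0.72476  0.10096
se       0.019663 0.95134 138.12000 19.24100
-loglik 47.0442  AIC 102.0883  CAIC 105.2554  BIC 108.4224
W* 0.0514  A* 0.3358  KS 0.1003 (p = 0.862)
```

The tilt α̂ ≈ 0.006 sharpens the upper tail relative to a plain
Weibull-exponential; the KS distance 0.100 with p = 0.86 indicates no
evidence against the fitted cdf.  The huge SEs on (β, λ) are the
expected signature of the model's scale ridge — only λ/β is
identifiable, and `fit_mle` warns accordingly (`fit$se_note`).

```r
compare_models(x, c("mow-e", "mo-w", "weibull-e"), seed = 1)
```

```
      model negloglik     aic    caic     bic     cvm_w     ad_a       ks ks_pvalue
1      mo-w   47.0442 100.088 102.464 104.839 0.0514213 0.335787 0.100290  0.861971
2     mow-e   47.0442 102.088 105.255 108.422 0.0514214 0.335787 0.100290  0.861973
3 weibull-e   51.4743 108.949 111.324 113.699 0.2006350 1.168060 0.149974  0.392945
```

MO-W and MOW-E reach the same maximized likelihood — they are the same
identifiable three-parameter law in different clothes (see the vignette)
— so the three-parameter version wins on AIC.  The untilted Weibull-G
fit is 4.4 log-likelihood units worse: the tilt is doing real work on
this sample.

```r
r <- run_study(sim_preset("mowe-case1", n = 500, nsimu = 200, seed = 1))
print(r)
```

```
Simulation study: mow-e, n = 500, nsimu = 200 (converged 100.0%)
            alpha       c     beta lambda
truth    0.050000 3.00000 0.200000 0.7000
mean MLE 0.057740 3.00200 0.203500 0.7249
|bias|   0.007745 0.00167 0.003472 0.0249
RMSE     0.028510 0.12700 0.026120 0.1233
```

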