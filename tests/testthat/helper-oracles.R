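# shared fixtures: a fixed parameter sweep and small numeric oracles

# deterministic (alpha, c, beta) sweep spanning both tilt regimes
sweep_params <- expand.grid(alpha = c(0.05, 0.5, 1, 2, 5),
                            c = c(0.5, 1, 2.5),
                            beta = c(0.5, 2))

sweep_baselines <- function() list(exp = baseline_exponential(1.3),
                                   wei = baseline_weibull(1.7, 0.8))

# adaptive-quadrature normalization of a density over (0, Inf)
quad_norm <- function(dens) {
  stats::integrate(dens, 0, Inf, rel.tol = 1e-9, subdivisions = 500L)$value
}

rel_err <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.eps)

# central finite difference
fd <- function(f, x, h = 1e-5) (f(x + h) - f(x - h)) / (2 * h)
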