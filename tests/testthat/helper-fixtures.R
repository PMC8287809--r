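# shared small fixtures and independent oracles

kB <- 1.380649e-23

# naive textbook evaluation of the cantilever mode shape, used as the
# independent oracle for the package's numerically stable evaluation
naive_mode_shape <- function(q, u) {
  (-cosh(q) - cos(q)) / (sin(q) + sinh(q)) * (sin(q * u) - sinh(q * u)) +
    cos(q * u) - cosh(q * u)
}

# bisection root of cos(q)cosh(q) + 1 = 0 in (lo, hi), independent of
# the package's uniroot-based solver
bisect_eigenvalue <- function(lo, hi, tol = 1e-10) {
  f <- function(q) cos(q) * cosh(q) + 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# small simulated ensemble used by several estimator tests
tiny_ensemble <- function(seed = 42, n_frames = 60, ...) {
  simulate_ensemble(sim_config(n_frames = n_frames, seed = seed, ...))
}

# fitted growth rates for seven ordered groups emulating a
# plateau / rising / plateau concentration series
three_regime_rates <- function(seed, means = c(1.3, 1.3, 4, 7, 10.1, 16, 16),
                               n_traces = 20) {
  rates <- lapply(seq_along(means), function(i) {
    tr <- generate_growth_traces(means[i], noise_sd = 0.05, duration = 60,
                                 dt = 2, n_traces = n_traces,
                                 seed = seed * 101 + i)
    vapply(tr, function(x) fit_growth_rate(x)$rate, numeric(1))
  })
  names(rates) <- paste0("c", seq_along(means))
  rates
}
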