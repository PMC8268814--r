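# Independent oracles used across the suite.  Each is deliberately naive
# (plain bisection, exhaustive grids) so it shares no code path with the
# implementation it checks.

# Plain bisection for the mass balance s + n K s^n = s_total on [0, s_total].
# Only valid where n K s_total^n does not overflow.
bisect_monomer <- function(s_total, n, K, iter = 200L) {
  if (s_total == 0) return(0)
  f <- function(s) s + n * K * s^n - s_total
  lo <- 0
  hi <- s_total
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Exhaustive dense-grid search for the continuous segmented fit: evaluates
# the fixed-breakpoint least-squares model on a fine psi grid.
grid_breakpoint <- function(conc, gamma, n_grid = 4000L) {
  t <- log(conc)
  psis <- seq(t[2L], t[length(t) - 1L], length.out = n_grid)
  rss <- vapply(psis, function(psi) {
    X <- cbind(1, t, pmax(t - psi, 0))
    sum(qr.resid(qr(X), gamma)^2)
  }, numeric(1))
  i <- which.min(rss)
  list(psi = psis[i], rss = rss[i])
}

# Closed-form OLS slope, for checking heat_capacity_demic.
ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Numeric grid + local refinement for the inflection cmc criterion: locates
# the extremum of the second derivative d2[S]/dStot2 by finite differences
# of the solver output on a log-spaced s_total grid.
grid_cmc <- function(params, span = c(1e-4, 1e4), n_grid = 2001L) {
  anchor <- exp(-log(params$K) / params$n)   # rough scale of the transition
  lg <- seq(log(anchor * span[1L]), log(anchor * span[2L]),
            length.out = n_grid)
  ct <- exp(lg)
  s <- monomer_concentration(ct, params)
  d1 <- diff(s) / diff(ct)
  cm <- (ct[-1L] + ct[-length(ct)]) / 2
  d2 <- diff(d1) / diff(cm)
  c2 <- (cm[-1L] + cm[-length(cm)]) / 2
  i <- which.max(abs(d2))
  f <- function(lc) {
    h <- 1e-3 * exp(lc)
    cs <- exp(lc) + c(-h, 0, h)
    ss <- monomer_concentration(cs, params)
    (ss[3L] - 2 * ss[2L] + ss[1L]) / h^2
  }
  o <- stats::optimize(function(lc) -abs(f(lc)),
                       log(c2[max(1, i - 2)]) + c(-0.1, 0.1) * 3,
                       tol = 1e-10)
  exp(o$minimum)
}

make_clean_series <- function(n = 10, cmc = 0.45, dH_demic = -5,
                              dH_dil = -0.2, schedule = default_itc_schedule()) {
  truth <- synthetic_truth(n = n, cmc = cmc, dH_demic = dH_demic,
                           dH_dil = dH_dil, noise_sd = 0)
  gen_itc_experiment(truth, schedule)
}
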