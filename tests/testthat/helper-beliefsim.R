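# Shared fixtures and property-check helpers (everything generated in code).

# heavyweight simulation batches reused by several test blocks
.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache))
    assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

tiny_params <- function(...) {
  model_params(n_agents = 10L, n_steps = 100L, snapshot_every = 20L,
               seed = 42L, ...)
}

# population sitting exactly on corner states consistent with k0
corner_population <- function(n, k0) {
  half <- n %/% 2
  if (k0 == -1) {
    population(a1 = c(rep(1, half), rep(-1, n - half)),
               a2 = c(rep(-1, half), rep(1, n - half)))
  } else {
    population(a1 = c(rep(1, half), rep(-1, n - half)),
               a2 = c(rep(1, half), rep(-1, n - half)))
  }
}

# exact one-step outcome distribution for a single agent at (a1, a2) with
# fixed rho and noise magnitude za: per attitude, three outcomes
# (unchanged; updated with +za; updated with -za) with probabilities
# (1-p_gate, p_gate/2, p_gate/2). Independent across the two attitudes.
enumerate_onestep <- function(a1, a2, k0, rho, za) {
  cc <- a1 * a2 * k0
  one <- function(a) {
    p <- 1 - abs(a)
    up <- function(z) min(1, max(-1, sign(a) * (abs(a) + rho * cc) + z))
    data.frame(value = c(a, up(za), up(-za)),
               prob = c(1 - p, p / 2, p / 2))
  }
  list(a1 = one(a1), a2 = one(a2))
}

# classify observed values against an enumerated outcome set
match_outcome <- function(x, values) {
  vapply(x, function(v) which.min(abs(values - v)), integer(1))
}

# mean extremity-ratio time series (a1 and a2 averaged) over replicate
# seeds, at one epsilon
mean_extremity_series <- function(params, n_seeds, eps) {
  runs <- run_replicates(params, n_seeds)
  series <- vapply(runs, function(tr) {
    m <- tr$metrics[tr$metrics$eps == eps, ]
    (m$extremity_a1 + m$extremity_a2) / 2
  }, numeric(length(runs[[1]]$times)))
  list(times = runs[[1]]$times, mean = rowMeans(series), runs = runs)
}
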