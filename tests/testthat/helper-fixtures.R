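# Shared fixtures: random-but-valid twitch parameters, small pools, and the
# naive summation oracle used to cross-check the windowed engine.

# reference parameter set used throughout (an S-like twitch)
ref_params <- function() twitch_params(2, 10, 20, 35, 80, 1)

# one random valid parameter set; t_hc/t_c kept in [0.2, 0.85] so the rising
# exponent stays inside the solver bracket
random_twitch_params <- function() {
  t_c <- runif(1, 8, 40)
  t_hc <- runif(1, 0.2, 0.85) * t_c
  t_hr <- t_c * runif(1, 1.1, 2.5)
  t_tot <- t_hr * runif(1, 1.3, 4)
  twitch_params(runif(1, 0, 5), t_hc, t_c, t_hr, t_tot,
                exp(runif(1, -1, 3)))
}

# naive O(k * G) reference summation: full outer evaluation over every
# (grid point, stimulus) pair, independent of the engine's windowing
naive_simulate_mu <- function(fn, train, duration, dt = 0.1) {
  times <- seq(0, duration + dt / 2, by = dt)
  if (!length(train)) return(numeric(length(times)))
  keep <- train <= duration
  train <- train[keep]
  if (!length(train)) return(numeric(length(times)))
  rowSums(outer(times, train, function(tg, s) twitch_force(fn, tg - s)))
}

# closed-form oracles for the 6-parameter shape coefficients
oracle_m <- function(t_hc, t_c) {
  r <- t_hc / t_c
  log(0.5) / (log(r) + 1 - r)
}
oracle_bc <- function(t_c, t_hr, t_tot, epsilon = 0.01) {
  b <- log(log(1 / epsilon) / log(2)) / log((t_tot - t_c) / (t_hr - t_c))
  c(b = b, c = log(2) / (t_hr - t_c)^b)
}

small_pool <- function(seed = 7) generate_pool(2, 2, 2, seed = seed)

# relative error helper tolerant of exact zeros
rel_err <- function(got, want) abs(got - want) / pmax(abs(want), 1e-12)
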