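test_that("windowed summation matches the naive double-loop oracle", {
  set.seed(202)
  for (k in 1:30) {
    p <- random_twitch_params()
    fn <- suppressWarnings(twitch_6p(p))
    n_stim <- sample(0:20, 1)
    train <- sort(runif(n_stim, 0, 150))
    if (length(train) > 1) train <- train[c(TRUE, diff(train) > 1e-6)]
    duration <- runif(1, 50, 200)
    got <- simulate_mu(fn, train, duration, dt = 0.1)
    want <- naive_simulate_mu(fn, train, duration, dt = 0.1)
    expect_equal(got, want, tolerance = 1e-9)
  }
  # same check for the two-parameter model's infinite tail
  fn2 <- twitch_2p(1.3, 15, 2)
  train <- c(0, 7, 30)
  expect_equal(simulate_mu(fn2, train, 120, 0.1),
               naive_simulate_mu(fn2, train, 120, 0.1), tolerance = 1e-9)
})

test_that("a single stimulus reproduces the sampled twitch", {
  fn <- twitch_6p(ref_params())
  tt <- seq(0, 100 + 0.05, by = 0.1)
  expect_equal(simulate_mu(fn, 0, 100, 0.1), twitch_force(fn, tt))
  pk <- peak_force(simulate_mu(fn, 0, 100, 0.1), tt)
  expect_equal(pk$value, 1)
  expect_equal(pk$time, 22)
})

test_that("non-overlapping stimuli do not summate", {
  fn <- twitch_6p(ref_params())  # support ends at t_lead + t_tot = 82 ms
  s <- simulate_mu(fn, c(0, 100), 250, 0.1)
  expect_equal(max(s), 1, tolerance = 1e-9)
})

test_that("total force is conserved across MUs and groups", {
  pool <- small_pool()
  stim <- make_irregular_asynchronous(pool, tc_scaled_mean_ipis(pool), 20,
                                      seed = 9)
  tr <- simulate_muscle(pool, stim)
  expect_equal(tr$total, rowSums(tr$per_mu), tolerance = 1e-9)
  expect_equal(tr$total, tr$group_S + tr$group_FR + tr$group_FF,
               tolerance = 1e-9)
  for (ty in c("S", "FR", "FF"))
    expect_equal(tr[[paste0("group_", ty)]],
                 rowSums(tr$per_mu[, pool$mu_type == ty, drop = FALSE]),
                 tolerance = 1e-9)
  expect_true(all(tr$total >= 0))
})

test_that("scaling every f_max scales every output series linearly", {
  pool <- small_pool()
  alpha <- 2.5
  scaled <- pool
  scaled$f_max <- alpha * scaled$f_max
  stim <- make_synchronous(nrow(pool), regular_train(0, 25, 10))
  cfg <- sim_config(duration = 400)
  tr1 <- simulate_muscle(pool, stim, cfg)
  tr2 <- simulate_muscle(scaled, stim, cfg)
  expect_equal(tr2$total, alpha * tr1$total, tolerance = 1e-9)
  expect_equal(tr2$per_mu, alpha * tr1$per_mu, tolerance = 1e-9)
})

test_that("degenerate inputs reduce sensibly", {
  pool <- small_pool()
  # empty stimulation -> all-zero trace
  tr <- simulate_muscle(pool, make_synchronous(nrow(pool), numeric(0)),
                        sim_config(duration = 100))
  expect_true(all(tr$total == 0))
  # one-MU pool -> total equals the single-MU simulation
  p1 <- generate_pool(1, 0, 0, seed = 2)
  stim1 <- stimulation_set(list(regular_train(0, 30, 5)))
  tr1 <- simulate_muscle(p1, stim1, sim_config(duration = 300))
  fn1 <- mupsim:::pool_twitch_fn(p1, 1)
  expect_equal(tr1$total, simulate_mu(fn1, stim1$trains[[1]], 300, 0.1))
  # mismatched sizes are an error
  expect_error(simulate_muscle(pool, stim1), class = "mupsim_error_counts")
})

test_that("peak force reports the earliest maximum", {
  expect_equal(peak_force(c(0, 0, 0)), list(value = 0, time = 1))
  expect_equal(peak_force(c(0, 2, 2, 1), times = c(0, 10, 20, 30)),
               list(value = 2, time = 10))
  expect_error(peak_force(numeric(0)), class = "mupsim_error_empty")
})

test_that("superposition bounds hold: n stimuli never exceed n twitch peaks", {
  fn <- twitch_6p(ref_params())
  for (n_stim in c(2, 5, 10)) {
    s <- simulate_mu(fn, regular_train(0, 1, n_stim), 200, 0.1)
    expect_lte(max(s), n_stim * 1 + 1e-9)
    expect_gte(max(s), 1)
  }
  # IPI -> 0 approaches equality
  s <- simulate_mu(fn, regular_train(0, 0.01, 5), 200, 0.1)
  expect_equal(max(s), 5, tolerance = 0.01)
})

test_that("peak tetanic force is non-decreasing in stimulation rate", {
  fn <- suppressWarnings(twitch_6p(twitch_params(2, 12, 24, 45, 120, 1.7)))
  freqs <- c(1, 10, 12.5, 16.6, 20, 25, 30, 33.3, 40, 50, 60, 75, 100)
  peaks <- vapply(freqs, function(f)
    mupsim:::regular_peak(fn, f, 50, 0.1), numeric(1))
  # slack covers grid-phase sampling of the smooth peak at dt = 0.1
  expect_true(all(diff(peaks) >= -2e-4 * peaks[1]))
  # low-rate limit: IPI beyond the twitch duration leaves the twitch peak
  expect_equal(peaks[1], 1.7, tolerance = 1e-6)
})

test_that("force CSVs carry every series in both layouts", {
  pool <- small_pool()
  stim <- make_synchronous(nrow(pool), regular_train(0, 20, 5))
  tr <- simulate_muscle(pool, stim, sim_config(duration = 200))
  wide_path <- withr::local_tempfile(fileext = ".csv")
  long_path <- withr::local_tempfile(fileext = ".csv")
  write_force_csv(tr, wide_path, "wide")
  write_force_csv(tr, long_path, "long")
  wide <- read.csv(wide_path)
  expect_named(wide, c("time_ms", paste0("mu_", 1:6),
                       "group_S", "group_FR", "group_FF", "total"))
  expect_equal(wide$total, tr$total, tolerance = 1e-9)
  long <- read.csv(long_path)
  expect_named(long, c("time_ms", "series_id", "force"))
  expect_equal(nrow(long), nrow(wide) * 10)
  expect_equal(long$force[long$series_id == "total"], tr$total,
               tolerance = 1e-9)
})
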