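test_that("regular trains are arithmetic sequences", {
  expect_equal(regular_train(0, 20, 3), c(0, 20, 40))
  tr <- regular_train(0, 20, 50)
  expect_length(tr, 50)
  expect_equal(tr[50], 980)
  expect_length(regular_train(0, 20, 0), 0)
  expect_error(regular_train(-1, 20, 3), class = "mupsim_error_train")
  expect_error(regular_train(0, 0, 3), class = "mupsim_error_train")
})

test_that("irregular trains respect the variability bounds and the seed", {
  tr <- irregular_train(0, 16.6, 50, seed = 1)
  ipis <- diff(tr)
  expect_true(all(ipis >= 0.5 * 16.6 & ipis <= 1.5 * 16.6))
  expect_identical(tr, irregular_train(0, 16.6, 50, seed = 1))
  # degenerate bounds reduce to the regular train
  expect_equal(irregular_train(0, 20, 10, variability = c(1, 1), seed = 1),
               regular_train(0, 20, 10))
  expect_error(irregular_train(0, 20, 10, variability = c(1.5, 0.5)),
               class = "mupsim_error_variability")
})

test_that("sampled interpulse intervals average to the requested mean", {
  # law of large numbers on Uniform(0.5, 1.5) * mean
  tr <- irregular_train(0, 20, 1e5 + 1, seed = 99)
  expect_equal(mean(diff(tr)), 20, tolerance = 0.005)
})

test_that("synchronous sets copy one train to every MU", {
  tr <- regular_train(0, 1000 / 60, 50)
  stim <- make_synchronous(30, tr)
  expect_length(stim, 30)
  expect_true(all(vapply(stim$trains, identical, logical(1), tr)))
  expect_length(make_synchronous(1, tr), 1)
  empty <- make_synchronous(3, numeric(0))
  expect_true(all(lengths(empty$trains) == 0))
})

test_that("regular-asynchronous sets shift first spikes within [0, max_shift]", {
  stim <- make_regular_asynchronous(30, 16.6, 50, max_shift = 40, seed = 7)
  first <- vapply(stim$trains, `[`, numeric(1), 1)
  expect_true(all(first >= 0 & first <= 40))
  expect_gt(stats::sd(first), 0)
  # regularity preserved within each MU
  for (tr in stim$trains)
    expect_equal(diff(tr), rep(16.6, 49))
  # zero shift degenerates to the synchronous set
  s0 <- make_regular_asynchronous(5, 16.6, 10, max_shift = 0, seed = 1)
  expect_equal(s0$trains, make_synchronous(5, regular_train(0, 16.6, 10))$trains)
})

test_that("irregular-asynchronous sets draw one train per MU from its own mean", {
  pool <- small_pool()
  means <- seq(10, 100, length.out = nrow(pool))
  stim <- make_irregular_asynchronous(pool, means, 30, seed = 5)
  expect_length(stim, nrow(pool))
  expect_gt(length(unique(vapply(stim$trains, paste, character(1),
                                 collapse = ","))), 1)
  for (i in seq_along(means)) {
    ipis <- diff(stim$trains[[i]])
    expect_true(all(ipis >= 0.5 * means[i] & ipis <= 1.5 * means[i]))
  }
  expect_identical(stim$trains,
                   make_irregular_asynchronous(pool, means, 30, seed = 5)$trains)
  expect_error(make_irregular_asynchronous(pool, means[-1], 30),
               class = "mupsim_error_counts")
})

test_that("contraction-time-scaled mean IPIs follow the 1.25 rule", {
  pool <- small_pool()
  expect_equal(tc_scaled_mean_ipis(pool), 1.25 * pool$t_c)
  expect_equal(tc_scaled_mean_ipis(pool, factor = 1), pool$t_c)
  # rate for T_c = 20 ms is 40 Hz; for T_c = 33.06 ms it is ~24.2 Hz
  expect_equal(1000 / (1.25 * 20), 40)
  expect_equal(1000 / (1.25 * 33.06), 24.2, tolerance = 1e-3)
})

test_that("size-principle schedules recruit weak-first and derecruit strong-first", {
  pool <- generate_pool(3, 3, 3, seed = 21)
  n <- nrow(pool)
  delays <- (seq_len(n) - 1) * 100
  targets <- 5000 - (seq_len(n) - 1) * 100
  stim <- size_principle_schedule(pool, delays, targets,
                                  tc_scaled_mean_ipis(pool), seed = 3)
  onset <- vapply(stim$trains, `[`, numeric(1), 1)
  last <- vapply(stim$trains, function(t) t[length(t)], numeric(1))
  r <- rank(pool$f_max, ties.method = "first")
  expect_true(all(diff(onset[order(r)]) > 0))
  expect_true(all(diff(last[order(r)]) < 0))
  expect_true(all(last <= targets[r]))
  # the next interval would overshoot the target for every MU
  for (i in seq_len(n)) {
    lo <- 0.5 * 1.25 * pool$t_c[i]
    expect_gt(last[i] + 1.5 * 1.25 * pool$t_c[i], targets[r[i]] - lo)
  }
  expect_error(size_principle_schedule(pool, rev(delays), targets,
                                       tc_scaled_mean_ipis(pool)),
               class = "mupsim_error_schedule")
  expect_error(size_principle_schedule(pool, delays, rev(targets),
                                       tc_scaled_mean_ipis(pool)),
               class = "mupsim_error_schedule")
  # strictly decreasing targets that undercut the late delays
  expect_error(size_principle_schedule(pool, delays, rev(delays) + 1,
                                       tc_scaled_mean_ipis(pool)),
               class = "mupsim_error_schedule")
})

test_that("impulse files round-trip in both variants", {
  path <- withr::local_tempfile(fileext = ".txt")
  # delay+IPI column [5; 20; 20] decodes to times 5, 25, 45
  writeLines(c("5", "20", "20"), path)
  expect_equal(read_impulses(path, "delay_ipi")$trains[[1]], c(5, 25, 45))

  set.seed(42)
  trains <- lapply(1:6, function(i)
    irregular_train(runif(1, 0, 30), runif(1, 10, 40), sample(0:25, 1)))
  stim <- stimulation_set(trains)
  for (fmt in c("times", "delay_ipi")) {
    write_impulses(stim, path, fmt)
    back <- read_impulses(path, fmt)
    expect_equal(back$trains, stim$trains, tolerance = 1e-8)
  }
})

test_that("padding sentinels terminate shorter trains", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 5", "20 25", "40 -1"), path)
  got <- read_impulses(path, "times")
  expect_equal(got$trains, list(c(0, 20, 40), c(5, 25)))
  writeLines(c("0 5", "20 10", "-1 -1"), path)
  got <- read_impulses(path, "delay_ipi")
  expect_equal(got$trains, list(c(0, 20), c(5, 15)))
})

test_that("invalid trains and missing files are rejected", {
  expect_error(stimulation_set(list(c(3, 2, 1))), class = "mupsim_error_train")
  expect_error(stimulation_set(list(c(-1, 2))), class = "mupsim_error_train")
  expect_error(read_impulses(file.path(tempdir(), "nope.txt")),
               class = "mupsim_error_io")
})
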