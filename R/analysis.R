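fig3_frequencies <- c(1, 10, 12.5, 16.6, 20, 25, 30, 33.3, 40, 50, 60, 75, 100)

# peak force of a regular train at rate f (Hz) for one twitch function,
# grid auto-sized to cover the full response
regular_peak <- function(fn, f_hz, n_stimuli, dt) {
  ipi <- 1000 / f_hz
  train <- regular_train(0, ipi, n_stimuli)
  supp <- twitch_support(fn)
  tail_ms <- if (is.finite(supp[2])) supp[2] else supp[1] + 1000
  duration <- train[length(train)] + tail_ms + dt
  max(simulate_mu(fn, train, duration, dt))
}

#' Force-frequency curve
#'
#' For each frequency `f`, a regular synchronous train of `n_stimuli` pulses
#' at interval `1000/f` ms is simulated and the peak tetanic force recorded;
#' peaks are normalized by the 1 Hz peak (at 1 Hz successive responses do not
#' summate, so the reference is the peak twitch force of that MU or group).
#' Applied to a pool, the curve is computed for every MU and for the S, FR and
#' FF group sums and the whole-muscle sum.
#'
#' @param x A twitch function (`"twitch_fn"`) or a [mu_pool()].
#' @param frequencies Stimulation rates, Hz; must include the 1 Hz normalizer
#'   (or supply `reference`). The default grid spans 1-100 Hz.
#' @param n_stimuli Pulses per train (default 50).
#' @param dt Grid step, ms.
#' @param reference Optional explicit normalizing peak (per series) replacing
#'   the 1 Hz peak.
#' @param ... Unused.
#' @return An object of class `c("force_frequency_curve", "data.frame")` with
#'   columns `frequency_hz`, `series_id`, `peak`, `normalized_peak`.
#' @examples
#' fn <- twitch_6p(twitch_params(2, 10, 20, 35, 80, 1))
#' force_frequency_curve(fn, frequencies = c(1, 10, 40, 100), n_stimuli = 10)
#' @export
force_frequency_curve <- function(x, frequencies = fig3_frequencies,
                                  n_stimuli = 50, dt = 0.1,
                                  reference = NULL, ...) {
  UseMethod("force_frequency_curve")
}

#' @export
force_frequency_curve.twitch_fn <- function(x, frequencies = fig3_frequencies,
                                            n_stimuli = 50, dt = 0.1,
                                            reference = NULL, ...) {
  peaks <- vapply(frequencies, function(f)
    regular_peak(x, f, n_stimuli, dt), numeric(1))
  ref <- reference %||% {
    if (!any(frequencies == 1))
      stop_invalid("frequencies must include the 1 Hz normalizer (or supply reference)",
                   "mupsim_error_reference")
    peaks[match(1, frequencies)]
  }
  out <- data.frame(frequency_hz = frequencies, series_id = "mu_1",
                    peak = peaks, normalized_peak = peaks / ref)
  class(out) <- c("force_frequency_curve", "data.frame")
  out
}

#' @export
force_frequency_curve.mu_pool <- function(x, frequencies = fig3_frequencies,
                                          n_stimuli = 50, dt = 0.1,
                                          reference = NULL, ...) {
  if (!any(frequencies == 1) && is.null(reference))
    stop_invalid("frequencies must include the 1 Hz normalizer (or supply reference)",
                 "mupsim_error_reference")
  n <- nrow(x)
  fns <- lapply(seq_len(n), pool_twitch_fn, pool = x)
  rows <- list()
  for (f in frequencies) {
    ipi <- 1000 / f
    train <- regular_train(0, ipi, n_stimuli)
    duration <- train[length(train)] + max(x$t_lead + x$t_tot) + dt
    g <- length(time_grid(duration, dt))
    groups <- list(S = numeric(g), FR = numeric(g), FF = numeric(g))
    mu_peaks <- numeric(n)
    for (i in seq_len(n)) {
      s <- simulate_mu(fns[[i]], train, duration, dt)
      mu_peaks[i] <- max(s)
      groups[[x$mu_type[i]]] <- groups[[x$mu_type[i]]] + s
    }
    rows[[length(rows) + 1L]] <- data.frame(
      frequency_hz = f,
      series_id = c(paste0("mu_", seq_len(n)),
                    "group_S", "group_FR", "group_FF", "total"),
      peak = c(mu_peaks, max(groups$S), max(groups$FR), max(groups$FF),
               max(groups$S + groups$FR + groups$FF)))
  }
  out <- do.call(rbind, rows)
  ref_tab <- if (is.null(reference)) {
    r <- out[out$frequency_hz == 1, c("series_id", "peak")]
    stats::setNames(r$peak, r$series_id)
  } else reference
  out$normalized_peak <- out$peak / ref_tab[out$series_id]
  rownames(out) <- NULL
  class(out) <- c("force_frequency_curve", "data.frame")
  out
}

#' @export
plot.force_frequency_curve <- function(x, series = NULL, ...) {
  ids <- series %||% unique(x$series_id)
  cols <- grDevices::hcl.colors(length(ids), "Dark 3")
  first <- TRUE
  for (k in seq_along(ids)) {
    d <- x[x$series_id == ids[k], ]
    d <- d[order(d$frequency_hz), ]
    if (first) {
      graphics::plot(d$frequency_hz, d$normalized_peak, type = "b",
                     col = cols[k], xlab = "frequency (Hz)",
                     ylab = "normalized peak force",
                     ylim = range(x$normalized_peak), ...)
      first <- FALSE
    } else graphics::lines(d$frequency_hz, d$normalized_peak, type = "b",
                           col = cols[k])
  }
  invisible(x)
}

#' Tetanic gain between two stimulation rates
#'
#' Ratio of the peak tetanic force at a high rate to the peak at a low rate
#' (default 100 Hz vs 10 Hz, i.e. interpulse intervals 10 ms vs 100 ms) under
#' regular synchronous stimulation, computed per MU, per type group and for
#' the whole muscle. Slow units, whose relaxation is long relative to their
#' contraction time, summate far more effectively and show much larger gains
#' than fast units.
#'
#' @param pool A [mu_pool()].
#' @param f_low,f_high Rates in Hz (`f_high > f_low`).
#' @param n_stimuli Pulses per train (default 50).
#' @param dt Grid step, ms.
#' @return List with `per_mu` (data frame: `mu`, `mu_type`, `gain`), `groups`
#'   (named numeric: S, FR, FF) and `total` (scalar).
#' @export
tetanic_gain <- function(pool, f_low = 10, f_high = 100, n_stimuli = 50,
                         dt = 0.1) {
  stopifnot(inherits(pool, "mu_pool"), f_high > f_low)
  peaks_at <- function(f) {
    ipi <- 1000 / f
    train <- regular_train(0, ipi, n_stimuli)
    duration <- train[length(train)] + max(pool$t_lead + pool$t_tot) + dt
    g <- length(time_grid(duration, dt))
    groups <- list(S = numeric(g), FR = numeric(g), FF = numeric(g))
    mu_peaks <- numeric(nrow(pool))
    for (i in seq_len(nrow(pool))) {
      s <- simulate_mu(pool_twitch_fn(pool, i), train, duration, dt)
      mu_peaks[i] <- max(s)
      groups[[pool$mu_type[i]]] <- groups[[pool$mu_type[i]]] + s
    }
    list(mu = mu_peaks,
         groups = c(S = max(groups$S), FR = max(groups$FR),
                    FF = max(groups$FF)),
         total = max(groups$S + groups$FR + groups$FF))
  }
  lo <- peaks_at(f_low)
  hi <- peaks_at(f_high)
  if (any(lo$mu == 0) || lo$total == 0)
    stop_invalid("zero peak force at the low frequency", "mupsim_error_zero")
  present <- names(lo$groups)[lo$groups > 0]
  list(per_mu = data.frame(mu = seq_len(nrow(pool)), mu_type = pool$mu_type,
                           gain = hi$mu / lo$mu),
       groups = (hi$groups / lo$groups)[present],
       total = hi$total / lo$total)
}

#' Tetanic fusion index
#'
#' Flatness of the tetanic plateau: over a steady-state window, the index is
#' \eqn{1 - (\max - \min)/\max}. A fully fused (flat) tetanus scores 1;
#' widely separated twitches, whose force returns to zero between stimuli,
#' score 0. The window is the last `steady_window_fraction` of the active
#' period, which runs from force onset to `active_end` (pass the last
#' stimulus time to exclude the final relaxation; by default the end of force
#' support is used).
#'
#' @param series Numeric force series on a grid.
#' @param times Matching time grid, ms (defaults to the sample index).
#' @param active_end Optional end of the active period, ms (e.g. the last
#'   stimulus time).
#' @param steady_window_fraction Fraction of the active period used, from its
#'   end (default 0.3).
#' @return Fusion index in `[0, 1]`.
#' @export
fusion_index <- function(series, times = NULL, active_end = NULL,
                         steady_window_fraction = 0.3) {
  if (is.null(times)) times <- seq_along(series)
  stopifnot(length(series) == length(times),
            steady_window_fraction > 0, steady_window_fraction <= 1)
  act <- which(series > 0)
  if (!length(act))
    stop_invalid("series has no positive force; fusion undefined",
                 "mupsim_error_empty")
  t0 <- times[act[1]]
  t1 <- if (is.null(active_end)) times[act[length(act)]] else active_end
  w0 <- t1 - steady_window_fraction * (t1 - t0)
  win <- series[times >= w0 & times <= t1]
  if (length(win) < 2L)
    stop_invalid("steady window contains fewer than 2 samples",
                 "mupsim_error_empty")
  1 - (max(win) - min(win)) / max(win)
}

#' Compare synchronous and asynchronous regular stimulation
#'
#' Simulates the pool under a regular synchronous train and under
#' regular-asynchronous stimulation (same interpulse interval, first spikes
#' shifted uniformly on `[0, max_shift]`) for each seed, and compares peak
#' total forces. Desynchronising the pool spreads the individual twitch peaks
#' in time, so the asynchronous peak cannot exceed the synchronous one.
#'
#' @param pool A [mu_pool()].
#' @param ipi Interpulse interval, ms (default 16.6 ms, i.e. 60 Hz).
#' @param n_stimuli Pulses per MU (default 50).
#' @param max_shift Maximum first-spike shift, ms (default 40).
#' @param seeds Integer vector of seeds, one asynchronous realisation each.
#' @param dt Grid step, ms.
#' @return List with `sync_peak`, `async_peaks` (one per seed) and
#'   `frac_async_le_sync`, the fraction of seeds with asynchronous peak not
#'   exceeding the synchronous peak.
#' @export
compare_sync_async <- function(pool, ipi = 16.6, n_stimuli = 50,
                               max_shift = 40, seeds = 1:10, dt = 0.1) {
  stopifnot(inherits(pool, "mu_pool"))
  n <- nrow(pool)
  duration <- (n_stimuli - 1) * ipi + max_shift +
    max(pool$t_lead + pool$t_tot) + dt
  cfg <- sim_config(duration = duration, dt = dt)
  sync <- simulate_muscle(pool, make_synchronous(n, regular_train(0, ipi, n_stimuli)),
                          cfg, keep_per_mu = FALSE)
  sync_peak <- max(sync$total)
  async_peaks <- vapply(seeds, function(sd) {
    stim <- make_regular_asynchronous(n, ipi, n_stimuli,
                                      max_shift = max_shift, seed = sd)
    max(simulate_muscle(pool, stim, cfg, keep_per_mu = FALSE)$total)
  }, numeric(1))
  list(sync_peak = sync_peak, async_peaks = async_peaks,
       frac_async_le_sync = mean(async_peaks <= sync_peak + 1e-12))
}

#' Compare total-force ripple under irregular synchronous vs asynchronous firing
#'
#' For each seed, the pool is stimulated with one shared irregular train
#' (synchronous) and with independent irregular trains of the same mean
#' interval (asynchronous), and the ripple of the total force — `1 -`
#' [fusion_index()] — is measured. The steady window ends when the first MU
#' stops firing, so the comparison is made over the period where every unit
#' is active and the asynchronous trains' scattered endings do not masquerade
#' as ripple. Independent random patterns decorrelate the fluctuations of
#' individual units, so the asynchronous total force is smoother.
#'
#' @param pool A [mu_pool()].
#' @param mean_ipi Shared mean interpulse interval, ms (default 16.6, 60 Hz).
#' @param n_stimuli Pulses per MU (default 50).
#' @param seeds Integer vector of seeds; each yields one sync/async pair.
#' @param variability Per-interval bounds as in [irregular_train()].
#' @param dt Grid step, ms.
#' @return Data frame with one row per seed: `seed`, `ripple_sync`,
#'   `ripple_async`, `async_smoother`.
#' @export
compare_irregular_ripple <- function(pool, mean_ipi = 16.6, n_stimuli = 50,
                                     seeds = 1:10, variability = c(0.5, 1.5),
                                     dt = 0.1) {
  stopifnot(inherits(pool, "mu_pool"))
  n <- nrow(pool)
  ripple <- function(stim) {
    tr <- simulate_muscle(pool, stim, sim_config(dt = dt), keep_per_mu = FALSE)
    common_end <- min(vapply(stim$trains, function(t) t[length(t)],
                             numeric(1)))
    1 - fusion_index(tr$total, tr$times, active_end = common_end)
  }
  rows <- lapply(seeds, function(sd) {
    r_sync <- ripple(make_synchronous(
      n, irregular_train(0, mean_ipi, n_stimuli, variability, seed = sd)))
    r_async <- ripple(make_irregular_asynchronous(
      pool, rep(mean_ipi, n), n_stimuli, variability, seed = sd + 1000L))
    data.frame(seed = sd, ripple_sync = r_sync, ripple_async = r_async,
               async_smoother = r_async < r_sync)
  })
  do.call(rbind, rows)
}
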