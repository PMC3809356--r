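#' Simulation configuration
#'
#' @param duration Simulation duration `T_duration`, ms. `NULL` lets
#'   [simulate_muscle()] take it from the stimulation set or extend the grid
#'   to cover the last twitch.
#' @param dt Time-grid step, ms (default 0.1, well below the shortest
#'   half-contraction times of fast MUs).
#' @param twitch_model `"six_param"` (default) or `"two_param"`.
#' @param epsilon Relaxation floor passed to [twitch_6p()].
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(duration = NULL, dt = 0.1,
                       twitch_model = c("six_param", "two_param"),
                       epsilon = 0.01) {
  twitch_model <- match.arg(twitch_model)
  stopifnot(dt > 0, is.null(duration) || duration > 0)
  structure(list(duration = duration, dt = dt, twitch_model = twitch_model,
                 epsilon = epsilon),
            class = "sim_config")
}

# time grid 0, dt, ..., duration (inclusive end within dt/2)
time_grid <- function(duration, dt) seq(0, duration + dt / 2, by = dt)

#' Simulate the force of one motor unit
#'
#' Linear summation of identical twitch responses: on the grid
#' `t = 0, dt, ..., duration`,
#' \deqn{F_i(t) = \sum_j f(t - t_{ij})}
#' where `f` is the MU's twitch function and `t_ij` its stimulus times.
#' Stimuli after `duration` are ignored; responses straddling the end of the
#' grid are truncated. The summation only touches the grid window supporting
#' each response, which is numerically identical to the naive double loop over
#' (stimulus, grid point).
#'
#' @param fn A twitch function from [twitch_6p()] or [twitch_2p()].
#' @param train Numeric vector of stimulus times, ms.
#' @param duration Simulation duration, ms.
#' @param dt Grid step, ms.
#' @return Numeric vector of forces on the grid (length
#'   `floor(duration/dt) + 1`).
#' @export
simulate_mu <- function(fn, train, duration, dt = 0.1) {
  stopifnot(inherits(fn, "twitch_fn"), duration > 0, dt > 0)
  times <- time_grid(duration, dt)
  force <- numeric(length(times))
  supp <- twitch_support(fn)
  for (s in as.numeric(train)) {
    if (s > duration) next
    lo <- s + supp[1]; hi <- min(s + supp[2], duration)
    i0 <- max(1L, as.integer(floor(lo / dt)) + 1L)
    i1 <- min(length(times), as.integer(ceiling(hi / dt)) + 1L)
    if (i0 > i1) next
    idx <- i0:i1
    force[idx] <- force[idx] + twitch_force(fn, times[idx] - s)
  }
  force
}

#' Simulate whole-muscle force from a pool and stimulation set
#'
#' Computes each MU's force by twitch summation ([simulate_mu()]) and sums
#' them into the S, FR and FF group forces and the total muscle force.
#'
#' @param pool A [mu_pool()].
#' @param stim A [stimulation_set()] with one train per MU.
#' @param cfg A [sim_config()]. If its `duration` is `NULL`, the duration is
#'   taken from `stim$duration`, or extended to cover the response to the last
#'   stimulus.
#' @param keep_per_mu Keep the per-MU force matrix (default `TRUE`); set to
#'   `FALSE` to save memory on long simulations when only group/total series
#'   are needed.
#' @return An object of class `"force_trace"`: list with `times` (ms),
#'   `per_mu` (grid x N matrix, columns `mu_1 ...`, or `NULL`), `group_S`,
#'   `group_FR`, `group_FF`, `total` (numeric series), `pool`, `config`.
#' @examples
#' pool <- generate_pool(2, 2, 2, seed = 1)
#' stim <- make_synchronous(nrow(pool), regular_train(0, 20, 10))
#' tr <- simulate_muscle(pool, stim)
#' peak_force(tr$total, tr$times)
#' @export
simulate_muscle <- function(pool, stim, cfg = sim_config(),
                            keep_per_mu = TRUE) {
  stopifnot(inherits(pool, "mu_pool"), inherits(stim, "stimulation_set"))
  n <- nrow(pool)
  if (length(stim) != n)
    stop_invalid(sprintf("pool has %d MUs but stimulation set has %d trains",
                         n, length(stim)), "mupsim_error_counts")
  duration <- cfg$duration %||% stim$duration %||% {
    last <- suppressWarnings(max(c(0, unlist(stim$trains))))
    max(last + max(pool$t_lead + pool$t_tot), 1)
  }
  times <- time_grid(duration, cfg$dt)
  g <- length(times)
  per_mu <- if (keep_per_mu) matrix(0, g, n) else NULL
  groups <- list(S = numeric(g), FR = numeric(g), FF = numeric(g))
  for (i in seq_len(n)) {
    fn <- pool_twitch_fn(pool, i, model = cfg$twitch_model,
                         epsilon = cfg$epsilon)
    f <- simulate_mu(fn, stim$trains[[i]], duration, cfg$dt)
    if (keep_per_mu) per_mu[, i] <- f
    ty <- pool$mu_type[i]
    groups[[ty]] <- groups[[ty]] + f
  }
  if (keep_per_mu) colnames(per_mu) <- paste0("mu_", seq_len(n))
  structure(list(times = times, per_mu = per_mu,
                 group_S = groups$S, group_FR = groups$FR,
                 group_FF = groups$FF,
                 total = groups$S + groups$FR + groups$FF,
                 pool = pool, config = cfg),
            class = "force_trace")
}

#' Peak force of a series
#'
#' @param series Numeric force series.
#' @param times Optional matching time grid, ms; if omitted the index of the
#'   peak is returned as the time.
#' @return List with `value` (maximum force) and `time` (earliest grid time
#'   attaining it).
#' @export
peak_force <- function(series, times = NULL) {
  if (!length(series))
    stop_invalid("series is empty", "mupsim_error_empty")
  i <- which.max(series)  # earliest index on ties
  list(value = series[i],
       time = if (is.null(times)) i else times[i])
}

#' @export
print.force_trace <- function(x, ...) {
  n <- if (is.null(x$per_mu)) nrow(x$pool) else ncol(x$per_mu)
  pk <- peak_force(x$total, x$times)
  cat(sprintf(
    "Force trace: %d MUs, %d grid points (dt=%g ms, duration=%g ms)\n",
    n, length(x$times), x$config$dt, max(x$times)))
  cat(sprintf("  peak total force %g at %g ms\n", pk$value, pk$time))
  invisible(x)
}

#' @export
summary.force_trace <- function(object, ...) {
  series <- list(total = object$total, group_S = object$group_S,
                 group_FR = object$group_FR, group_FF = object$group_FF)
  out <- do.call(rbind, lapply(series, function(s) {
    pk <- peak_force(s, object$times)
    data.frame(peak = pk$value, peak_time_ms = pk$time, mean = mean(s))
  }))
  out
}

#' Plot whole-muscle and group forces
#'
#' Total force in black, S in red, FR in blue, FF in green (the field's usual
#' colour code).
#'
#' @param x A `"force_trace"` from [simulate_muscle()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.force_trace <- function(x, ...) {
  graphics::plot(x$times, x$total, type = "l", col = "black",
                 xlab = "time (ms)", ylab = "force", ...)
  graphics::lines(x$times, x$group_S, col = "red")
  graphics::lines(x$times, x$group_FR, col = "blue")
  graphics::lines(x$times, x$group_FF, col = "darkgreen")
  graphics::legend("topright",
                   legend = c("total", "S", "FR", "FF"),
                   col = c("black", "red", "blue", "darkgreen"),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Write force series to CSV
#'
#' `"wide"` writes one column per series (`time_ms`, `mu_1 ... mu_N`,
#' `group_S`, `group_FR`, `group_FF`, `total`); `"long"` writes tidy triplets
#' (`time_ms`, `series_id`, `force`).
#'
#' @param trace A `"force_trace"`.
#' @param path Output path.
#' @param format `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_force_csv <- function(trace, path, format = c("wide", "long")) {
  format <- match.arg(format)
  wide <- data.frame(time_ms = trace$times, check.names = FALSE)
  if (!is.null(trace$per_mu)) wide <- cbind(wide, as.data.frame(trace$per_mu))
  wide$group_S <- trace$group_S
  wide$group_FR <- trace$group_FR
  wide$group_FF <- trace$group_FF
  wide$total <- trace$total
  if (format == "wide") {
    utils::write.csv(wide, path, row.names = FALSE)
  } else {
    ids <- setdiff(names(wide), "time_ms")
    long <- data.frame(
      time_ms = rep(wide$time_ms, times = length(ids)),
      series_id = rep(ids, each = nrow(wide)),
      force = unlist(wide[ids], use.names = FALSE))
    utils::write.csv(long, path, row.names = FALSE)
  }
  invisible(path)
}
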