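#' Regular stimulus train
#'
#' Equally spaced stimuli: `start + ipi * (0:(n_stimuli-1))`. A firing rate
#' `f` in Hz corresponds to `ipi = 1000 / f` ms.
#'
#' @param start Time of the first stimulus, ms (>= 0).
#' @param ipi Interpulse interval, ms (> 0).
#' @param n_stimuli Number of stimuli (>= 0; 0 gives an empty train).
#' @return Numeric vector of stimulus times, ms.
#' @export
regular_train <- function(start, ipi, n_stimuli) {
  if (start < 0)
    stop_invalid("start must be >= 0", "mupsim_error_train")
  if (ipi <= 0)
    stop_invalid("ipi must be > 0", "mupsim_error_train")
  n_stimuli <- as.integer(n_stimuli)
  if (n_stimuli < 0)
    stop_invalid("n_stimuli must be >= 0", "mupsim_error_train")
  if (n_stimuli == 0L) return(numeric(0))
  start + ipi * (seq_len(n_stimuli) - 1)
}

#' Irregular stimulus train
#'
#' Successive interpulse intervals are drawn independently and uniformly on
#' `[variability[1], variability[2]] * mean_ipi` — by default between 50% and
#' 150% of the mean interval, the variability observed for motor unit firing.
#'
#' @param start Time of the first stimulus, ms.
#' @param mean_ipi Mean interpulse interval, ms (> 0).
#' @param n_stimuli Number of stimuli.
#' @param variability Length-2 fractions `(low, high)` of `mean_ipi` bounding
#'   each interval; `c(1, 1)` degenerates to [regular_train()].
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of stimulus times, ms, strictly increasing.
#' @export
irregular_train <- function(start, mean_ipi, n_stimuli,
                            variability = c(0.5, 1.5), seed = NULL) {
  if (start < 0) stop_invalid("start must be >= 0", "mupsim_error_train")
  if (mean_ipi <= 0) stop_invalid("mean_ipi must be > 0", "mupsim_error_train")
  check_variability(variability)
  n_stimuli <- as.integer(n_stimuli)
  if (n_stimuli <= 0L) return(numeric(0))
  with_seed(seed, {
    ipis <- stats::runif(n_stimuli - 1L,
                         variability[1] * mean_ipi, variability[2] * mean_ipi)
    start + c(0, cumsum(ipis))
  })
}

check_variability <- function(variability) {
  if (length(variability) != 2L || variability[1] <= 0 ||
      variability[1] > variability[2])
    stop_invalid("variability must be (low, high) with 0 < low <= high",
                 "mupsim_error_variability")
  invisible(variability)
}

#' Stimulation set container
#'
#' Bundles one stimulus train per MU. Each train is a strictly increasing
#' numeric vector of stimulus times in ms.
#'
#' @param trains List of numeric vectors, one per MU.
#' @param duration Optional simulation duration `T_duration`, ms.
#' @param seed The RNG seed the set was generated from, if any (metadata).
#' @return An object of class `"stimulation_set"`.
#' @export
stimulation_set <- function(trains, duration = NULL, seed = NULL) {
  stopifnot(is.list(trains))
  for (i in seq_along(trains)) {
    tr <- trains[[i]]
    if (length(tr) && (any(tr < 0) || any(diff(tr) <= 0)))
      stop_invalid(sprintf(
        "train %d must be strictly increasing and non-negative", i),
        "mupsim_error_train")
  }
  structure(list(trains = trains, duration = duration, seed = seed),
            class = "stimulation_set")
}

#' @export
print.stimulation_set <- function(x, ...) {
  len <- lengths(x$trains)
  cat(sprintf("Stimulation set: %d MUs, %d-%d stimuli per MU%s\n",
              length(x$trains), if (length(len)) min(len) else 0L,
              if (length(len)) max(len) else 0L,
              if (is.null(x$duration)) ""
              else sprintf(", duration %g ms", x$duration)))
  invisible(x)
}

#' @export
length.stimulation_set <- function(x) length(x$trains)

#' Synchronous stimulation: one shared train
#'
#' Every MU of the pool receives a copy of the same train (all active MUs fire
#' with the same pattern).
#'
#' @param pool_size Number of MUs.
#' @param train Stimulus-time vector shared by all MUs.
#' @param duration Optional duration, ms.
#' @return A [stimulation_set()].
#' @export
make_synchronous <- function(pool_size, train, duration = NULL) {
  pool_size <- as.integer(pool_size)
  stopifnot(pool_size >= 1L)
  stimulation_set(rep(list(as.numeric(train)), pool_size), duration = duration)
}

#' Regular asynchronous stimulation: shared rate, shifted onsets
#'
#' Each MU fires a regular train at the same interpulse interval, but the
#' first spike of MU *i* is shifted by an independent uniform draw on
#' `[0, max_shift]`, desynchronising the pool while preserving the rate.
#'
#' @param pool_size Number of MUs.
#' @param ipi Shared interpulse interval, ms.
#' @param n_stimuli Stimuli per MU.
#' @param max_shift Maximum first-spike shift, ms (default 40).
#' @param seed Optional integer seed.
#' @param duration Optional duration, ms.
#' @return A [stimulation_set()].
#' @export
make_regular_asynchronous <- function(pool_size, ipi, n_stimuli,
                                      max_shift = 40, seed = NULL,
                                      duration = NULL) {
  pool_size <- as.integer(pool_size)
  stopifnot(pool_size >= 1L, max_shift >= 0)
  with_seed(seed, {
    shifts <- stats::runif(pool_size, 0, max_shift)
    stimulation_set(lapply(shifts, regular_train, ipi = ipi,
                           n_stimuli = n_stimuli),
                    duration = duration, seed = seed)
  })
}

#' Irregular asynchronous stimulation: individual random trains
#'
#' Each MU receives its own irregular train with its own mean interpulse
#' interval (e.g. rates spanning 10-100 Hz across the pool, or the
#' contraction-time-scaled means of [tc_scaled_mean_ipis()]).
#'
#' @param pool A [mu_pool()] (or an integer pool size).
#' @param mean_ipis Numeric vector of per-MU mean interpulse intervals, ms.
#' @param n_stimuli Stimuli per MU.
#' @param variability Per-interval bounds as in [irregular_train()].
#' @param seed Optional integer seed.
#' @param start Common start time of the first stimulus, ms.
#' @param duration Optional duration, ms.
#' @return A [stimulation_set()].
#' @export
make_irregular_asynchronous <- function(pool, mean_ipis, n_stimuli,
                                        variability = c(0.5, 1.5),
                                        seed = NULL, start = 0,
                                        duration = NULL) {
  n <- if (inherits(pool, "mu_pool")) nrow(pool) else as.integer(pool)
  if (length(mean_ipis) != n)
    stop_invalid(sprintf("need one mean IPI per MU (%d != %d)",
                         length(mean_ipis), n), "mupsim_error_counts")
  with_seed(seed, {
    stimulation_set(lapply(mean_ipis, function(mi)
      irregular_train(start, mi, n_stimuli, variability)),
      duration = duration, seed = seed)
  })
}

#' Contraction-time-scaled mean interpulse intervals
#'
#' The mean interval of each MU is set to `factor * t_c` (1.25 by default),
#' which places every unit on the steep part of its force-frequency curve and
#' yields unfused tetani of similar fusion across the pool.
#'
#' @param pool A [mu_pool()].
#' @param factor Multiple of the contraction time (default 1.25).
#' @return Numeric vector of mean IPIs, ms (one per MU).
#' @export
tc_scaled_mean_ipis <- function(pool, factor = 1.25) {
  stopifnot(inherits(pool, "mu_pool"), factor > 0)
  factor * pool$t_c
}

#' Size-principle recruitment/derecruitment schedule
#'
#' Builds irregular trains honouring Henneman's size principle: MUs are
#' recruited (first stimulus) in order of increasing peak twitch force and
#' derecruited (last stimulus) in the reverse order. The MU with force rank
#' `r` (1 = weakest across the whole pool) starts at `recruit_delays[r]`; its
#' intervals are drawn as in [irregular_train()] and the train is cut after
#' the largest stimulus time not exceeding `derecruit_targets[r]`.
#'
#' @param pool A [mu_pool()].
#' @param recruit_delays Strictly increasing vector of first-stimulus times,
#'   ms, indexed by force rank.
#' @param derecruit_targets Strictly decreasing vector of last-stimulus target
#'   times, ms, indexed by force rank; each must exceed its delay.
#' @param mean_ipis Per-MU mean interpulse intervals, ms (pool order), e.g.
#'   from [tc_scaled_mean_ipis()].
#' @param variability Per-interval bounds as in [irregular_train()].
#' @param seed Optional integer seed.
#' @return A [stimulation_set()] in pool order.
#' @export
size_principle_schedule <- function(pool, recruit_delays, derecruit_targets,
                                    mean_ipis, variability = c(0.5, 1.5),
                                    seed = NULL) {
  stopifnot(inherits(pool, "mu_pool"))
  n <- nrow(pool)
  if (length(recruit_delays) != n || length(derecruit_targets) != n)
    stop_invalid("need one recruit delay and one derecruit target per MU",
                 "mupsim_error_counts")
  if (length(mean_ipis) != n)
    stop_invalid("need one mean IPI per MU", "mupsim_error_counts")
  if (any(diff(recruit_delays) <= 0))
    stop_invalid("recruit_delays must be strictly increasing with force rank",
                 "mupsim_error_schedule")
  if (any(diff(derecruit_targets) >= 0))
    stop_invalid("derecruit_targets must be strictly decreasing with force rank",
                 "mupsim_error_schedule")
  if (any(derecruit_targets <= recruit_delays))
    stop_invalid("every derecruit target must exceed its recruit delay",
                 "mupsim_error_schedule")
  check_variability(variability)
  rank <- rank(pool$f_max, ties.method = "first")
  with_seed(seed, {
    trains <- vector("list", n)
    for (i in seq_len(n)) {
      r <- rank[i]
      t0 <- recruit_delays[r]; tend <- derecruit_targets[r]
      times <- t0
      lo <- variability[1] * mean_ipis[i]; hi <- variability[2] * mean_ipis[i]
      repeat {
        nxt <- times[length(times)] + stats::runif(1, lo, hi)
        if (nxt > tend) break
        times <- c(times, nxt)
      }
      trains[[i]] <- times
    }
    stimulation_set(trains, seed = seed)
  })
}

#' Read a stimulation file (impulses.txt format)
#'
#' The file is a rectangular whitespace-separated table with one column per
#' MU. Two variants exist and must be named explicitly (they are numerically
#' ambiguous): `"times"`, where column *i* holds the absolute stimulus times
#' of MU *i*; and `"delay_ipi"`, where the first row holds the recruitment
#' delay of each MU and the rows below hold its consecutive interpulse
#' intervals (times are recovered by cumulative summation). Because trains of
#' different lengths share one rectangle, shorter trains are padded: a
#' non-increasing time (`"times"` variant) or a value <= 0 after the first row
#' (`"delay_ipi"` variant) terminates that MU's train; the writer pads
#' with -1.
#'
#' @param path Path to the file.
#' @param format `"times"` or `"delay_ipi"`.
#' @return A [stimulation_set()].
#' @export
read_impulses <- function(path, format = c("times", "delay_ipi")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_invalid(sprintf("stimulation file not found: %s", path),
                 "mupsim_error_io")
  tab <- as.matrix(utils::read.table(path, header = FALSE))
  trains <- lapply(seq_len(ncol(tab)), function(i) {
    col <- tab[, i]
    col <- col[!is.na(col)]
    if (format == "times") {
      if (!length(col) || col[1] < 0) return(numeric(0))
      keep <- 1L
      while (keep < length(col) && col[keep + 1L] > col[keep])
        keep <- keep + 1L
      col[seq_len(keep)]
    } else {
      if (!length(col) || col[1] < 0) return(numeric(0))
      ipis <- col[-1]
      stop_at <- which(ipis <= 0)
      if (length(stop_at)) ipis <- ipis[seq_len(stop_at[1] - 1L)]
      col[1] + c(0, cumsum(ipis))
    }
  })
  stimulation_set(trains)
}

#' Write a stimulation file (impulses.txt format)
#'
#' Inverse of [read_impulses()]; columns shorter than the longest train are
#' padded with the sentinel -1. Values are written with 10 significant digits
#' so a write/read round trip reproduces the set to text precision.
#'
#' @param stim A [stimulation_set()].
#' @param path Output path.
#' @param format `"times"` or `"delay_ipi"`.
#' @return `path`, invisibly.
#' @export
write_impulses <- function(stim, path, format = c("times", "delay_ipi")) {
  format <- match.arg(format)
  stopifnot(inherits(stim, "stimulation_set"))
  cols <- lapply(stim$trains, function(tr) {
    if (format == "times") tr else if (length(tr)) c(tr[1], diff(tr))
    else numeric(0)
  })
  # empty trains encode as a single -1 row entry
  k <- max(1L, max(lengths(cols)))
  m <- vapply(cols, function(cl) c(cl, rep(-1, k - length(cl))), numeric(k))
  m <- matrix(m, nrow = k)
  lines <- apply(m, 1, function(r) paste(sprintf("%.10g", r), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}
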