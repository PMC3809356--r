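#' Run a simulation and write its outputs
#'
#' Simulates the pool under the given stimulation set and writes the force
#' series as wide and long CSV files plus a JSON manifest (configuration echo,
#' seed, package version) sufficient to reproduce the run.
#'
#' @param pool A [mu_pool()].
#' @param stim A [stimulation_set()].
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @param plot If `TRUE`, also writes `forces.pdf` with the group/total plot.
#' @param seed Seed recorded in the manifest (the stimulation set's own seed
#'   by default).
#' @return The `"force_trace"`, invisibly.
#' @export
run_simulation <- function(pool, stim, cfg = sim_config(), out_dir,
                           plot = FALSE, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trace <- simulate_muscle(pool, stim, cfg)
  write_force_csv(trace, file.path(out_dir, "forces_wide.csv"), "wide")
  write_force_csv(trace, file.path(out_dir, "forces_long.csv"), "long")
  write_manifest(out_dir, list(
    pool = list(n = nrow(pool), counts = as.list(attr(pool, "counts"))),
    stimulation = list(n_trains = length(stim),
                       n_stimuli = lengths(stim$trains),
                       seed = seed %||% stim$seed),
    config = unclass(cfg)))
  if (plot) {
    grDevices::pdf(file.path(out_dir, "forces.pdf"), width = 8, height = 5)
    on.exit(grDevices::dev.off())
    plot(trace)
  }
  invisible(trace)
}

write_manifest <- function(out_dir, entries) {
  entries$package <- "mupsim"
  entries$version <- as.character(utils::packageVersion("mupsim"))
  jsonlite::write_json(entries, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(entries)
}

#' Run a canned stimulation experiment
#'
#' Reproduces the four standard demonstration scenarios on any pool:
#' \describe{
#'   \item{`"fig2"`}{Regular synchronous stimulation: 50 stimuli at a 20 ms
#'     interpulse interval applied to every MU; writes the force CSVs.}
#'   \item{`"fig3"`}{Force-frequency analysis: the normalized peak-force curve
#'     over the 13-point 1-100 Hz grid, plus representative tetani at 10, 30,
#'     40, 60 and 100 Hz; writes the curve and gain tables.}
#'   \item{`"fig4"`}{Synchrony comparison at a mean rate of 60 Hz (16.6 ms):
#'     regular synchronous, regular asynchronous (first spikes shifted 0-40
#'     ms), irregular synchronous and irregular asynchronous; writes peak and
#'     fusion tables and the four traces.}
#'   \item{`"fig5"`}{Size-principle recruitment/derecruitment with irregular
#'     trains at mean interval `1.25 * t_c` per MU; recruit delays increase
#'     with force rank and last-impulse targets decrease with it.}
#' }
#'
#' @param name One of `"fig2"`, `"fig3"`, `"fig4"`, `"fig5"`.
#' @param pool A [mu_pool()].
#' @param seed Integer seed for the stochastic scenarios.
#' @param out_dir Output directory.
#' @param dt Grid step, ms.
#' @param n_stimuli Pulses per MU for the fig2-fig4 scenarios.
#' @param plot If `TRUE`, writes PDF figures alongside the CSVs.
#' @return A list of the experiment's result objects, invisibly.
#' @export
run_experiment <- function(name = c("fig2", "fig3", "fig4", "fig5"),
                           pool, seed = 1, out_dir, dt = 0.1,
                           n_stimuli = 50, plot = FALSE) {
  name <- match.arg(name)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(pool)
  res <- switch(name,
    fig2 = {
      stim <- make_synchronous(n, regular_train(0, 20, n_stimuli))
      trace <- run_simulation(pool, stim, sim_config(dt = dt), out_dir,
                              plot = plot, seed = seed)
      list(trace = trace)
    },
    fig3 = {
      curve <- force_frequency_curve(pool, n_stimuli = n_stimuli, dt = dt)
      utils::write.csv(curve, file.path(out_dir, "force_frequency.csv"),
                       row.names = FALSE)
      gains <- tetanic_gain(pool, n_stimuli = n_stimuli, dt = dt)
      utils::write.csv(
        data.frame(series_id = c(paste0("group_", names(gains$groups)), "total"),
                   gain_10_to_100_hz = c(unname(gains$groups), gains$total)),
        file.path(out_dir, "tetanic_gain.csv"), row.names = FALSE)
      tet <- list()
      for (f in c(10, 30, 40, 60, 100)) {
        stim <- make_synchronous(n, regular_train(0, 1000 / f, n_stimuli))
        tet[[as.character(f)]] <- simulate_muscle(
          pool, stim, sim_config(dt = dt), keep_per_mu = FALSE)
        write_force_csv(tet[[as.character(f)]],
                        file.path(out_dir, sprintf("tetanus_%ghz.csv", f)),
                        "wide")
      }
      if (plot) {
        grDevices::pdf(file.path(out_dir, "force_frequency.pdf"))
        on.exit(grDevices::dev.off())
        plot(curve, series = c("group_S", "group_FR", "group_FF", "total"))
      }
      write_manifest(out_dir, list(experiment = "fig3", seed = seed,
                                   config = list(dt = dt, n_stimuli = n_stimuli)))
      list(curve = curve, gains = gains, tetani = tet)
    },
    fig4 = {
      ipi <- 16.6
      cfg <- sim_config(dt = dt)
      mean_ipis <- rep(ipi, n)
      stims <- list(
        regular_sync = make_synchronous(n, regular_train(0, ipi, n_stimuli)),
        regular_async = make_regular_asynchronous(n, ipi, n_stimuli,
                                                  max_shift = 40, seed = seed),
        irregular_sync = make_synchronous(
          n, irregular_train(0, ipi, n_stimuli, seed = seed)),
        irregular_async = make_irregular_asynchronous(
          pool, mean_ipis, n_stimuli, seed = seed + 1L))
      traces <- lapply(stims, function(s)
        simulate_muscle(pool, s, cfg, keep_per_mu = FALSE))
      stats_tab <- do.call(rbind, Map(function(id, tr, st) {
        last_stim <- max(unlist(st$trains))
        data.frame(regime = id, peak_total = max(tr$total),
                   fusion_index = fusion_index(tr$total, tr$times,
                                               active_end = last_stim))
      }, names(traces), traces, stims))
      utils::write.csv(stats_tab, file.path(out_dir, "sync_async.csv"),
                       row.names = FALSE)
      for (id in names(traces))
        write_force_csv(traces[[id]],
                        file.path(out_dir, sprintf("forces_%s.csv", id)),
                        "wide")
      write_manifest(out_dir, list(experiment = "fig4", seed = seed,
                                   config = list(dt = dt, ipi = ipi,
                                                 n_stimuli = n_stimuli)))
      list(traces = traces, stats = stats_tab)
    },
    fig5 = {
      rank_delays <- (seq_len(n) - 1) * 50        # 50 ms per force rank
      plateau_end <- max(rank_delays) + 6500
      rank_targets <- plateau_end - (seq_len(n) - 1) * 50
      stim <- size_principle_schedule(
        pool, rank_delays, rank_targets,
        mean_ipis = tc_scaled_mean_ipis(pool), seed = seed)
      trace <- run_simulation(pool, stim, sim_config(dt = dt), out_dir,
                              plot = plot, seed = seed)
      sched <- data.frame(
        mu = seq_len(n), mu_type = pool$mu_type, f_max = pool$f_max,
        rank = rank(pool$f_max, ties.method = "first"),
        onset = vapply(stim$trains, function(t) t[1], numeric(1)),
        last_stimulus = vapply(stim$trains, function(t) t[length(t)],
                               numeric(1)))
      utils::write.csv(sched, file.path(out_dir, "recruitment_schedule.csv"),
                       row.names = FALSE)
      list(trace = trace, schedule = sched, stimulation = stim)
    })
  invisible(res)
}
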