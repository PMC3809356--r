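#' Construct a motor unit pool
#'
#' A pool is an ordered collection of motor units: the first `n_s` are slow
#' (S), the next `n_fr` fast-fatigue-resistant (FR) and the last `n_ff` fast
#' fatigable (FF). Within each type block the units must be arranged by
#' increasing peak twitch force `f_max` (the field's usual file convention);
#' with `strict = FALSE` a violation is a warning instead of an error.
#'
#' @param params Data frame with numeric columns `t_lead`, `t_hc`, `t_c`,
#'   `t_hr`, `t_tot`, `f_max` (one row per MU, ms / force units), or a list of
#'   [twitch_params()] objects.
#' @param n_s,n_fr,n_ff Number of S, FR and FF units; must sum to `nrow(params)`.
#' @param strict If `TRUE` (default) non-increasing `f_max` within a type
#'   block is an error; if `FALSE`, a warning.
#' @return An object of class `c("mu_pool", "data.frame")`: the parameter
#'   table with an `mu_type` column, plus a `counts` attribute.
#' @seealso [generate_pool()], [read_datatw()], [write_datatw()]
#' @export
mu_pool <- function(params, n_s, n_fr, n_ff, strict = TRUE) {
  if (is.list(params) && !is.data.frame(params) &&
      all(vapply(params, inherits, logical(1), "twitch_params"))) {
    params <- do.call(rbind, lapply(params, function(p)
      data.frame(t_lead = p$t_lead, t_hc = p$t_hc, t_c = p$t_c,
                 t_hr = p$t_hr, t_tot = p$t_tot, f_max = p$f_max)))
  }
  params <- as.data.frame(params)
  need <- c("t_lead", "t_hc", "t_c", "t_hr", "t_tot", "f_max")
  if (!all(need %in% names(params)))
    stop_invalid(paste("pool table must have columns:",
                       paste(need, collapse = ", ")), "mupsim_error_format")
  n_s <- as.integer(n_s); n_fr <- as.integer(n_fr); n_ff <- as.integer(n_ff)
  if (min(n_s, n_fr, n_ff) < 0 || n_s + n_fr + n_ff < 1L)
    stop_invalid("type counts must be >= 0 and sum to at least 1",
                 "mupsim_error_counts")
  if (nrow(params) != n_s + n_fr + n_ff)
    stop_invalid(sprintf("pool has %d rows but n_s + n_fr + n_ff = %d",
                         nrow(params), n_s + n_fr + n_ff),
                 "mupsim_error_counts")
  mu_type <- rep(c("S", "FR", "FF"), times = c(n_s, n_fr, n_ff))
  for (i in seq_len(nrow(params))) {
    pr <- params[i, ]
    tryCatch(
      twitch_params(pr$t_lead, pr$t_hc, pr$t_c, pr$t_hr, pr$t_tot, pr$f_max,
                    mu_type[i]),
      mupsim_error = function(e)
        stop_invalid(sprintf("MU %d (row %d): %s", i, i, conditionMessage(e)),
                     "mupsim_error_row"))
  }
  for (ty in unique(mu_type)) {
    fm <- params$f_max[mu_type == ty]
    if (length(fm) > 1L && any(diff(fm) <= 0)) {
      msg <- sprintf("f_max is not strictly increasing within the %s block", ty)
      if (strict) stop_invalid(msg, "mupsim_error_order") else warning(msg)
    }
  }
  pool <- cbind(mu_type = mu_type, params[need])
  rownames(pool) <- NULL
  structure(pool, counts = c(n_s = n_s, n_fr = n_fr, n_ff = n_ff),
            class = c("mu_pool", "data.frame"))
}

#' @export
print.mu_pool <- function(x, ...) {
  n <- attr(x, "counts")
  cat(sprintf("Motor unit pool: %d MUs (%d S, %d FR, %d FF)\n",
              nrow(x), n[["n_s"]], n[["n_fr"]], n[["n_ff"]]))
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
summary.mu_pool <- function(object, ...) {
  agg <- do.call(rbind, lapply(split(as.data.frame(object)[-1], object$mu_type),
                               function(d) vapply(d, mean, numeric(1))))
  cat("Per-type means of twitch parameters:\n")
  print(agg[intersect(c("S", "FR", "FF"), rownames(agg)), , drop = FALSE])
  invisible(agg)
}

#' Plot the twitch curves of a pool
#'
#' Overlays the six-parameter twitch of every MU, coloured by type (S red,
#' FR blue, FF green — the field's usual colour code).
#'
#' @param x A [mu_pool()].
#' @param dt Sampling step, ms.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.mu_pool <- function(x, dt = 0.1, ...) {
  tmax <- max(x$t_lead + x$t_tot)
  tt <- seq(0, tmax, by = dt)
  ff <- vapply(seq_len(nrow(x)),
               function(i) twitch_force(pool_twitch_fn(x, i), tt),
               numeric(length(tt)))
  cols <- c(S = "red", FR = "blue", FF = "darkgreen")[x$mu_type]
  graphics::matplot(tt, ff, type = "l", lty = 1, col = cols,
                    xlab = "time (ms)", ylab = "force", ...)
  graphics::legend("topright", legend = c("S", "FR", "FF"),
                   col = c("red", "blue", "darkgreen"), lty = 1, bty = "n")
  invisible(x)
}

# twitch function object for MU i of a pool; the shallow-relaxation warning
# is muffled here so bulk simulations do not repeat it once per rebuild
# (direct twitch_6p() calls still signal it)
pool_twitch_fn <- function(pool, i, model = c("six_param", "two_param"),
                           epsilon = 0.01) {
  model <- match.arg(model)
  pr <- pool[i, ]
  if (model == "six_param") {
    p <- twitch_params(pr$t_lead, pr$t_hc, pr$t_c, pr$t_hr, pr$t_tot,
                       pr$f_max, pr$mu_type)
    withCallingHandlers(
      twitch_6p(p, epsilon = epsilon),
      mupsim_shallow_relaxation = function(w) invokeRestart("muffleWarning"))
  } else {
    twitch_2p(pr$f_max, pr$t_c, pr$t_lead)
  }
}

#' Read a motor unit pool file (datatw.txt format)
#'
#' The file has one row per MU and six whitespace-separated numeric columns in
#' the order `T_lead, T_hc, T_c, T_hr, T_tot, F_max`. The first `n_s` rows are
#' the S units, the next `n_fr` the FR units and the last `n_ff` the FF units,
#' each block sorted by increasing `F_max`.
#'
#' @param path Path to the file.
#' @param n_s,n_fr,n_ff Type counts; their sum must equal the number of rows.
#' @param strict Passed to [mu_pool()].
#' @return A [mu_pool()].
#' @export
read_datatw <- function(path, n_s, n_fr, n_ff, strict = TRUE) {
  if (!file.exists(path))
    stop_invalid(sprintf("pool file not found: %s", path), "mupsim_error_io")
  tab <- utils::read.table(path, header = FALSE)
  if (ncol(tab) != 6L)
    stop_invalid(sprintf("%s: expected 6 columns, found %d", path, ncol(tab)),
                 "mupsim_error_format")
  names(tab) <- c("t_lead", "t_hc", "t_c", "t_hr", "t_tot", "f_max")
  mu_pool(tab, n_s, n_fr, n_ff, strict = strict)
}

#' Write a motor unit pool file (datatw.txt format)
#'
#' Values are written with 10 significant digits so a write/read round trip
#' reproduces the pool to text precision.
#'
#' @param pool A [mu_pool()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_datatw <- function(pool, path) {
  stopifnot(inherits(pool, "mu_pool"))
  if (nrow(pool) < 1L)
    stop_invalid("pool must contain at least one MU", "mupsim_error_counts")
  m <- as.matrix(as.data.frame(pool)[c("t_lead", "t_hc", "t_c", "t_hr",
                                       "t_tot", "f_max")])
  lines <- apply(m, 1, function(r) paste(sprintf("%.10g", r), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Generate a synthetic motor unit pool
#'
#' Draws per-MU twitch parameters emulating the statistical structure of a
#' mixed mammalian pool: contraction times `t_c` uniform within type-specific
#' ranges, peak forces following an inverse power law
#' \eqn{F_{max} = A \, T_c^{-\gamma} e^{\eta}} with lognormal jitter
#' \eqn{\eta \sim N(0, \sigma^2)}, and the remaining times as type-specific
#' ratios of `t_c` (slow units relax relatively slower). Each type block is
#' re-sorted by `f_max` after drawing so the pool satisfies the file ordering
#' convention.
#'
#' The default `t_c` ranges are chosen so that, under the `1.25 * t_c`
#' mean-interpulse-interval rule of [tc_scaled_mean_ipis()], mean firing rates
#' fall in the physiological windows reported for rat medial gastrocnemius
#' MUs: 24.2-40.0 Hz (S), 42.1-59.7 Hz (FR), 43.2-61.5 Hz (FF). The default
#' amplitude scales make FF units the strongest and leave the weakest S unit
#' near 1 force unit.
#'
#' @param n_s,n_fr,n_ff Type counts (default 10/10/10). The preset
#'   `"rat-MG-realistic"` uses the experimentally estimated male rat medial
#'   gastrocnemius composition 8 S / 23 FR / 26 FF.
#' @param seed Integer seed; regeneration with the same seed is bit-identical.
#' @param preset Optional named composition preset, currently
#'   `"rat-MG-realistic"`; overrides the counts.
#' @param type_profiles Named list of per-type generation profiles; see
#'   [default_type_profiles()].
#' @param gamma Inverse-power exponent of the `f_max`-`t_c` relation.
#' @param sigma Lognormal jitter SD around the power law.
#' @return A [mu_pool()].
#' @examples
#' pool <- generate_pool(seed = 42)
#' summary(pool)
#' @export
generate_pool <- function(n_s = 10, n_fr = 10, n_ff = 10, seed = NULL,
                          preset = NULL,
                          type_profiles = default_type_profiles(),
                          gamma = 2, sigma = 0.3) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "rat-MG-realistic")
    n_s <- 8; n_fr <- 23; n_ff <- 26
  }
  counts <- c(S = n_s, FR = n_fr, FF = n_ff)
  if (sum(counts) < 1L)
    stop_invalid("pool must contain at least one MU", "mupsim_error_counts")
  with_seed(seed, {
    blocks <- lapply(names(counts), function(ty) {
      n <- counts[[ty]]
      if (n == 0L) return(NULL)
      pf <- type_profiles[[ty]]
      t_c <- stats::runif(n, pf$t_c[1], pf$t_c[2])
      f_max <- pf$amplitude * t_c^(-gamma) *
        exp(stats::rnorm(n, 0, sigma))
      rho_hc <- stats::runif(n, pf$rho_hc[1], pf$rho_hc[2])
      rho_hr <- stats::runif(n, pf$rho_hr[1], pf$rho_hr[2])
      rho_tot <- stats::runif(n, pf$rho_tot[1], pf$rho_tot[2])
      if (any(rho_hc >= 1) || any(rho_hr <= 1) || any(rho_tot <= max(rho_hr)))
        stop_invalid(sprintf(
          "type %s ratio ranges violate t_hc < t_c < t_hr < t_tot", ty),
          "mupsim_error_ratios")
      d <- data.frame(
        t_lead = stats::runif(n, pf$t_lead[1], pf$t_lead[2]),
        t_hc = rho_hc * t_c, t_c = t_c, t_hr = rho_hr * t_c,
        t_tot = rho_tot * t_c, f_max = f_max)
      d[order(d$f_max), ]
    })
    mu_pool(do.call(rbind, blocks), n_s, n_fr, n_ff)
  })
}

#' Default per-type generation profiles
#'
#' Returns the named list of per-type parameter ranges used by
#' [generate_pool()]: the `t_c` sampling interval (ms), the ratio ranges
#' `rho_hc = t_hc/t_c`, `rho_hr = t_hr/t_c`, `rho_tot = t_tot/t_c`, the
#' `t_lead` interval (ms) and the power-law amplitude `A`. Edit the returned
#' list to model a different muscle.
#'
#' @return Named list with elements `S`, `FR`, `FF`.
#' @export
default_type_profiles <- function() {
  list(
    S = list(t_c = c(20, 1000 / (1.25 * 24.2)),   # 20 .. 33.06 ms
             rho_hc = c(0.45, 0.65), rho_hr = c(1.5, 2.2),
             rho_tot = c(4, 7), t_lead = c(1, 4), amplitude = 800),
    FR = list(t_c = c(1000 / (1.25 * 59.7), 1000 / (1.25 * 42.1)), # 13.40..19.00
              rho_hc = c(0.45, 0.65), rho_hr = c(1.3, 1.8),
              rho_tot = c(3, 5), t_lead = c(1, 4), amplitude = 8000),
    FF = list(t_c = c(1000 / (1.25 * 61.5), 1000 / (1.25 * 43.2)), # 13.01..18.52
              rho_hc = c(0.45, 0.65), rho_hr = c(1.3, 1.8),
              rho_tot = c(3, 5), t_lead = c(1, 4), amplitude = 20000))
}
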