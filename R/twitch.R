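#' Six-parameter twitch description of a motor unit
#'
#' Bundles the six descriptors of a single motor-unit (MU) twitch: the lead
#' time between stimulus and force onset (`t_lead`), the half-contraction time
#' (`t_hc`, onset to half of peak force), the contraction time (`t_c`, onset to
#' peak), the half-relaxation time (`t_hr`, onset to half of peak during
#' relaxation), the total twitch duration (`t_tot`) and the peak twitch force
#' (`f_max`). All times are in milliseconds; force is in the (arbitrary) unit
#' of the input data.
#'
#' @param t_lead Lead time, ms (>= 0).
#' @param t_hc Half-contraction time, ms.
#' @param t_c Contraction time, ms.
#' @param t_hr Half-relaxation time, ms (measured from force onset, like
#'   `t_hc` and `t_c`).
#' @param t_tot Total twitch duration, ms.
#' @param f_max Peak twitch force (> 0), arbitrary force units.
#' @param mu_type Motor unit type, one of `"S"`, `"FR"`, `"FF"`.
#'
#' @return An object of class `"twitch_params"`.
#' @seealso [twitch_6p()], [twitch_2p()]
#' @examples
#' p <- twitch_params(2, 10, 20, 35, 80, 1)
#' p
#' @export
twitch_params <- function(t_lead, t_hc, t_c, t_hr, t_tot, f_max,
                          mu_type = c("S", "FR", "FF")) {
  mu_type <- match.arg(mu_type)
  p <- structure(
    list(t_lead = as.numeric(t_lead), t_hc = as.numeric(t_hc),
         t_c = as.numeric(t_c), t_hr = as.numeric(t_hr),
         t_tot = as.numeric(t_tot), f_max = as.numeric(f_max),
         mu_type = mu_type),
    class = "twitch_params")
  validate_twitch_params(p)
}

#' Validate twitch parameters
#'
#' Checks the ordering invariant `0 <= t_lead`, `0 < t_hc < t_c < t_hr < t_tot`
#' and `f_max > 0`. Each violation raises a distinct classed condition so
#' callers (e.g. the pool file reader) can report which constraint failed.
#'
#' @param p A `"twitch_params"` object (or a bare list with the same fields).
#' @return `p`, unchanged, if all invariants hold.
#' @export
validate_twitch_params <- function(p) {
  num <- unlist(p[c("t_lead", "t_hc", "t_c", "t_hr", "t_tot", "f_max")])
  if (any(!is.finite(num)))
    stop_invalid("all twitch parameters must be finite numbers",
                 "mupsim_error_nonfinite")
  if (p$t_lead < 0)
    stop_invalid("t_lead must be >= 0", "mupsim_error_negative_lead")
  if (p$f_max <= 0)
    stop_invalid("f_max must be > 0", "mupsim_error_nonpositive_fmax")
  if (p$t_hc <= 0)
    stop_invalid("t_hc must be > 0", "mupsim_error_ordering")
  if (p$t_hc >= p$t_c)
    stop_invalid("t_hc must be < t_c", "mupsim_error_ordering")
  if (p$t_c >= p$t_hr)
    stop_invalid("t_c must be < t_hr", "mupsim_error_ordering")
  if (p$t_hr >= p$t_tot)
    stop_invalid("t_hr must be < t_tot", "mupsim_error_ordering")
  p
}

#' @export
print.twitch_params <- function(x, ...) {
  cat(sprintf(
    "Twitch parameters (%s MU): T_lead=%g  T_hc=%g  T_c=%g  T_hr=%g  T_tot=%g ms;  F_max=%g\n",
    x$mu_type, x$t_lead, x$t_hc, x$t_c, x$t_hr, x$t_tot, x$f_max))
  invisible(x)
}

#' Build the six-parameter analytical twitch curve
#'
#' Constructs a twitch force-versus-time function that reproduces all six
#' descriptors exactly. With \eqn{\tau = t - T_{lead}}:
#' \deqn{F(\tau) = F_{max} (\tau/T_c)^m e^{m(1 - \tau/T_c)}, \quad \tau \in [0, T_c]}
#' \deqn{F(\tau) = F_{max} e^{-c (\tau - T_c)^b}, \quad \tau \in (T_c, T_{tot})}
#' and \eqn{F \equiv 0} outside \eqn{[0, T_{tot})} (hard truncation at
#' `t_tot`). The rising exponent `m > 0` is solved numerically from
#' \eqn{F(T_{hc}) = F_{max}/2} (root bracket \eqn{(10^{-6}, 100)}, absolute
#' tolerance 1e-12); the relaxation coefficients come from the closed forms
#' \deqn{b = \frac{\ln(\ln(1/\epsilon)/\ln 2)}{\ln((T_{tot}-T_c)/(T_{hr}-T_c))},
#'   \qquad c = \frac{\ln 2}{(T_{hr}-T_c)^b}}
#' imposed by \eqn{F(T_{hr}) = F_{max}/2} and \eqn{F(T_{tot}) = \epsilon
#' F_{max}}. The relaxation floor `epsilon` makes the finite duration `t_tot`
#' meaningful: a strictly positive exponential never reaches zero, so the curve
#' is cut where it has decayed to `epsilon * f_max` (1% by default).
#'
#' Both pieces equal `f_max` at the peak, so the curve is continuous; the
#' rising piece has zero slope there. When `b < 1` the relaxation piece has
#' infinite slope at the peak (the curve itself is still continuous); this is
#' signalled as a warning of class `"mupsim_shallow_relaxation"`.
#'
#' @param p A [twitch_params()] object.
#' @param epsilon Relaxation floor as a fraction of `f_max`, in (0, 0.5).
#' @return An object of class `c("twitch_6p", "twitch_fn")` storing the
#'   parameters and shape coefficients `m`, `b`, `c`; evaluate it with
#'   [twitch_force()].
#' @examples
#' fn <- twitch_6p(twitch_params(2, 10, 20, 35, 80, 1))
#' twitch_force(fn, c(2, 12, 22, 37, 81.999))
#' @export
twitch_6p <- function(p, epsilon = 0.01) {
  p <- validate_twitch_params(p)
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L,
            epsilon > 0, epsilon < 0.5)
  r <- p$t_hc / p$t_c
  # F(T_hc) = F_max/2  <=>  r^m exp(m (1 - r)) = 1/2, monotone decreasing in m
  g <- function(m) r^m * exp(m * (1 - r)) - 0.5
  lo <- 1e-6; hi <- 100
  if (g(hi) >= 0) {
    stop_invalid(sprintf(
      paste0("rising-exponent solver cannot bracket a root for ",
             "T_hc/T_c = %.6g (T_hc=%g, T_c=%g): required exponent exceeds %g"),
      r, p$t_hc, p$t_c, hi), "mupsim_error_no_root")
  }
  m <- stats::uniroot(g, c(lo, hi), tol = 1e-12)$root

  ratio <- (p$t_tot - p$t_c) / (p$t_hr - p$t_c)
  b <- log(log(1 / epsilon) / log(2)) / log(ratio)
  c_coef <- log(2) / (p$t_hr - p$t_c)^b
  if (b < 1)
    warning(warningCondition(
      sprintf("relaxation shape exponent b = %.4g < 1 (T_tot - T_c much longer than T_hr - T_c); curve is continuous but has infinite slope just after the peak",
              b),
      class = "mupsim_shallow_relaxation"))

  structure(list(params = p, model = "six_param", epsilon = epsilon,
                 m = m, b = b, c = c_coef),
            class = c("twitch_6p", "twitch_fn"))
}

#' Build the two-parameter comparison twitch
#'
#' The classical impulse-response twitch used by pool models that describe a
#' twitch by peak force and contraction time only:
#' \eqn{F(\tau) = F_{max} (\tau/T_c) e^{1 - \tau/T_c}} for
#' \eqn{\tau = t - T_{lead} \ge 0}, else 0. The curve peaks at `f_max` at
#' \eqn{t = T_{lead} + T_c} and has an infinite exponential tail (no
#' truncation); in practice the evaluation grid bounds it.
#'
#' @param f_max Peak force (> 0).
#' @param t_c Contraction time, ms (> 0).
#' @param t_lead Lead time shift, ms (>= 0).
#' @return An object of class `c("twitch_2p", "twitch_fn")`.
#' @examples
#' fn <- twitch_2p(1, 20)
#' twitch_force(fn, c(20, 40)) # peak, then 2/e
#' @export
twitch_2p <- function(f_max, t_c, t_lead = 0) {
  if (!is.numeric(f_max) || f_max <= 0)
    stop_invalid("f_max must be > 0", "mupsim_error_nonpositive_fmax")
  if (!is.numeric(t_c) || t_c <= 0)
    stop_invalid("t_c must be > 0", "mupsim_error_ordering")
  if (t_lead < 0)
    stop_invalid("t_lead must be >= 0", "mupsim_error_negative_lead")
  structure(list(f_max = as.numeric(f_max), t_c = as.numeric(t_c),
                 t_lead = as.numeric(t_lead), model = "two_param"),
            class = c("twitch_2p", "twitch_fn"))
}

#' Evaluate a twitch function
#'
#' Elementwise force at the given times (ms since the stimulus); zero outside
#' the curve's support.
#'
#' @param fn A `"twitch_fn"` object from [twitch_6p()] or [twitch_2p()].
#' @param times Numeric vector of times, ms.
#' @return Numeric vector of forces, same length as `times`.
#' @export
twitch_force <- function(fn, times) UseMethod("twitch_force")

#' @export
twitch_force.twitch_6p <- function(fn, times) {
  stopifnot(is.numeric(times), all(is.finite(times)))
  p <- fn$params
  tau <- times - p$t_lead
  f <- numeric(length(tau))
  ris <- tau > 0 & tau <= p$t_c
  # truncation compared in absolute time so t = t_lead + t_tot is exactly zero
  rel <- tau > p$t_c & times < p$t_lead + p$t_tot
  if (any(ris)) {
    x <- tau[ris] / p$t_c
    f[ris] <- p$f_max * x^fn$m * exp(fn$m * (1 - x))
  }
  if (any(rel))
    f[rel] <- p$f_max * exp(-fn$c * (tau[rel] - p$t_c)^fn$b)
  f
}

#' @export
twitch_force.twitch_2p <- function(fn, times) {
  stopifnot(is.numeric(times), all(is.finite(times)))
  tau <- times - fn$t_lead
  f <- numeric(length(tau))
  pos <- tau > 0
  if (any(pos)) {
    x <- tau[pos] / fn$t_c
    f[pos] <- fn$f_max * x * exp(1 - x)
  }
  f
}

#' @export
print.twitch_fn <- function(x, ...) {
  if (inherits(x, "twitch_6p")) {
    cat("6-parameter twitch function\n")
    print(x$params)
    cat(sprintf("  shape coefficients: m=%.6g  b=%.6g  c=%.6g  (epsilon=%g)\n",
                x$m, x$b, x$c, x$epsilon))
  } else {
    cat(sprintf("2-parameter twitch function: F_max=%g, T_c=%g ms, T_lead=%g ms\n",
                x$f_max, x$t_c, x$t_lead))
  }
  invisible(x)
}

# support of a twitch function, in ms since the stimulus (upper end Inf for 2p)
twitch_support <- function(fn) {
  if (inherits(fn, "twitch_6p"))
    c(fn$params$t_lead, fn$params$t_lead + fn$params$t_tot)
  else
    c(fn$t_lead, Inf)
}

stop_invalid <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mupsim_error")))
}
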