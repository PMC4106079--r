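# Time-domain integration (fixed-step RK4) and long-run attractor
# classification, the nonlinear cross-check of the linear verdicts.

# Local maxima by slope-sign change, carrying the last nonzero slope
# through plateaus so a crest sampled as two equal values still counts
# as one peak.
peak_indices <- function(V) {
  s <- sign(diff(V))
  last <- -1
  for (i in seq_along(s)) {
    if (s[i] == 0) s[i] <- last else last <- s[i]
  }
  which(s[-length(s)] > 0 & s[-1] < 0) + 1L
}

#' Equilibrium state with a small voltage perturbation
#'
#' Convention for classification runs: the tracked equilibrium with V
#' displaced by `delta_V` and gates left at their steady-state values.
#' A small kick reveals instability without large-stimulus artifacts.
#'
#' @param params An [hh_params()] object.
#' @param delta_V Voltage offset (mV).
#' @param V_ref Reference potential for [tracked_equilibrium()].
#' @return Named numeric state `(V, m, h, n)`.
#' @export
perturbed_equilibrium <- function(params, delta_V = 1, V_ref = 0) {
  eq <- tracked_equilibrium(params, V_ref = V_ref)
  c(V = eq$V_star + delta_V, m = eq$m_star, h = eq$h_star, n = eq$n_star)
}

#' Simulate the model with fixed-step RK4
#'
#' Integrates the four-dimensional vector field with the classical
#' 4th-order Runge-Kutta method at a fixed step, so trajectories are
#' deterministic and exactly reproducible.
#'
#' @param params An [hh_params()] object.
#' @param initial Initial state (vector or one-row data frame with
#'   V, m, h, n).  Default: the tracked equilibrium perturbed by
#'   +1 mV ([perturbed_equilibrium()]).
#' @param t_end Integration horizon (ms).
#' @param dt Step size (ms).
#' @return A tibble of class `hh_trace` with columns `time`, `V`, `m`,
#'   `h`, `n` at the uniform grid `seq(0, t_end, by = dt)`; the
#'   parameter set and step are attached as attributes `params` and
#'   `dt`.
#' @examples
#' \donttest{
#' tr <- hh_simulate(update(hh_params(), g_K = 15), t_end = 200)
#' classify_attractor(tr)
#' }
#' @export
hh_simulate <- function(params, initial = NULL, t_end = 500, dt = 0.01) {
  validate_hh_params(params)
  if (!is.finite(t_end) || t_end <= 0) abort("t_end must be positive")
  if (!is.finite(dt) || dt <= 0) abort("dt must be positive")
  if (is.null(initial)) initial <- perturbed_equilibrium(params)
  y0 <- as_hh_state(initial)
  if (any(y0[c("m", "h", "n")] < -1e-9) || any(y0[c("m", "h", "n")] > 1 + 1e-9)) {
    abort("initial gating variables must lie in [0, 1]")
  }

  times <- seq(0, t_end, by = dt)
  deriv <- function(t, y, parms) {
    list(hh_rhs_raw(y[[1]], y[[2]], y[[3]], y[[4]], parms))
  }
  sol <- deSolve::rk4(y = y0, times = times, func = deriv, parms = params)
  sol <- unclass(sol)
  bad <- which(!stats::complete.cases(sol) | rowSums(!is.finite(sol)) > 0)
  if (length(bad) > 0) {
    abort(sprintf("integration produced a non-finite state at t = %g ms",
                  sol[bad[1], 1]))
  }
  out <- tibble::tibble(time = sol[, 1], V = sol[, 2], m = sol[, 3],
                        h = sol[, 4], n = sol[, 5])
  attr(out, "params") <- params
  attr(out, "dt") <- dt
  class(out) <- c("hh_trace", class(out))
  out
}

#' Classify the long-run attractor of a trace
#'
#' Discards the leading transient, measures the peak-to-trough
#' amplitude of V over the remaining window, and detects voltage peaks
#' to estimate a period.  The verdict is `"fixed_point"` when the
#' post-transient amplitude is below `lower_threshold`,
#' `"limit_cycle"` when the amplitude reaches `amplitude_threshold`
#' and at least three inter-peak intervals agree to a coefficient of
#' variation below 5%, and `"undetermined"` otherwise (in particular
#' in the slow-transient band between the two thresholds, which is
#' never silently forced into a class).
#'
#' @param trace An [hh_simulate()] result (or any data frame with
#'   `time` and `V` columns).
#' @param transient_fraction Fraction of the trace discarded as
#'   transient; the remaining window must cover at least 100 ms.
#' @param amplitude_threshold Peak-to-trough amplitude (mV) above
#'   which sustained oscillation is credited.
#' @param lower_threshold Amplitude (mV) below which the trace is
#'   called settled.
#' @return An object of class `hh_attractor`: list with `label`,
#'   `V_amplitude` (mV), `period_estimate` (ms, `NA` when no reliable
#'   peaks), `n_cycles`, `cv_period`, `final_state` and the analysis
#'   `window` (ms).  [tidy()] gives a one-row tibble.
#' @export
classify_attractor <- function(trace, transient_fraction = 0.5,
                               amplitude_threshold = 1,
                               lower_threshold = 0.1) {
  if (!is.data.frame(trace) || !all(c("time", "V") %in% names(trace))) {
    abort("trace must have time and V columns")
  }
  if (transient_fraction < 0 || transient_fraction >= 1) {
    abort("transient_fraction must lie in [0, 1)")
  }
  t0 <- trace$time[1] +
    transient_fraction * (trace$time[nrow(trace)] - trace$time[1])
  win <- trace[trace$time >= t0, ]
  if (nrow(win) < 10 || (max(win$time) - min(win$time)) < 100) {
    abort("post-transient window shorter than 100 ms; simulate longer")
  }

  amp <- max(win$V) - min(win$V)
  period <- NA_real_
  n_cycles <- 0L
  cv <- NA_real_
  if (amp > lower_threshold) {
    pk <- peak_indices(win$V)
    pk <- pk[win$V[pk] >= min(win$V) + 0.5 * amp]
    if (length(pk) >= 2) {
      pk_t <- win$time[pk]
      gaps <- diff(sort(pk_t))
      n_cycles <- length(gaps)
      period <- mean(gaps)
      cv <- if (n_cycles >= 2) sd(gaps) / period else NA_real_
    }
  }

  label <- if (amp < lower_threshold) {
    "fixed_point"
  } else if (amp >= amplitude_threshold &&
             n_cycles >= 3 && is.finite(cv) && cv < 0.05) {
    "limit_cycle"
  } else {
    "undetermined"
  }

  cols <- intersect(c("V", "m", "h", "n"), names(trace))
  structure(
    list(label = label,
         V_amplitude = amp,
         period_estimate = period,
         n_cycles = n_cycles,
         cv_period = cv,
         final_state = unlist(trace[nrow(trace), cols]),
         window = c(t0, max(win$time))),
    class = "hh_attractor"
  )
}

#' @export
print.hh_attractor <- function(x, ...) {
  cat(sprintf("<hh_attractor>  %s\n", x$label))
  cat(sprintf("  V amplitude %.4g mV over [%g, %g] ms", x$V_amplitude,
              x$window[1], x$window[2]))
  if (is.finite(x$period_estimate)) {
    cat(sprintf(";  period %.4g ms (%d cycles, cv %.3g)",
                x$period_estimate, x$n_cycles, x$cv_period))
  }
  cat("\n")
  invisible(x)
}

#' @rdname classify_attractor
#' @param x An `hh_attractor` object.
#' @param ... Unused.
#' @export
tidy.hh_attractor <- function(x, ...) {
  tibble::tibble(
    label = x$label,
    V_amplitude = x$V_amplitude,
    period_estimate = x$period_estimate,
    n_cycles = x$n_cycles,
    cv_period = x$cv_period
  )
}

#' Write a simulation trace to CSV
#'
#' Columns `t, V, m, h, n`, one row per saved step.
#'
#' @param trace An [hh_simulate()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(is.data.frame(trace))
  out <- tibble::tibble(t = trace$time, V = trace$V, m = trace$m,
                        h = trace$h, n = trace$n)
  readr::write_csv(out, path)
  invisible(path)
}
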