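# Gate kinetics of the Hodgkin-Huxley model (depolarization-positive
# convention).  alpha_m and alpha_n have removable singularities at
# V = 25 and V = 10 mV; both are evaluated through ratio_x10() below.
# The *_raw helpers return plain numeric lists and skip validation;
# they are the hot path for root scans and integration.

# x / (1 - exp(-x/10)) with the analytic limit 10 at x = 0.
# Second-order Taylor branch for |x| < 1e-7; elsewhere expm1 keeps the
# denominator accurate for small x.
ratio_x10 <- function(x) {
  out <- x
  small <- abs(x) < 1e-7
  if (any(small)) {
    xs <- x[small]
    out[small] <- 10 + xs / 2 + xs^2 / 120
  }
  xl <- x[!small]
  out[!small] <- xl / (-expm1(-xl / 10))
  out
}

# d/dx of ratio_x10, same Taylor switch (series 1/2 + x/60 + O(x^3)).
ratio_x10_deriv <- function(x) {
  out <- x
  small <- abs(x) < 1e-7
  if (any(small)) {
    xs <- x[small]
    out[small] <- 1 / 2 + xs / 60
  }
  xl <- x[!small]
  D <- -expm1(-xl / 10)            # 1 - exp(-x/10)
  out[!small] <- (D - xl * (1 - D) / 10) / D^2
  out
}

rates_raw <- function(V) {
  list(
    alpha_m = 0.1 * ratio_x10(V - 25),
    beta_m  = 4 * exp(-V / 18),
    alpha_h = 0.07 * exp(-V / 20),
    beta_h  = 1 / (1 + exp(-(V - 30) / 10)),
    alpha_n = 0.01 * ratio_x10(V - 10),
    beta_n  = 0.125 * exp(-V / 80)
  )
}

rate_derivs_raw <- function(V) {
  Eb <- exp(-(V - 30) / 10)
  list(
    dalpha_m = 0.1 * ratio_x10_deriv(V - 25),
    dbeta_m  = -4 / 18 * exp(-V / 18),
    dalpha_h = -0.07 / 20 * exp(-V / 20),
    dbeta_h  = Eb / 10 / (1 + Eb)^2,
    dalpha_n = 0.01 * ratio_x10_deriv(V - 10),
    dbeta_n  = -0.125 / 80 * exp(-V / 80)
  )
}

ss_raw <- function(V) {
  r <- rates_raw(V)
  list(m = r$alpha_m / (r$alpha_m + r$beta_m),
       h = r$alpha_h / (r$alpha_h + r$beta_h),
       n = r$alpha_n / (r$alpha_n + r$beta_n))
}

check_finite_V <- function(V) {
  if (!is.numeric(V) || length(V) < 1L || any(!is.finite(V))) {
    abort("membrane potential V must be finite")
  }
  invisible(V)
}

#' Gate opening and closing rates
#'
#' First-order transition rates (1/ms) of the three Hodgkin-Huxley
#' gating variables as functions of membrane potential.  The removable
#' singularities of `alpha_m` (at V = 25 mV) and `alpha_n` (at
#' V = 10 mV) are evaluated by their analytic limits, so all six rates
#' are finite and strictly positive over the physiological range.
#'
#' @param V Membrane potential (mV); vectorized.
#' @return A tibble with columns `V`, `alpha_m`, `beta_m`, `alpha_h`,
#'   `beta_h`, `alpha_n`, `beta_n`.
#' @examples
#' gate_rates(c(0, 10, 25))
#' @export
gate_rates <- function(V) {
  check_finite_V(V)
  r <- rates_raw(V)
  tibble::tibble(V = V, alpha_m = r$alpha_m, beta_m = r$beta_m,
                 alpha_h = r$alpha_h, beta_h = r$beta_h,
                 alpha_n = r$alpha_n, beta_n = r$beta_n)
}

#' Gate steady states
#'
#' Voltage-dependent steady-state values `x_inf = alpha_x / (alpha_x +
#' beta_x)` of the three gating variables; each lies strictly inside
#' (0, 1).
#'
#' @inheritParams gate_rates
#' @return A tibble with columns `V`, `m_inf`, `h_inf`, `n_inf`.
#' @examples
#' gate_steady_state(0)
#' @export
gate_steady_state <- function(V) {
  check_finite_V(V)
  s <- ss_raw(V)
  tibble::tibble(V = V, m_inf = s$m, h_inf = s$h, n_inf = s$n)
}

as_hh_state <- function(state) {
  if (is.data.frame(state)) {
    if (nrow(state) != 1L) abort("state must be a single state")
    nm <- if (all(c("V", "m", "h", "n") %in% names(state))) {
      c("V", "m", "h", "n")
    } else {
      c("V_star", "m_star", "h_star", "n_star")
    }
    state <- unlist(state[1, nm], use.names = FALSE)
  }
  state <- as.numeric(state)
  if (length(state) != 4L || any(!is.finite(state))) {
    abort("state must be four finite numbers (V, m, h, n)")
  }
  names(state) <- c("V", "m", "h", "n")
  state
}

# Unvalidated right-hand side, shared by hh_rhs() and the integrator.
hh_rhs_raw <- function(V, m, h, n, p) {
  r <- rates_raw(V)
  dV <- (p$i_ext -
           p$g_Na * m^3 * h * (V - p$V_Na) -
           p$g_K * n^4 * (V - p$V_K) -
           p$g_l * (V - p$V_l)) / p$C_M
  c(V = dV,
    m = r$alpha_m * (1 - m) - r$beta_m * m,
    h = r$alpha_h * (1 - h) - r$beta_h * h,
    n = r$alpha_n * (1 - n) - r$beta_n * n)
}

#' Hodgkin-Huxley vector field
#'
#' Time-derivatives of the four state variables (V, m, h, n): the
#' membrane current balance divided by the capacitance, and the three
#' first-order gate relaxation equations.  `dV/dt` is in mV/ms, gate
#' derivatives in 1/ms.
#'
#' @param state Numeric vector `(V, m, h, n)` (named or positional), or
#'   a one-row data frame with those columns (also accepts the
#'   `*_star` columns returned by [find_equilibria()]).  Gates must lie
#'   in \[0, 1\].
#' @param params An [hh_params()] object.
#' @return Named numeric vector of the four derivatives
#'   `(V, m, h, n)`.
#' @examples
#' ss <- gate_steady_state(0)
#' hh_rhs(c(0, ss$m_inf, ss$h_inf, ss$n_inf), hh_params())
#' @export
hh_rhs <- function(state, params) {
  validate_hh_params(params)
  s <- as_hh_state(state)
  g <- s[c("m", "h", "n")]
  if (any(g < -1e-9) || any(g > 1 + 1e-9)) {
    abort("gating variables m, h, n must lie in [0, 1]")
  }
  hh_rhs_raw(s[["V"]], s[["m"]], s[["h"]], s[["n"]], params)
}
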