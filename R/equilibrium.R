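# Equilibria of the model.  With the gates slaved to their steady
# states every equilibrium is a root of a scalar current-balance
# equation in V; roots are bracketed on a uniform grid and refined by
# bisection.  mcr_raw()/equilibria_V() are the unvalidated hot path.

mcr_raw <- function(V, p) {
  s <- ss_raw(V)
  p$i_ext -
    p$g_Na * s$m^3 * s$h * (V - p$V_Na) -
    p$g_K * s$n^4 * (V - p$V_K) -
    p$g_l * (V - p$V_l)
}

# All roots of the scalar current balance in V_range (numeric vector).
equilibria_V <- function(p, V_range = c(-50, 150), n_brackets = 2000) {
  grid <- seq(V_range[1], V_range[2], length.out = n_brackets + 1)
  r <- mcr_raw(grid, p)
  if (any(!is.finite(r))) abort("non-finite current residual encountered in scan")
  s <- sign(r)
  roots <- grid[s == 0]
  idx <- which(s[-length(s)] * s[-1] < 0)
  if (length(idx) > 0) {
    lo <- grid[idx]
    hi <- grid[idx + 1]
    slo <- s[idx]
    # vectorized bisection across all brackets to width < 1e-12 mV
    while (max(hi - lo) > 1e-12) {
      mid <- (lo + hi) / 2
      smid <- sign(mcr_raw(mid, p))
      take_lo <- smid == slo
      lo <- ifelse(take_lo, mid, lo)
      hi <- ifelse(take_lo, hi, mid)
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  roots <- sort(roots)
  if (length(roots) > 1) roots <- roots[c(TRUE, diff(roots) > 1e-8)]
  roots
}

#' Steady-state membrane current balance
#'
#' The net membrane current (uA/cm^2) at potential `V` with all three
#' gates at their voltage-dependent steady states:
#' `i_ext - g_Na m_inf^3 h_inf (V - V_Na) - g_K n_inf^4 (V - V_K) -
#' g_l (V - V_l)`.  Equilibria of the full four-dimensional model are
#' exactly the zeros of this function.
#'
#' @param V Membrane potential (mV); vectorized.
#' @param params An [hh_params()] object.
#' @return Numeric vector of residual currents, one per element of `V`.
#' @examples
#' membrane_current_residual(seq(-20, 40, by = 10), hh_params())
#' @export
membrane_current_residual <- function(V, params) {
  validate_hh_params(params)
  check_finite_V(V)
  mcr_raw(V, params)
}

# Full state at a candidate equilibrium potential.
equilibrium_row <- function(V, params) {
  s <- ss_raw(V)
  st <- c(V, s$m, s$h, s$n)
  tibble::tibble(
    V_star = V,
    m_star = s$m,
    h_star = s$h,
    n_star = s$n,
    residual = max(abs(hh_rhs(st, params)))
  )
}

#' Find all equilibria of the model
#'
#' Scans the steady-state current balance
#' ([membrane_current_residual()]) on a uniform grid over `V_range`,
#' brackets every sign change and refines each bracket by bisection to
#' a width below 1e-12 mV.  Gate values at each root are filled in from
#' [gate_steady_state()], so the returned points satisfy the gate
#' equations exactly by construction.
#'
#' @param params An [hh_params()] object.
#' @param V_range Length-2 numeric, the potential interval scanned
#'   (mV).  The default comfortably contains all physiological
#'   equilibria over the conductance ranges this package scans.
#' @param n_brackets Number of grid intervals (at least 100).
#' @return A tibble with one row per distinct equilibrium, sorted by
#'   `V_star`: columns `V_star`, `m_star`, `h_star`, `n_star` and
#'   `residual` (the largest absolute component of the vector field at
#'   the point).  Zero rows when no sign change is found.
#' @examples
#' find_equilibria(hh_params())
#' @export
find_equilibria <- function(params, V_range = c(-50, 150), n_brackets = 2000) {
  validate_hh_params(params)
  if (length(V_range) != 2L || !all(is.finite(V_range)) || V_range[1] >= V_range[2]) {
    abort("V_range must be a finite increasing interval")
  }
  if (n_brackets < 100) abort("n_brackets must be at least 100")
  roots <- equilibria_V(params, V_range, n_brackets)
  if (length(roots) == 0) {
    return(tibble::tibble(V_star = double(), m_star = double(),
                          h_star = double(), n_star = double(),
                          residual = double()))
  }
  dplyr::bind_rows(lapply(roots, equilibrium_row, params = params))
}

#' Equilibrium tracked from a reference potential
#'
#' When several equilibria coexist, downstream stability analysis
#' follows the branch continuously connected to the canonical resting
#' state; this helper selects the root nearest a reference potential
#' (the previous point of a continuation scan, or 0 mV).
#'
#' @inheritParams find_equilibria
#' @param V_ref Reference potential (mV).
#' @return One row of the [find_equilibria()] tibble.
#' @export
tracked_equilibrium <- function(params, V_ref = 0, V_range = c(-50, 150),
                                n_brackets = 2000) {
  validate_hh_params(params)
  roots <- equilibria_V(params, V_range, n_brackets)
  if (length(roots) == 0) {
    abort("no equilibrium found in V_range")
  }
  equilibrium_row(roots[which.min(abs(roots - V_ref))], params)
}
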