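# Linear stability at an equilibrium: analytic Jacobian, quartic
# characteristic coefficients, eigenvalues, Routh-Hurwitz verdict.

#' Analytic Jacobian at an equilibrium
#'
#' The 4x4 Jacobian of the vector field in state order (V, m, h, n),
#' derived in closed form from the model equations.  Rows 2-4 (the
#' gate equations) are nonzero only in the V column and on the
#' diagonal, because each gate relaxes independently at fixed V:
#' `J_x1 = alpha_x'(V)(1 - x) - beta_x'(V) x` and
#' `J_xx = -(alpha_x(V) + beta_x(V))`.
#'
#' @param params An [hh_params()] object.
#' @param equilibrium An equilibrium: one row of [find_equilibria()]
#'   output, a numeric `(V, m, h, n)` vector, or a single potential
#'   (gates then filled from [gate_steady_state()]).  The point must
#'   satisfy the equilibrium equations to within `tol`; linearization
#'   is meaningless elsewhere.
#' @param tol Largest admissible absolute vector-field component at the
#'   point.
#' @return A 4x4 numeric matrix with dimnames `c("V","m","h","n")`.
#' @examples
#' p <- hh_params()
#' hh_jacobian(p, tracked_equilibrium(p))
#' @export
hh_jacobian <- function(params, equilibrium, tol = 1e-6) {
  validate_hh_params(params)
  if (is.numeric(equilibrium) && length(equilibrium) == 1L) {
    ss <- gate_steady_state(equilibrium)
    st <- c(equilibrium, ss$m_inf, ss$h_inf, ss$n_inf)
  } else {
    st <- as_hh_state(equilibrium)
  }
  if (max(abs(hh_rhs(st, params))) > tol) {
    abort("point is not an equilibrium to the requested tolerance")
  }
  jacobian_raw(params, st[["V"]], st[["m"]], st[["h"]], st[["n"]])
}

# Closed-form Jacobian entries; no validation (hot path).
jacobian_raw <- function(p, V, m = NULL, h = NULL, n = NULL) {
  if (is.null(m)) {
    s <- ss_raw(V)
    m <- s$m; h <- s$h; n <- s$n
  }
  r <- rates_raw(V)
  d <- rate_derivs_raw(V)
  J <- matrix(0, 4, 4, dimnames = list(c("V", "m", "h", "n"),
                                       c("V", "m", "h", "n")))
  J[1, 1] <- -(p$g_Na * m^3 * h + p$g_K * n^4 + p$g_l) / p$C_M
  J[1, 2] <- -3 * p$g_Na * m^2 * h * (V - p$V_Na) / p$C_M
  J[1, 3] <- -p$g_Na * m^3 * (V - p$V_Na) / p$C_M
  J[1, 4] <- -4 * p$g_K * n^3 * (V - p$V_K) / p$C_M
  J[2, 1] <- d$dalpha_m * (1 - m) - d$dbeta_m * m
  J[2, 2] <- -(r$alpha_m + r$beta_m)
  J[3, 1] <- d$dalpha_h * (1 - h) - d$dbeta_h * h
  J[3, 3] <- -(r$alpha_h + r$beta_h)
  J[4, 1] <- d$dalpha_n * (1 - n) - d$dbeta_n * n
  J[4, 4] <- -(r$alpha_n + r$beta_n)
  J
}

check_structured <- function(J, tol = 0) {
  if (!is.matrix(J) || !all(dim(J) == c(4, 4)) || !is.numeric(J)) {
    abort("J must be a numeric 4x4 matrix")
  }
  zero_idx <- rbind(c(2, 3), c(2, 4), c(3, 2), c(3, 4), c(4, 2), c(4, 3))
  if (any(abs(J[zero_idx]) > tol)) {
    abort("J lacks the gate-equation sparsity (rows 2-4 nonzero only in column 1 and the diagonal)")
  }
  invisible(J)
}

#' Characteristic polynomial coefficients
#'
#' Closed-form coefficients (a, b, c, d) of the monic quartic
#' `lambda^4 + a lambda^3 + b lambda^2 + c lambda + d` of a Jacobian
#' with the gate-equation sparsity, obtained by expanding
#' `det(lambda I - J)` along the structural zeros.  Kept as an
#' independent representation of the spectrum because the
#' Routh-Hurwitz stability argument runs through these coefficients.
#'
#' @param J 4x4 numeric matrix with zeros at the off-diagonal,
#'   off-column-1 positions of rows 2-4.
#' @return Named numeric vector `c(a, b, c, d)`.
#' @examples
#' characteristic_coefficients(diag(c(-1, -2, -3, -4)))
#' @export
characteristic_coefficients <- function(J) {
  check_structured(J)
  if (any(!is.finite(J))) abort("J must have finite entries")
  J11 <- J[1, 1]; J22 <- J[2, 2]; J33 <- J[3, 3]; J44 <- J[4, 4]
  p12 <- J[1, 2] * J[2, 1]
  p13 <- J[1, 3] * J[3, 1]
  p14 <- J[1, 4] * J[4, 1]
  a <- -(J11 + J22 + J33 + J44)
  b <- J11 * (J22 + J33 + J44) + J22 * (J33 + J44) + J33 * J44 -
    p12 - p13 - p14
  c_ <- p12 * (J33 + J44) + p13 * (J22 + J44) + p14 * (J22 + J33) -
    J11 * J22 * (J33 + J44) - (J11 + J22) * J33 * J44
  d <- J11 * J22 * J33 * J44 - p12 * J33 * J44 - p13 * J22 * J44 -
    p14 * J22 * J33
  c(a = a, b = b, c = c_, d = d)
}

#' Jacobian eigenvalues
#'
#' The four roots of the characteristic equation, computed by a dense
#' eigensolver (not the quartic formula) and returned sorted by
#' decreasing real part (ties by decreasing imaginary part).  Complex
#' eigenvalues come in conjugate pairs since the matrix is real.
#'
#' @param J 4x4 numeric matrix with finite entries.
#' @return Complex vector of length 4.
#' @examples
#' hh_eigenvalues(diag(c(-1, -2, -3, -4)))
#' @export
hh_eigenvalues <- function(J) {
  if (!is.matrix(J) || !all(dim(J) == c(4, 4)) || !is.numeric(J)) {
    abort("J must be a numeric 4x4 matrix")
  }
  if (any(!is.finite(J))) abort("J must have finite entries")
  ev <- as.complex(eigen(J, only.values = TRUE)$values)
  ev[order(-Re(ev), -Im(ev))]
}

#' Routh-Hurwitz stability verdict for a quartic
#'
#' For `lambda^4 + a lambda^3 + b lambda^2 + c lambda + d`, all roots
#' have negative real parts if and only if `a > 0`, `ab > c`, `d > 0`
#' and `abc > c^2 + a^2 d`.  The four tested quantities are `a`,
#' `ab - c`, `d` and `abc - c^2 - a^2 d`; if any lies within
#' `boundary_tol` of zero the verdict is `"boundary"` rather than a
#' possibly spurious sign call.
#'
#' @param a Either the coefficient `a`, or the full named vector
#'   returned by [characteristic_coefficients()].
#' @param b,c,d Remaining coefficients when `a` is scalar.
#' @param boundary_tol Half-width of the indeterminate band around each
#'   threshold.
#' @return `"stable"`, `"unstable"` or `"boundary"`.
#' @examples
#' routh_hurwitz(10, 35, 50, 24)
#' @export
routh_hurwitz <- function(a, b = NULL, c = NULL, d = NULL,
                          boundary_tol = 1e-10) {
  if (is.null(b)) {
    co <- a
    if (length(co) != 4L) abort("expected four coefficients (a, b, c, d)")
    a <- co[[1]]; b <- co[[2]]; c <- co[[3]]; d <- co[[4]]
  }
  q <- c(a, a * b - c, d, a * b * c - c^2 - a^2 * d)
  if (any(!is.finite(q))) abort("coefficients must be finite")
  if (any(abs(q) <= boundary_tol)) return("boundary")
  if (all(q > 0)) "stable" else "unstable"
}

#' Full linear stability report at an equilibrium
#'
#' Bundles the analytic Jacobian, characteristic coefficients,
#' eigenvalues, largest eigenvalue real part and the Routh-Hurwitz
#' verdict at the tracked equilibrium (or a supplied one).
#'
#' @param params An [hh_params()] object.
#' @param equilibrium Optional equilibrium (see [hh_jacobian()]);
#'   defaults to the equilibrium tracked from `V_ref`.
#' @param V_ref Reference potential for [tracked_equilibrium()].
#' @return An object of class `hh_stability` with fields
#'   `params`, `equilibrium` (one-row tibble), `jacobian`,
#'   `char_coeffs`, `eigenvalues`, `max_real_part` and `verdict`.
#'   [tidy()] returns the eigenvalues as a tibble, [glance()] a
#'   one-row summary.
#' @examples
#' rep <- stability_report(hh_params())
#' rep
#' glance(rep)
#' @export
stability_report <- function(params, equilibrium = NULL, V_ref = 0) {
  validate_hh_params(params)
  if (is.null(equilibrium)) {
    equilibrium <- tracked_equilibrium(params, V_ref = V_ref)
  }
  if (is.numeric(equilibrium) && length(equilibrium) == 1L) {
    equilibrium <- equilibrium_row(equilibrium, params)
  }
  J <- hh_jacobian(params, equilibrium)
  co <- characteristic_coefficients(J)
  ev <- hh_eigenvalues(J)
  structure(
    list(params = params,
         equilibrium = tibble::as_tibble(equilibrium),
         jacobian = J,
         char_coeffs = co,
         eigenvalues = ev,
         max_real_part = max(Re(ev)),
         verdict = routh_hurwitz(co)),
    class = "hh_stability"
  )
}

#' @export
print.hh_stability <- function(x, ...) {
  cat("<hh_stability>\n")
  cat(sprintf("  equilibrium: V* = %.10g mV\n", x$equilibrium$V_star))
  cat(sprintf("  char. coeffs: a = %.6g, b = %.6g, c = %.6g, d = %.6g\n",
              x$char_coeffs[1], x$char_coeffs[2],
              x$char_coeffs[3], x$char_coeffs[4]))
  cat("  eigenvalues (1/ms):\n")
  for (ev in x$eigenvalues) {
    re <- Re(ev)
    note <- if (abs(re) <= 1e-8 && Im(ev) != 0) "  (real part 0-consistent)" else ""
    cat(sprintf("    %+.10g %+.10gi%s\n", re, Im(ev), note))
  }
  cat(sprintf("  max real part: %.6g;  Routh-Hurwitz: %s\n",
              x$max_real_part, x$verdict))
  invisible(x)
}

#' @rdname stability_report
#' @param x An `hh_stability` object.
#' @param ... Unused.
#' @export
tidy.hh_stability <- function(x, ...) {
  tibble::tibble(
    eigenvalue = seq_along(x$eigenvalues),
    real = Re(x$eigenvalues),
    imag = Im(x$eigenvalues)
  )
}

#' @rdname stability_report
#' @export
glance.hh_stability <- function(x, ...) {
  tibble::tibble(
    V_star = x$equilibrium$V_star,
    a = x$char_coeffs[["a"]], b = x$char_coeffs[["b"]],
    c = x$char_coeffs[["c"]], d = x$char_coeffs[["d"]],
    max_real_part = x$max_real_part,
    verdict = x$verdict,
    stable = x$verdict == "stable"
  )
}

#' Serialize a stability report to JSON
#'
#' Writes the Jacobian (row-major), characteristic coefficients,
#' eigenvalues as `[re, im]` pairs, the equilibrium and the verdict.
#'
#' @param report An object from [stability_report()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stability_report <- function(report, path) {
  stopifnot(inherits(report, "hh_stability"))
  obj <- list(
    equilibrium = as.list(report$equilibrium),
    jacobian = as.vector(t(report$jacobian)),
    char_coeffs = as.list(report$char_coeffs),
    eigenvalues = lapply(report$eigenvalues, function(ev) c(Re(ev), Im(ev))),
    max_real_part = report$max_real_part,
    verdict = report$verdict
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 12)
  invisible(path)
}
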