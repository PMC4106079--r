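# Hopf-point location by bisection on the stability margin,
# one-parameter equilibrium/stability curves, and the two-parameter
# (g_Na, g_K) stability map with a least-squares fit of its upper
# boundary.

# Margin plus the equilibrium potential it was evaluated at (for
# continuation).  Unvalidated hot path shared by the sweeps.
margin_at <- function(params, V_ref = 0, V_range = c(-50, 150),
                      n_brackets = 2000) {
  roots <- equilibria_V(params, V_range, n_brackets)
  if (length(roots) == 0) abort("no equilibrium found in V_range")
  V <- roots[which.min(abs(roots - V_ref))]
  J <- jacobian_raw(params, V)
  ev <- as.complex(eigen(J, only.values = TRUE)$values)
  ev <- ev[order(-Re(ev), -Im(ev))]
  list(margin = max(Re(ev)), eigenvalues = ev,
       verdict = routh_hurwitz(characteristic_coefficients(J)),
       V_star = V)
}

#' Stability margin of the tracked equilibrium
#'
#' Largest real part (1/ms) among the Jacobian eigenvalues at the
#' tracked equilibrium; negative means locally asymptotically stable.
#'
#' @inheritParams tracked_equilibrium
#' @return A single number.
#' @examples
#' stability_margin(hh_params())               # stable resting state
#' stability_margin(update(hh_params(), g_Na = 250))  # unstable
#' @export
stability_margin <- function(params, V_ref = 0, V_range = c(-50, 150),
                             n_brackets = 2000) {
  margin_at(params, V_ref = V_ref, V_range = V_range,
            n_brackets = n_brackets)$margin
}

#' Locate a Hopf bifurcation by bisection
#'
#' Bisects one maximal conductance on the sign of the stability margin
#' until the bracket is narrower than `tol`, then reports the bracket
#' midpoint together with the eigenvalues there.  At a genuine Hopf
#' point the leading conjugate pair sits on the imaginary axis with a
#' nonzero frequency while the remaining eigenvalues stay strictly in
#' the left half-plane.
#'
#' @param params Base [hh_params()]; the swept field is overridden.
#' @param param Which conductance to sweep: `"g_Na"` or `"g_K"`.
#' @param bracket Length-2 interval (mS/cm^2) whose endpoints must give
#'   opposite stability verdicts.
#' @param tol Bracket width at which bisection stops (mS/cm^2); the
#'   default resolves the critical value to about nine digits.
#' @param V_ref Starting reference potential for equilibrium tracking;
#'   the tracked branch is continued across bisection iterates.
#' @return An object of class `hh_hopf`: list with `param_name`,
#'   `critical_value`, `bracket`, `tol`, `eigenvalues_at_point`,
#'   `frequency` (the |imaginary part| of the critical pair, 1/ms) and
#'   the full `report` ([stability_report()]) at the point.  [tidy()]
#'   gives a one-row tibble.
#' @examples
#' \donttest{
#' find_hopf(hh_params(), "g_Na", c(0, 500))
#' }
#' @export
find_hopf <- function(params, param = c("g_Na", "g_K"), bracket,
                      tol = 1e-9, V_ref = 0) {
  validate_hh_params(params)
  param <- match.arg(param)
  if (length(bracket) != 2L || !all(is.finite(bracket)) ||
      bracket[1] >= bracket[2]) {
    abort("bracket must be a finite increasing interval")
  }
  if (!is.finite(tol) || tol <= 0) abort("tol must be positive")

  set_p <- function(v) {
    upd <- stats::setNames(list(v), param)
    do.call(update, c(list(params), upd))
  }
  lo <- bracket[1]; hi <- bracket[2]
  m_lo <- margin_at(set_p(lo), V_ref = V_ref)
  m_hi <- margin_at(set_p(hi), V_ref = V_ref)
  if (sign(m_lo$margin) == sign(m_hi$margin)) {
    abort("bracket endpoints have the same stability verdict; no sign change to bisect")
  }
  V_ref_cur <- m_lo$V_star
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    m_mid <- margin_at(set_p(mid), V_ref = V_ref_cur)
    V_ref_cur <- m_mid$V_star
    if (sign(m_mid$margin) == sign(m_lo$margin)) {
      lo <- mid
      m_lo <- m_mid
    } else {
      hi <- mid
    }
  }
  critical <- (lo + hi) / 2
  rep <- stability_report(set_p(critical), V_ref = V_ref_cur)
  ev <- rep$eigenvalues
  pair <- ev[Im(ev) != 0]
  freq <- if (length(pair) > 0) max(abs(Im(pair))) else NA_real_
  structure(
    list(param_name = param,
         critical_value = critical,
         bracket = c(lo, hi),
         tol = tol,
         eigenvalues_at_point = ev,
         frequency = freq,
         report = rep),
    class = "hh_hopf"
  )
}

#' @export
print.hh_hopf <- function(x, ...) {
  cat("<hh_hopf>  Hopf bifurcation point\n")
  cat(sprintf("  %s* = %.12g mS/cm^2  (bracket width %.3g)\n",
              x$param_name, x$critical_value, diff(x$bracket)))
  cat(sprintf("  critical pair: %+.3g +/- %.10gi (1/ms)\n",
              max(Re(x$eigenvalues_at_point[Im(x$eigenvalues_at_point) != 0])),
              x$frequency))
  invisible(x)
}

#' @rdname find_hopf
#' @param x An `hh_hopf` object.
#' @param ... Unused.
#' @export
tidy.hh_hopf <- function(x, ...) {
  tibble::tibble(
    param_name = x$param_name,
    critical_value = x$critical_value,
    frequency = x$frequency,
    V_star = x$report$equilibrium$V_star,
    bracket_width = diff(x$bracket)
  )
}

#' One-parameter equilibrium and stability curve
#'
#' Sweeps one conductance over a grid, tracking the equilibrium by
#' nearest-potential continuation from point to point, and reports the
#' equilibrium state, stability margin and Routh-Hurwitz verdict at
#' each grid value.
#'
#' @inheritParams find_hopf
#' @param values Numeric grid of conductances, swept in the order
#'   given (continuation follows this order).
#' @param V_ref Reference potential used for the first grid point.
#' @return A tibble with columns `param_name`, `param_value`,
#'   `V_star`, `m_star`, `h_star`, `n_star`, `residual`, `margin`,
#'   `verdict`, `stable`.
#' @examples
#' \donttest{
#' equilibrium_curve(hh_params(), "g_Na", seq(0, 500, by = 10))
#' }
#' @export
equilibrium_curve <- function(params, param = c("g_Na", "g_K"), values,
                              V_ref = 0) {
  validate_hh_params(params)
  param <- match.arg(param)
  if (length(values) < 1L || any(!is.finite(values))) {
    abort("values must be a nonempty finite grid")
  }
  rows <- vector("list", length(values))
  for (i in seq_along(values)) {
    p <- do.call(update, c(list(params), stats::setNames(list(values[i]), param)))
    m <- margin_at(p, V_ref = V_ref)
    V_ref <- m$V_star
    rows[[i]] <- dplyr::mutate(
      equilibrium_row(m$V_star, p),
      param_name = param, param_value = values[i],
      margin = m$margin, verdict = m$verdict,
      stable = m$verdict == "stable",
      .before = 1
    )
  }
  dplyr::bind_rows(rows)
}

#' Two-parameter stability map over (g_Na, g_K)
#'
#' Evaluates the Routh-Hurwitz verdict of the tracked equilibrium on a
#' rectangular conductance grid, then refines every coarse
#' stable/unstable transition along each g_Na column by bisection in
#' g_K.  Within a column the transition points are tagged `"upper"`
#' (the topmost transition, provided stability is regained as g_K
#' increases through it -- the branch that traces the straight upper
#' edge of the stable region) or `"lower"` (the irregular lower
#' boundary).  Columns whose upper Hopf branch lies above `gK_range`
#' contribute no upper point.
#'
#' @param params Base [hh_params()]; both conductances are overridden.
#' @param gNa_range,gK_range Scanned intervals (mS/cm^2).
#' @param n_gNa,n_gK Grid resolution (number of points per axis).  The
#'   defaults step g_Na by 2 and g_K by 0.5.
#' @param refine_tol Bisection tolerance for boundary refinement
#'   (mS/cm^2).
#' @param n_brackets Passed to the equilibrium scan at each cell.
#' @return An object of class `hh_stability_map`: list with `grid` (a
#'   tibble of `g_Na`, `g_K`, `margin`, `verdict`, `stable` in
#'   column-major order), `boundary` (tibble of refined `g_Na`, `g_K`,
#'   `branch`), the axis grids and `params`.  Grid cells where no
#'   equilibrium is found are kept with `NA` entries.
#' @examples
#' \donttest{
#' m <- stability_map(hh_params(), n_gNa = 21, n_gK = 31)
#' fit_upper_boundary(m)
#' }
#' @export
stability_map <- function(params, gNa_range = c(0, 400), gK_range = c(0, 60),
                          n_gNa = 201, n_gK = 121, refine_tol = 1e-6,
                          n_brackets = 2000) {
  validate_hh_params(params)
  if (n_gNa < 2 || n_gK < 2) abort("resolutions must be at least 2")
  gNa_grid <- seq(gNa_range[1], gNa_range[2], length.out = n_gNa)
  gK_grid <- seq(gK_range[1], gK_range[2], length.out = n_gK)

  cells <- vector("list", n_gNa)
  bpts <- list()

  for (i in seq_len(n_gNa)) {
    gNa <- gNa_grid[i]
    margin <- rep(NA_real_, n_gK)
    verdict <- rep(NA_character_, n_gK)
    Vs <- rep(NA_real_, n_gK)
    V_ref <- 0
    for (j in seq_len(n_gK)) {
      p <- update(params, g_Na = gNa, g_K = gK_grid[j])
      m <- tryCatch(
        margin_at(p, V_ref = V_ref, n_brackets = n_brackets),
        error = function(e) NULL
      )
      if (is.null(m)) next
      margin[j] <- m$margin
      verdict[j] <- m$verdict
      Vs[j] <- m$V_star
      V_ref <- m$V_star
    }
    # Routh-Hurwitz verdict decides the cell; a (measure-zero) boundary
    # verdict falls back on the eigenvalue sign.
    stable <- ifelse(is.na(verdict), NA,
                     ifelse(verdict == "boundary", margin < 0,
                            verdict == "stable"))

    # coarse transitions along this column, refined by bisection
    trans <- which(stable[-n_gK] != stable[-1] &
                     !is.na(stable[-n_gK]) & !is.na(stable[-1]))
    if (length(trans) > 0) {
      topmost <- max(trans)
      for (j in trans) {
        lo <- gK_grid[j]; hi <- gK_grid[j + 1]
        s_lo <- stable[j]
        V_ref_b <- Vs[j]
        while (hi - lo > refine_tol) {
          mid <- (lo + hi) / 2
          mm <- margin_at(update(params, g_Na = gNa, g_K = mid),
                          V_ref = V_ref_b, n_brackets = n_brackets)
          V_ref_b <- mm$V_star
          if ((mm$margin < 0) == s_lo) lo <- mid else hi <- mid
        }
        branch <- if (j == topmost && !stable[j] && stable[j + 1]) "upper" else "lower"
        bpts[[length(bpts) + 1]] <-
          tibble::tibble(g_Na = gNa, g_K = (lo + hi) / 2, branch = branch)
      }
    }
    cells[[i]] <- tibble::tibble(g_Na = gNa, g_K = gK_grid,
                                 margin = margin, verdict = verdict,
                                 stable = stable)
  }

  structure(
    list(grid = dplyr::bind_rows(cells),
         boundary = if (length(bpts) > 0) dplyr::bind_rows(bpts) else
           tibble::tibble(g_Na = double(), g_K = double(), branch = character()),
         gNa_grid = gNa_grid, gK_grid = gK_grid,
         params = params),
    class = "hh_stability_map"
  )
}

#' @export
print.hh_stability_map <- function(x, ...) {
  n_up <- sum(x$boundary$branch == "upper")
  cat("<hh_stability_map>\n")
  cat(sprintf("  grid: %d x %d over g_Na [%g, %g], g_K [%g, %g]\n",
              length(x$gNa_grid), length(x$gK_grid),
              min(x$gNa_grid), max(x$gNa_grid),
              min(x$gK_grid), max(x$gK_grid)))
  cat(sprintf("  stable cells: %d / %d  (%d NA)\n",
              sum(x$grid$stable, na.rm = TRUE), nrow(x$grid),
              sum(is.na(x$grid$stable))))
  cat(sprintf("  boundary points: %d upper, %d lower\n",
              n_up, nrow(x$boundary) - n_up))
  invisible(x)
}

#' Least-squares line through the upper stability boundary
#'
#' Ordinary least squares of g_K on g_Na over the refined upper-branch
#' boundary points of a stability map.  The lower boundary is
#' irregular and is never fitted.
#'
#' @param map An [stability_map()] result, or a data frame of boundary
#'   points with columns `g_Na`, `g_K` and optionally `branch` (rows
#'   with `branch != "upper"` are dropped).
#' @return An object of class `hh_boundary_fit`: list with `slope`,
#'   `intercept` (mS/cm^2), `rms_residual`, `n_points` and the
#'   underlying `lm` fit.  [tidy()] and [glance()] methods are
#'   provided.
#' @export
fit_upper_boundary <- function(map) {
  pts <- if (inherits(map, "hh_stability_map")) map$boundary else
    tibble::as_tibble(map)
  if (!all(c("g_Na", "g_K") %in% names(pts))) {
    abort("boundary points need columns g_Na and g_K")
  }
  if ("branch" %in% names(pts)) pts <- pts[pts$branch == "upper", ]
  if (nrow(pts) < 2) abort("need at least 2 upper boundary points to fit a line")
  fit <- stats::lm(g_K ~ g_Na, data = pts)
  res <- stats::residuals(fit)
  structure(
    list(slope = unname(coef(fit)[["g_Na"]]),
         intercept = unname(coef(fit)[["(Intercept)"]]),
         rms_residual = sqrt(mean(res^2)),
         n_points = nrow(pts),
         fit = fit),
    class = "hh_boundary_fit"
  )
}

#' @export
print.hh_boundary_fit <- function(x, ...) {
  cat("<hh_boundary_fit>\n")
  cat(sprintf("  g_K = %.6g * g_Na + (%.6g)   [%d points, rms %.3g]\n",
              x$slope, x$intercept, x$n_points, x$rms_residual))
  invisible(x)
}

#' @rdname fit_upper_boundary
#' @param x An `hh_boundary_fit` object.
#' @param ... Unused.
#' @export
tidy.hh_boundary_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @rdname fit_upper_boundary
#' @export
glance.hh_boundary_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 rms_residual = x$rms_residual, n_points = x$n_points)
}

#' Write stability-map products to disk
#'
#' The grid goes to CSV in long form (`g_Na, g_K, stable, margin`),
#' the boundary points to CSV (`g_Na, g_K, branch`) and a boundary fit
#' to JSON.
#'
#' @param map An [stability_map()] result.
#' @param grid_path,boundary_path CSV output paths (either may be
#'   `NULL` to skip).
#' @return The map, invisibly.
#' @export
write_stability_map <- function(map, grid_path = NULL, boundary_path = NULL) {
  stopifnot(inherits(map, "hh_stability_map"))
  if (!is.null(grid_path)) {
    readr::write_csv(map$grid[, c("g_Na", "g_K", "stable", "margin")], grid_path)
  }
  if (!is.null(boundary_path)) {
    readr::write_csv(map$boundary, boundary_path)
  }
  invisible(map)
}

#' @param fit An [fit_upper_boundary()] result.
#' @param path JSON output path.
#' @rdname write_stability_map
#' @export
write_boundary_fit <- function(fit, path) {
  stopifnot(inherits(fit, "hh_boundary_fit"))
  jsonlite::write_json(
    list(slope = fit$slope, intercept = fit$intercept,
         rms_residual = fit$rms_residual, n_points = fit$n_points),
    path, auto_unbox = TRUE, digits = 12
  )
  invisible(path)
}
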