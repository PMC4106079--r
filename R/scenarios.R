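# Scenario generation: the analysis consumes parameter sets, not
# measurements, so everything the tests and examples run on is built
# here -- the canonical squid-axon set, the five single-override case
# studies, seeded random conductance draws, and random matrices with
# the gate-equation sparsity for oracle testing of the linear algebra.

# Default seed; kept fixed so documented runs reproduce exactly.
.default_seed <- 20140703L

#' Canonical parameter set
#'
#' The classic squid-axon values: `g_Na = 120`, `g_K = 36`,
#' `g_l = 0.3` mS/cm^2, `C_M = 1` uF/cm^2, no injected current, with
#' the package's default reversal potentials.
#'
#' @return An [hh_params()] object.
#' @examples
#' canonical_parameters()
#' @export
canonical_parameters <- function() {
  hh_params()
}

#' Single-conductance case studies
#'
#' The five benchmark scenarios in which exactly one maximal
#' conductance is moved off its canonical value and the long-run
#' behaviour is known from the bifurcation structure: g_Na = 198
#' (below the sodium Hopf point, settles), g_Na = 250 (above it,
#' fires periodically), and g_K = 2.8 / 15 / 21 (below, between and
#' above the two potassium Hopf points: settle, fire, settle).
#'
#' @return A tibble with columns `name`, `param`, `value`,
#'   `expected_class` and a list-column `params` of ready-to-use
#'   [hh_params()] objects.
#' @examples
#' reference_cases()
#' @export
reference_cases <- function() {
  base <- canonical_parameters()
  spec <- tibble::tribble(
    ~name,       ~param,  ~value, ~expected_class,
    "gNa_198",   "g_Na",   198,   "fixed_point",
    "gNa_250",   "g_Na",   250,   "limit_cycle",
    "gK_2.8",    "g_K",    2.8,   "fixed_point",
    "gK_15",     "g_K",    15,    "limit_cycle",
    "gK_21",     "g_K",    21,    "fixed_point"
  )
  spec$params <- purrr::map2(spec$param, spec$value, function(pn, v) {
    do.call(update, c(list(base), stats::setNames(list(v), pn)))
  })
  spec
}

#' Random conductance draws
#'
#' Independent uniform draws of (g_Na, g_K) over a rectangle,
#' deterministic for a given seed; all other fields come from `base`.
#'
#' @param n Number of draws.
#' @param gNa_range,gK_range Sampling intervals (mS/cm^2).
#' @param seed Integer seed.
#' @param base Base [hh_params()] for the non-sampled fields.
#' @return A tibble with columns `g_Na`, `g_K` and a list-column
#'   `params`.
#' @examples
#' sample_parameters(3, seed = 1)
#' @export
sample_parameters <- function(n, gNa_range = c(0, 400), gK_range = c(0, 60),
                              seed = .default_seed,
                              base = canonical_parameters()) {
  if (!is.numeric(n) || n < 1) abort("n must be at least 1")
  if (gNa_range[1] > gNa_range[2] || gK_range[1] > gK_range[2] ||
      gNa_range[1] < 0 || gK_range[1] < 0) {
    abort("sampling ranges must be valid non-negative intervals")
  }
  draws <- withr::with_seed(as.integer(seed), {
    tibble::tibble(
      g_Na = stats::runif(n, gNa_range[1], gNa_range[2]),
      g_K = stats::runif(n, gK_range[1], gK_range[2])
    )
  })
  draws$params <- purrr::map2(draws$g_Na, draws$g_K, function(na, k) {
    update(base, g_Na = na, g_K = k)
  })
  draws
}

#' Random matrix with the gate-equation sparsity
#'
#' A 4x4 matrix whose rows 2-4 are nonzero only in column 1 and on the
#' diagonal -- the structure shared by every Jacobian of this model.
#' The ten free entries are iid N(0, 2) draws, giving a healthy mix of
#' stable and unstable spectra for oracle tests of the characteristic
#' coefficients and the Routh-Hurwitz criterion.
#'
#' @param seed Integer seed; the draw is deterministic per seed.
#' @return A 4x4 numeric matrix.
#' @examples
#' random_structured_matrix(seed = 1)
#' @export
random_structured_matrix <- function(seed = .default_seed) {
  withr::with_seed(as.integer(seed), {
    e <- stats::rnorm(10, mean = 0, sd = 2)
    J <- matrix(0, 4, 4)
    J[1, ] <- e[1:4]
    J[2, 1] <- e[5]; J[2, 2] <- e[6]
    J[3, 1] <- e[7]; J[3, 3] <- e[8]
    J[4, 1] <- e[9]; J[4, 4] <- e[10]
    J
  })
}

#' Write or read a scenario list
#'
#' Scenario tables serialize to YAML as a named list of flat
#' key-value parameter sets plus the expected class, the same dialect
#' [read_hh_config()] uses for single parameter sets.
#'
#' @param cases A tibble from [reference_cases()] (or of the same
#'   shape).
#' @param path Output YAML path.
#' @return `path` invisibly; `read_scenarios()` returns the tibble.
#' @export
write_scenarios <- function(cases, path) {
  obj <- lapply(seq_len(nrow(cases)), function(i) {
    c(unclass(cases$params[[i]]),
      list(expected_class = cases$expected_class[i]))
  })
  names(obj) <- cases$name
  yaml::write_yaml(obj, path, precision = 12)
  invisible(path)
}

#' @rdname write_scenarios
#' @export
read_scenarios <- function(path) {
  obj <- yaml::read_yaml(path)
  tibble::tibble(
    name = names(obj),
    expected_class = unname(purrr::map_chr(obj, "expected_class")),
    params = purrr::map(obj, function(o) {
      o$expected_class <- NULL
      do.call(hh_params, o)
    })
  )
}
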