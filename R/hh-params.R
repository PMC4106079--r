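#' Hodgkin-Huxley model parameters
#'
#' Constructs the full parameter set of the four-dimensional
#' Hodgkin-Huxley membrane model in the depolarization-positive
#' convention (resting potential near 0 mV).  The unit system is fixed
#' as mV, ms, mS/cm^2, uA/cm^2 and uF/cm^2, so the membrane equation
#' needs no conversion factors.
#'
#' Defaults are the classic squid-axon values: `g_Na = 120`,
#' `g_K = 36`, `g_l = 0.3` mS/cm^2, `C_M = 1` uF/cm^2 and no injected
#' current.  The reversal potentials default to `V_Na = 115`,
#' `V_K = -12` and `V_l = 10.599` mV; the leak reversal is calibrated so
#' that the resting equilibrium of the canonical set sits at
#' essentially 0 mV (see the methods vignette for the calibration).
#'
#' @param g_Na,g_K,g_l Maximal sodium, potassium and leak conductances
#'   (mS/cm^2); must be non-negative.
#' @param V_Na,V_K,V_l Reversal potentials (mV).
#' @param C_M Membrane capacitance (uF/cm^2); must be positive.
#' @param i_ext External current density (uA/cm^2).
#'
#' @return An object of class `hh_params`: a named list with the eight
#'   fields above.
#' @seealso [canonical_parameters()], [update.hh_params()],
#'   [read_hh_config()]
#' @examples
#' p <- hh_params()
#' p
#' update(p, g_K = 15)
#' @export
hh_params <- function(g_Na = 120, g_K = 36, g_l = 0.3,
                      V_Na = 115, V_K = -12, V_l = 10.599,
                      C_M = 1, i_ext = 0) {
  p <- list(g_Na = g_Na, g_K = g_K, g_l = g_l,
            V_Na = V_Na, V_K = V_K, V_l = V_l,
            C_M = C_M, i_ext = i_ext)
  validate_hh_params(p)
  structure(p, class = c("hh_params", "list"))
}

validate_hh_params <- function(p) {
  fields <- c("g_Na", "g_K", "g_l", "V_Na", "V_K", "V_l", "C_M", "i_ext")
  missing <- setdiff(fields, names(p))
  if (length(missing) > 0) {
    abort(paste0("missing parameter field(s): ", paste(missing, collapse = ", ")))
  }
  for (f in fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(paste0("parameter '", f, "' must be a single finite number"))
    }
  }
  if (p$g_Na < 0 || p$g_K < 0 || p$g_l < 0) {
    abort("conductances g_Na, g_K, g_l must be non-negative")
  }
  if (p$C_M <= 0) abort("membrane capacitance C_M must be positive")
  invisible(p)
}

#' Update fields of a parameter set
#'
#' @param object An [hh_params()] object.
#' @param ... Named fields to replace, e.g. `g_Na = 250`.
#' @return A new validated `hh_params` object.
#' @examples
#' update(hh_params(), g_Na = 250)
#' @export
update.hh_params <- function(object, ...) {
  new <- modifyList(unclass(object), list(...))
  do.call(hh_params, new)
}

#' @export
print.hh_params <- function(x, ...) {
  cat("<hh_params>  (mV, ms, mS/cm^2, uA/cm^2, uF/cm^2)\n")
  cat(sprintf("  g_Na = %g  g_K = %g  g_l = %g\n", x$g_Na, x$g_K, x$g_l))
  cat(sprintf("  V_Na = %g  V_K = %g  V_l = %g\n", x$V_Na, x$V_K, x$V_l))
  cat(sprintf("  C_M  = %g  i_ext = %g\n", x$C_M, x$i_ext))
  invisible(x)
}

#' @export
as.data.frame.hh_params <- function(x, ...) {
  as.data.frame(unclass(x))
}

#' Coerce a parameter set to a one-row tibble
#'
#' @param x An [hh_params()] object.
#' @param ... Unused.
#' @return A one-row tibble with one column per field.
#' @export
as_tibble.hh_params <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Read or write a parameter configuration file
#'
#' Parameter sets are stored as flat key-value files in YAML or JSON
#' (chosen from the file extension), with keys named exactly
#' `g_Na, g_K, g_l, V_Na, V_K, V_l, C_M, i_ext`.  Missing keys fall
#' back to the [hh_params()] defaults.
#'
#' @param path File path; `.json` selects JSON, anything else is parsed
#'   as YAML (of which JSON is a subset).
#' @return `read_hh_config()` returns an [hh_params()] object;
#'   `write_hh_config()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_hh_config(hh_params(g_K = 15), f)
#' read_hh_config(f)
#' @export
read_hh_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("g_Na", "g_K", "g_l", "V_Na", "V_K", "V_l", "C_M", "i_ext")
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0) {
    abort(paste0("unknown key(s) in config: ", paste(extra, collapse = ", ")))
  }
  do.call(hh_params, vals[intersect(names(vals), known)])
}

#' @param params An [hh_params()] object to serialize.
#' @rdname read_hh_config
#' @export
write_hh_config <- function(params, path) {
  validate_hh_params(params)
  vals <- unclass(params)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path, precision = 12)
  }
  invisible(path)
}
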