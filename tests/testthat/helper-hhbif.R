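# Shared fixtures: reference critical values, a lazy cache for the
# expensive objects reused across files, and a finite-difference
# Jacobian oracle independent of the analytic entries.

# Reported critical conductances and eigenvalues at them (frozen
# reference values the analysis should reproduce).
ref <- list(
  gNa_star = 212.648720656,
  gK_star1 = 3.843499029,
  gK_star2 = 19.762260771,
  eig_real_gNa = c(-4.9711711484, -0.1259717048),
  freq_gNa = 0.3798402483,
  eig_real_gK1 = c(-5.3218099843, -0.4223840650),
  freq_gK1 = 1.1305093754,
  eig_real_gK2 = c(-4.5370272278, -0.1319002182),
  freq_gK2 = 0.3436440068
)

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, make) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- make()
  }
  .fixture_cache[[key]]
}

cached_hopf <- function(which) {
  p <- canonical_parameters()
  switch(which,
    g_Na = cached("hopf_gNa", function() find_hopf(p, "g_Na", c(0, 500))),
    g_K1 = cached("hopf_gK1", function() find_hopf(p, "g_K", c(0, 10))),
    g_K2 = cached("hopf_gK2", function() find_hopf(p, "g_K", c(10, 200)))
  )
}

# Coarse but refined stability map reused by several files
# (21 columns x 31 rows keeps it to ~2 s).
cached_small_map <- function() {
  cached("small_map", function() {
    stability_map(canonical_parameters(), n_gNa = 21, n_gK = 31)
  })
}

# Central finite-difference Jacobian of the vector field; the oracle
# against which the closed-form entries are checked.
fd_jacobian <- function(params, state, eps = 1e-6) {
  st <- as.numeric(state)
  J <- matrix(0, 4, 4)
  for (j in 1:4) {
    d <- numeric(4)
    d[j] <- eps
    J[, j] <- (hh_rhs(st + d, params) - hh_rhs(st - d, params)) / (2 * eps)
  }
  J
}

equilibrium_state <- function(eq) {
  c(eq$V_star, eq$m_star, eq$h_star, eq$n_star)
}
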