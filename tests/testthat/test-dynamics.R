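test_that("an exact equilibrium is invariant under integration", {
  p <- hh_params()
  eq <- tracked_equilibrium(p)
  tr <- hh_simulate(p, initial = eq, t_end = 100, dt = 0.01)
  expect_lt(max(abs(tr$V - eq$V_star)), 1e-6)
  expect_lt(max(abs(tr$n - eq$n_star)), 1e-8)
})

test_that("halving the step leaves a stable trajectory unchanged to tolerance", {
  p <- hh_params()
  tr1 <- hh_simulate(p, t_end = 50, dt = 0.01)
  tr2 <- hh_simulate(p, t_end = 50, dt = 0.005)
  V1 <- tr1$V[tr1$time == 50]
  V2 <- tr2$V[tr2$time == 50]
  expect_lt(abs(V1 - V2), 1e-4)
})

test_that("gating variables remain inside the unit interval along trajectories", {
  p <- update(hh_params(), g_K = 15)      # firing regime
  tr <- hh_simulate(p, t_end = 200, dt = 0.01)
  for (g in c("m", "h", "n")) {
    expect_gt(min(tr[[g]]), -1e-9)
    expect_lt(max(tr[[g]]), 1 + 1e-9)
  }
  expect_true(all(diff(tr$time) > 0))
  expect_equal(max(abs(diff(tr$time) - 0.01)), 0, tolerance = 1e-9)
})

test_that("attractor classification separates settled, periodic and ambiguous traces", {
  # constant synthetic trace
  flat <- tibble::tibble(time = seq(0, 300, by = 0.1), V = 0)
  cl <- classify_attractor(flat)
  expect_identical(cl$label, "fixed_point")
  expect_identical(cl$V_amplitude, 0)
  # sub-threshold oscillation lands in the indeterminate band
  tt <- seq(0, 300, by = 0.1)
  wobble <- tibble::tibble(time = tt, V = 0.25 * sin(2 * pi * tt / 15))
  expect_identical(classify_attractor(wobble)$label, "undetermined")
  # clean oscillation is periodic with the imposed period
  osc <- tibble::tibble(time = tt, V = 40 * sin(2 * pi * tt / 15))
  cl_osc <- classify_attractor(osc)
  expect_identical(cl_osc$label, "limit_cycle")
  expect_equal(cl_osc$period_estimate, 15, tolerance = 1e-2)
  expect_identical(tidy(cl_osc)$label, "limit_cycle")
})

test_that("a firing regime classifies as a limit cycle from a small perturbation", {
  p <- update(hh_params(), g_Na = 250)
  tr <- hh_simulate(p, t_end = 300, dt = 0.02)
  cl <- classify_attractor(tr)
  expect_identical(cl$label, "limit_cycle")
  expect_gt(cl$V_amplitude, 50)
  expect_gte(cl$n_cycles, 3L)
  expect_lt(cl$cv_period, 0.05)
})

test_that("nonlinear attractors corroborate the linear verdict away from boundaries", {
  # seeded random conductance pairs, keeping only points whose verdict
  # is locally constant (+/- 1 mS/cm^2 in each axis) and whose margin
  # is not vanishingly small -- i.e. points well clear of a bifurcation
  draws <- sample_parameters(120, seed = 555)
  kept <- 0L
  for (i in seq_len(nrow(draws))) {
    if (kept >= 50L) break
    p <- draws$params[[i]]
    m <- stability_margin(p)
    if (abs(m) < 0.005) next
    locally_constant <- TRUE
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      m2 <- tryCatch(
        stability_margin(update(p, g_Na = max(0, p$g_Na + d[1]),
                                g_K = max(0, p$g_K + d[2]))),
        error = function(e) NA_real_)
      if (!is.finite(m2) || sign(m2) != sign(m)) {
        locally_constant <- FALSE
        break
      }
    }
    if (!locally_constant) next
    kept <- kept + 1L
    cl <- classify_attractor(hh_simulate(p, t_end = 300, dt = 0.02))
    expected <- if (m < 0) "fixed_point" else "limit_cycle"
    expect_identical(cl$label, expected,
                     info = sprintf("g_Na = %.2f, g_K = %.2f", p$g_Na, p$g_K))
  }
  expect_identical(kept, 50L)
})

test_that("degenerate simulation requests are rejected", {
  p <- hh_params()
  expect_error(hh_simulate(p, t_end = -1), "positive")
  expect_error(hh_simulate(p, dt = 0), "positive")
  expect_error(classify_attractor(hh_simulate(p, t_end = 50, dt = 0.05)),
               "100 ms")
  expect_error(classify_attractor(tibble::tibble(time = 1, V = 1),
                                  transient_fraction = 1.5),
               "transient_fraction")
})
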