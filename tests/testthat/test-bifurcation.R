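test_that("stability margin is negative at canonical values and flips across the known cases", {
  p <- hh_params()
  expect_lt(stability_margin(p), 0)
  expect_lt(stability_margin(update(p, g_Na = 198)), 0)
  expect_gt(stability_margin(update(p, g_Na = 250)), 0)
  expect_lt(stability_margin(update(p, g_K = 2.8)), 0)
  expect_gt(stability_margin(update(p, g_K = 15)), 0)
  expect_lt(stability_margin(update(p, g_K = 21)), 0)
})

test_that("Hopf bisection converges and is insensitive to the tolerance", {
  p <- hh_params()
  coarse <- find_hopf(p, "g_Na", c(0, 500), tol = 1e-6)
  fine <- find_hopf(p, "g_Na", c(0, 500), tol = 1e-12)
  expect_lt(abs(coarse$critical_value - fine$critical_value), 1e-6)
  expect_lt(diff(fine$bracket), 1e-12)
  expect_error(find_hopf(p, "g_Na", c(0, 100)), "same stability")
  expect_error(find_hopf(p, "g_Na", c(5, 2)), "increasing")
})

test_that("located Hopf points carry a purely imaginary leading pair", {
  for (which in c("g_Na", "g_K1", "g_K2")) {
    hp <- cached_hopf(which)
    ev <- hp$eigenvalues_at_point
    pair <- ev[abs(Im(ev)) > 0]
    others <- ev[abs(Im(ev)) == 0]
    expect_identical(length(pair), 2L)
    expect_lt(max(abs(Re(pair))), 1e-8)
    expect_gt(max(abs(Im(pair))), 1e-3)
    expect_true(all(Re(others) < 0))
    expect_identical(tidy(hp)$critical_value, hp$critical_value)
  }
})

test_that("the stability verdict partitions the g_K axis into the three known intervals", {
  p <- hh_params()
  k1 <- cached_hopf("g_K1")$critical_value
  k2 <- cached_hopf("g_K2")$critical_value
  for (gK in c(1, 3, 5, 12, 18, 20, 30, 100)) {
    expected_stable <- gK < k1 || gK > k2
    expect_identical(stability_margin(update(p, g_K = gK)) < 0,
                     expected_stable, info = paste("g_K =", gK))
  }
})

test_that("a single-point curve reduces to the stability margin", {
  p <- hh_params()
  cv <- equilibrium_curve(p, "g_Na", 120)
  expect_identical(nrow(cv), 1L)
  expect_identical(cv$param_name, "g_Na")
  expect_equal(cv$margin, stability_margin(p))
  expect_true(cv$stable)
  expect_error(equilibrium_curve(p, "g_Na", numeric(0)), "nonempty")
})

test_that("the coarse stability map agrees with the one-parameter analysis", {
  m <- cached_small_map()
  grid <- m$grid
  cell <- function(gNa, gK) grid[grid$g_Na == gNa & grid$g_K == gK, ]
  expect_true(cell(120, 36)$stable)
  expect_false(cell(120, 14)$stable)   # inside the unstable g_K band
  expect_false(cell(120, 16)$stable)
  expect_true(cell(120, 2)$stable)
  # refined transitions on the g_Na = 120 column match the 1-D Hopf points
  col <- m$boundary[m$boundary$g_Na == 120, ]
  expect_lt(min(abs(col$g_K - cached_hopf("g_K1")$critical_value)), 1e-4)
  expect_lt(min(abs(col$g_K - cached_hopf("g_K2")$critical_value)), 1e-4)
  up <- col[col$branch == "upper", ]
  expect_equal(up$g_K, cached_hopf("g_K2")$critical_value, tolerance = 1e-4)
  # the g_K = 36 row transition brackets the sodium Hopf point
  gNa_star <- cached_hopf("g_Na")$critical_value
  p <- hh_params()
  expect_lt(stability_margin(update(p, g_Na = floor(gNa_star))), 0)
  expect_gt(stability_margin(update(p, g_Na = ceiling(gNa_star))), 0)
})

test_that("least squares recovers an exact synthetic boundary line", {
  pts <- tibble::tibble(g_Na = seq(0, 200, by = 10),
                        g_K = 0.2 * seq(0, 200, by = 10) + 1,
                        branch = "upper")
  f <- fit_upper_boundary(pts)
  expect_equal(f$slope, 0.2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_lt(f$rms_residual, 1e-12)
  expect_identical(glance(f)$n_points, length(pts$g_Na))
  expect_error(fit_upper_boundary(pts[1, ]), "at least 2")
})

test_that("the fitted boundary line is stable under halving the column resolution", {
  m_full <- cached_small_map()                       # 21 columns
  m_half <- stability_map(canonical_parameters(), n_gNa = 11, n_gK = 31)
  f_full <- fit_upper_boundary(m_full)
  f_half <- fit_upper_boundary(m_half)
  expect_lt(abs(f_full$slope - f_half$slope), 0.005)
})
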