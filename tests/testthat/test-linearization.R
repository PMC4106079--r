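test_that("characteristic coefficients match hand expansions on simple matrices", {
  # (lambda+1)(lambda+2)(lambda+3)(lambda+4)
  expect_equal(characteristic_coefficients(diag(c(-1, -2, -3, -4))),
               c(a = 10, b = 35, c = 50, d = 24))
  expect_equal(characteristic_coefficients(matrix(0, 4, 4)),
               c(a = 0, b = 0, c = 0, d = 0))
  expect_equal(sort(Re(hh_eigenvalues(diag(c(-1, -2, -3, -4))))),
               c(-4, -3, -2, -1))
})

test_that("structural requirements on the matrix are enforced", {
  J <- diag(4)
  J[2, 3] <- 1        # forbidden position: gate equations do not couple
  expect_error(characteristic_coefficients(J), "sparsity")
  expect_error(characteristic_coefficients(matrix(0, 3, 3)), "4x4")
  expect_error(hh_eigenvalues(matrix(Inf, 4, 4)), "finite")
})

test_that("coefficients agree with elementary symmetric functions of the eigenvalues", {
  for (s in 1:200) {
    J <- random_structured_matrix(seed = s)
    co <- characteristic_coefficients(J)
    ev <- hh_eigenvalues(J)
    e1 <- sum(ev)
    e2 <- sum(ev[1] * ev[2:4], ev[2] * ev[3:4], ev[3] * ev[4])
    e3 <- ev[1] * ev[2] * ev[3] + ev[1] * ev[2] * ev[4] +
      ev[1] * ev[3] * ev[4] + ev[2] * ev[3] * ev[4]
    e4 <- prod(ev)
    recon <- c(-Re(e1), Re(e2), -Re(e3), Re(e4))
    expect_lt(max(abs(unname(co) - recon)), 1e-8)
  }
})

test_that("analytic Jacobian matches the finite-difference oracle", {
  p <- hh_params()
  eq <- tracked_equilibrium(p)
  J <- hh_jacobian(p, eq)
  expect_lt(max(abs(J - fd_jacobian(p, equilibrium_state(eq)))), 1e-6)
  # and across random conductance draws
  draws <- sample_parameters(10, seed = 42)
  for (pp in draws$params) {
    eq <- tracked_equilibrium(pp)
    J <- hh_jacobian(pp, eq)
    expect_lt(max(abs(J - fd_jacobian(pp, equilibrium_state(eq)))), 1e-6)
  }
})

test_that("Jacobian requires an actual equilibrium", {
  p <- hh_params()
  expect_error(hh_jacobian(p, c(50, 0.5, 0.5, 0.5)), "not an equilibrium")
  # with zero ionic conductances the voltage row reduces to pure leak
  p0 <- update(p, g_Na = 0, g_K = 0)
  J <- hh_jacobian(p0, tracked_equilibrium(p0))
  expect_equal(unname(J[1, 2:4]), c(0, 0, 0))
  expect_equal(J[1, 1], -p0$g_l / p0$C_M)
})

test_that("Routh-Hurwitz verdicts match textbook cases and flag boundaries", {
  expect_identical(routh_hurwitz(10, 35, 50, 24), "stable")
  # (lambda-1)(lambda+2)(lambda+3)(lambda+4): one positive root
  expect_identical(routh_hurwitz(8, 17, -2, -24), "unstable")
  # d at its threshold
  expect_identical(routh_hurwitz(10, 35, 50, 0), "boundary")
  expect_identical(routh_hurwitz(c(a = 10, b = 35, c = 50, d = 24)), "stable")
  expect_error(routh_hurwitz(NaN, 1, 1, 1), "finite")
})

test_that("Routh-Hurwitz verdict is equivalent to the eigenvalue sign", {
  n_boundary <- 0L
  for (s in 201:500) {
    J <- random_structured_matrix(seed = s)
    v <- routh_hurwitz(characteristic_coefficients(J))
    if (v == "boundary") {
      n_boundary <- n_boundary + 1L
      next
    }
    mrp <- max(Re(hh_eigenvalues(J)))
    expect_identical(v, if (mrp < 0) "stable" else "unstable")
  }
  expect_lt(n_boundary, 5L)
})

test_that("complex eigenvalues appear in conjugate pairs, sorted by real part", {
  for (s in c(7, 19, 23)) {
    ev <- hh_eigenvalues(random_structured_matrix(seed = s))
    expect_true(all(diff(Re(ev)) <= 1e-12))
    cplx <- ev[abs(Im(ev)) > 0]
    if (length(cplx) > 0) {
      expect_equal(sort(Im(cplx)), sort(-Im(cplx)))
    }
  }
})

test_that("stability reports summarise the linearization coherently", {
  rep <- stability_report(hh_params())
  expect_s3_class(rep, "hh_stability")
  expect_identical(rep$verdict, "stable")
  expect_lt(rep$max_real_part, 0)
  # characteristic coefficients reproduce the eigenvalue spectrum
  ev <- rep$eigenvalues
  expect_equal(-Re(sum(ev)), unname(rep$char_coeffs["a"]), tolerance = 1e-10)
  expect_equal(Re(prod(ev)), unname(rep$char_coeffs["d"]), tolerance = 1e-10)
  td <- tidy(rep)
  expect_identical(nrow(td), 4L)
  gl <- glance(rep)
  expect_true(gl$stable)
  # JSON serialization round-trips the key numbers
  f <- withr::local_tempfile(fileext = ".json")
  write_stability_report(rep, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$max_real_part, rep$max_real_part, tolerance = 1e-10)
  expect_identical(back$verdict, "stable")
  expect_equal(matrix(back$jacobian, 4, 4, byrow = TRUE),
               unname(rep$jacobian), tolerance = 1e-10)
})
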