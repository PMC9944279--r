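test_that("ECD and sphere volume follow the circular/spherical geometry", {
  expect_equal(ecd_from_area(pi), 2)
  expect_equal(ecd_from_area(3), 1.954, tolerance = 1e-3)   # 3 um^2 -> ~2 um
  expect_equal(ecd_from_area(12), 3.909, tolerance = 1e-3)  # 12 um^2 -> ~3.9 um
  expect_error(ecd_from_area(0), class = "aggsink_config_error")

  expect_equal(sphere_volume(1), pi / 6)
  expect_equal(sphere_volume(2) / sphere_volume(1), 8)
})

test_that("settling velocity converts cm/s to m/d with the 864 factor", {
  expect_equal(settling_velocity(60, 15), 216)
  expect_equal(settling_velocity(150, 15), 86.4)
  expect_equal(settling_velocity(30, 15), 2 * settling_velocity(60, 15))
  expect_error(settling_velocity(0), class = "aggsink_config_error")
})

test_that("Stokes excess density reproduces the treatment means at printed precision", {
  expect_equal(round(excess_density(201, 2.4), 1), 0.8) # non-infected
  expect_equal(round(excess_density(144, 2.4), 1), 0.6) # infected
  expect_equal(excess_density(0, 2.4), 0)
})

test_that("porosity reproduces the treatment means and rejects impossible inputs", {
  expect_equal(round(porosity(0.6, 1.258), 4), 0.9995)
  expect_equal(round(porosity(1.3, 1.284), 4), 0.9990)
  expect_equal(porosity(0, 1.284), 1)
  expect_error(porosity(2000, 1.284), class = "aggsink_config_error")
})

test_that("Reynolds number and drag coefficient follow their closed forms", {
  expect_equal(reynolds_number(2.4, 201), 0.24 * (201 / 864) / 1.085e-2,
               tolerance = 1e-12)
  expect_equal(reynolds_number(2.4, 201), 5.146, tolerance = 1e-3)
  expect_equal(reynolds_number(2.4, 0), 0)
  expect_equal(reynolds_number(2.4, 402), 2 * reynolds_number(2.4, 201))

  expect_equal(drag_coefficient(1), 27.4)
  expect_equal(drag_coefficient(5.146), 6.90, tolerance = 1e-3)
  expect_equal(drag_coefficient(1e6), 0.4, tolerance = 0.02)
  expect_error(drag_coefficient(0), class = "aggsink_config_error")
})

test_that("excess density and porosity round-trip through Stokes' law", {
  u <- c(52, 144, 201, 534); d <- c(1.1, 2.4, 2.4, 4.9)
  drho <- excess_density(u, d)
  expect_equal(stokes_velocity(drho, d), u, tolerance = 1e-9)
  # porosity back to excess density
  phi <- porosity(drho, 1.284)
  expect_equal(1000 * (1 - phi) * 1.284, drho, tolerance = 1e-9)
})

test_that("power-law fits recover exact data at machine precision", {
  dat <- tibble::tibble(d_mm = c(1, 1.7, 2.9, 4.1), u_m_d = 2 * c(1, 1.7, 2.9, 4.1)^1.5)
  for (m in c("loglog_ols", "nonlinear_ls")) {
    fit <- fit_power_law(dat, method = m)
    expect_equal(fit$a, 2, tolerance = 1e-7)
    expect_equal(fit$b, 1.5, tolerance = 1e-7)
  }
  # constant velocities: exponent 0
  flat <- tibble::tibble(d_mm = 1:5, u_m_d = rep(7, 5))
  expect_equal(fit_power_law(flat, method = "loglog_ols")$b, 0)
  expect_error(fit_power_law(tibble::tibble(d_mm = 1:2, u_m_d = 1:2)),
               "at least 3")
  expect_error(fit_power_law(tibble::tibble(d_mm = c(1, 2, -3),
                                            u_m_d = c(1, 2, 3))),
               "positive")
})

test_that("log-log OLS agrees with the normal-equations oracle", {
  withr::with_seed(19, {
    d <- runif(40, 1, 5)
    u <- 60 * d^1.37 * exp(rnorm(40, sd = 0.2))
  })
  fit <- fit_power_law(tibble::tibble(d_mm = d, u_m_d = u),
                       method = "loglog_ols")
  oracle <- normal_equations_fit(log10(d), log10(u))
  expect_equal(fit$b, unname(oracle["slope"]), tolerance = 1e-10)
  expect_equal(log10(fit$a), unname(oracle["intercept"]), tolerance = 1e-10)
})

test_that("fractal dimension is slope + 1 and scale-invariant", {
  dat <- tibble::tibble(d_mm = c(1, 2, 3, 4), u_m_d = 60 * c(1, 2, 3, 4)^1.37)
  expect_equal(fractal_dimension(dat)$d3, 2.37, tolerance = 1e-10)
  flat <- tibble::tibble(d_mm = 1:4, u_m_d = rep(5, 4))
  expect_equal(fractal_dimension(flat)$d3, 1)
  solid <- tibble::tibble(d_mm = 1:4, u_m_d = 3 * (1:4)^2)
  expect_equal(fractal_dimension(solid)$d3, 3, tolerance = 1e-10)

  # rescaling d by c and u by c^b leaves D3 unchanged
  withr::with_seed(7, {
    d <- runif(30, 1, 5); u <- 40 * d^1.64 * exp(rnorm(30, sd = 0.1))
  })
  base <- fractal_dimension(tibble::tibble(d_mm = d, u_m_d = u))$d3
  scaled <- fractal_dimension(tibble::tibble(d_mm = 3 * d,
                                             u_m_d = u * 3^1.64))$d3
  expect_equal(scaled, base, tolerance = 1e-9)
})

test_that("curve comparison nests correctly and flags no difference for identical groups", {
  withr::with_seed(3, {
    d <- runif(12, 1, 5); u <- 60 * d^1.37 * exp(rnorm(12, sd = 0.1))
  })
  g <- tibble::tibble(d_mm = d, u_m_d = u)
  same <- compare_fits(g, g)
  expect_lt(same$f, 1e-8)
  expect_gt(same$p, 0.999)
  # pooled SS can never undercut separate SS
  withr::with_seed(4, {
    d2 <- runif(12, 1, 5); u2 <- 34 * d2^1.64 * exp(rnorm(12, sd = 0.1))
  })
  diff <- compare_fits(g, tibble::tibble(d_mm = d2, u_m_d = u2))
  expect_gte(diff$ss_pooled, diff$ss_separate)
  expect_equal(diff$df1, 2)
  expect_equal(diff$df2, 20)
})

test_that("curve comparison detects the treatment exponent contrast with high power", {
  hits <- 0
  for (s in 1:100) {
    withr::with_seed(1000 + s, {
      d1 <- runif(12, 1, 5); u1 <- 60 * d1^1.37 * exp(rnorm(12, sd = 0.05))
      d2 <- runif(12, 1, 5); u2 <- 60 * d2^1.64 * exp(rnorm(12, sd = 0.05))
    })
    p <- compare_fits(tibble::tibble(d_mm = d1, u_m_d = u1),
                      tibble::tibble(d_mm = d2, u_m_d = u2))$p
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("density-layer assignment returns the measured layer density", {
  g <- density_gradient()
  expect_equal(assign_density_layer(3, g, measured_layer_density = 1.284),
               1.284)
  expect_equal(assign_density_layer(2, g, measured_layer_density = 1.251),
               1.251)
  expect_equal(assign_density_layer(1, g), 1.18)
  expect_error(assign_density_layer(7, g), "exceeds gradient",
               class = "aggsink_exceeds_gradient")
  expect_error(density_gradient(c(1.3, 1.2)), class = "aggsink_config_error")
})

test_that("aggregate_biophysics appends all derived columns consistently", {
  rec <- aggregate_biophysics(tibble::tibble(d_mm = 2.4, u_m_d = 201), 1.284)
  expect_equal(round(rec$drho_mg_cm3, 1), 0.8)
  expect_equal(round(rec$phi, 4), 0.9994)
  expect_equal(rec$re, reynolds_number(2.4, 201))
  expect_equal(rec$c_d, drag_coefficient(rec$re))
  expect_equal(rec$v_mm3, sphere_volume(2.4))
})
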