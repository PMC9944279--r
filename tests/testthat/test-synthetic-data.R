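test_that("population generator is a pure function of (params, seed)", {
  p <- population_params(n_aggregates = 50, velocity_noise_sd = 0.1, seed = 11)
  expect_identical(generate_aggregate_population(p),
                   generate_aggregate_population(p))
  p2 <- population_params(n_aggregates = 50, velocity_noise_sd = 0.1, seed = 12)
  expect_false(identical(generate_aggregate_population(p)$d_mm,
                         generate_aggregate_population(p2)$d_mm))
})

test_that("noiseless population follows the exact U = a d^(D3-1) power law", {
  p <- population_params(n_aggregates = 30, d3_true = 2.37,
                         velocity_scale_a = 60, velocity_noise_sd = 0, seed = 1)
  pop <- generate_aggregate_population(p)
  expect_equal(pop$u_m_d, 60 * pop$d_mm^1.37, tolerance = 1e-12)
  fd <- fractal_dimension(pop)
  expect_equal(fd$d3, 2.37, tolerance = 1e-10)
})

test_that("log-log estimator recovers the generating D3 from a noisy sample", {
  p <- population_params(n_aggregates = 200, d3_true = 2.37,
                         velocity_noise_sd = 0.1, seed = 1)
  fd <- fractal_dimension(generate_aggregate_population(p))
  expect_lt(abs(fd$d3 - 2.37), 0.1)
})

test_that("population ground truth is internally Stokes-consistent", {
  pop <- generate_aggregate_population(
    population_params(n_aggregates = 20, velocity_noise_sd = 0.2, seed = 3))
  # excess density recorded for each aggregate reproduces its velocity
  expect_equal(stokes_velocity(pop$drho_mg_cm3, pop$d_mm), pop$u_m_d,
               tolerance = 1e-9)
  # POC proportional to solid (non-porous) volume
  expect_equal(pop$poc_ug / pop$solid_v_mm3,
               rep(1480, 20), tolerance = 1e-9)
  expect_true(all(pop$phi > 0.99 & pop$phi < 1))
})

test_that("velocity noise is multiplicative and keeps velocities positive", {
  p <- population_params(n_aggregates = 500, velocity_noise_sd = 0.5, seed = 9)
  pop <- generate_aggregate_population(p)
  expect_true(all(pop$u_m_d > 0))
  logratio <- log(pop$u_m_d / pop$u_expected_m_d)
  expect_equal(sd(logratio), 0.5, tolerance = 0.1)
})

test_that("invalid population parameters are configuration errors", {
  expect_error(population_params(d_range = c(-1, 3)), class = "aggsink_config_error")
  expect_error(population_params(d3_true = 3.5), class = "aggsink_config_error")
  expect_error(population_params(velocity_noise_sd = -0.1),
               class = "aggsink_config_error")
})

test_that("settling trials invert exactly at zero timing noise", {
  pop <- generate_aggregate_population(population_params(n_aggregates = 15))
  tr <- generate_settling_trials(pop, distance_cm = 15)
  expect_equal(settling_velocity(tr$time_s, 15), pop$u_m_d, tolerance = 1e-12)
  # a 216 m/d aggregate takes 60 s over 15 cm
  expect_equal(15 / (216 / 864), 60)
  # determinism with noise
  t1 <- generate_settling_trials(pop, timing_noise_sd_s = 1, seed = 4)
  t2 <- generate_settling_trials(pop, timing_noise_sd_s = 1, seed = 4)
  expect_identical(t1, t2)
  expect_true(all(t1$time_s > 0))
})

test_that("zero-rate, zero-drift O2 assays show no drawdown", {
  pop <- generate_aggregate_population(
    population_params(n_aggregates = 5, resp_rate = 0))
  a <- generate_o2_assays(pop)
  expect_equal(a$o2_end_umol_L, rep(300, nrow(a)))
})

test_that("respiration chain inverts the assay generator at zero noise", {
  pop <- generate_aggregate_population(
    population_params(n_aggregates = 10, resp_rate = 0.34, resp_rate_cv = 0.3,
                      seed = 2))
  a <- generate_o2_assays(pop, control_drift_frac = 0.02)
  r <- o2_consumption(a)
  k <- c_specific_rate(r$o2_rate_umol_d, r$poc_ug)
  expect_equal(k, pop$resp_k_d, tolerance = 1e-9)
})

test_that("drift correction is unbiased in expectation over seeds", {
  pop <- generate_aggregate_population(
    population_params(n_aggregates = 4, resp_rate = 0.2, seed = 5))
  ks <- vapply(1:100, function(s) {
    a <- generate_o2_assays(pop, control_drift_frac = 0.02,
                            noise_sd_umol_L = 1, seed = s)
    r <- o2_consumption(a)
    mean(c_specific_rate(r$o2_rate_umol_d, r$poc_ug))
  }, numeric(1))
  expect_equal(mean(ks), 0.2, tolerance = 0.02)
})

test_that("excessive drawdown raises an anoxia error", {
  pop <- generate_aggregate_population(
    population_params(n_aggregates = 3, resp_rate = 50,
                      poc_per_solid_volume = 5e4))
  expect_error(generate_o2_assays(pop), "anoxia")
})

test_that("cell census reproduces stage mix, enrichment, and bacterial means", {
  prm <- census_params(n_cells = 1e5, seed = 21)
  cc <- generate_cell_census(prm)
  amb <- cc[cc$compartment == "ambient", ]
  agg <- cc[cc$compartment == "aggregate", ]
  # ambient prevalence near the 42% implied by the stage mix
  expect_equal(prevalence(amb), 42, tolerance = 1)
  # enrichment parameter (71/42) recovered by the downstream ratio
  expect_equal(enrichment(prevalence(agg), prevalence(amb)), 71 / 42,
               tolerance = 0.05)
  # per-stage empirical bacterial means within 2% of the parameters
  means <- tapply(cc$bacteria, cc$stage, mean)
  pars <- c(non = 6.5, early = 9.9, mature = 9.6, post = 16.1, decaying = 24.2)
  expect_equal(as.numeric(means[names(pars)]), as.numeric(pars),
               tolerance = 0.02)
})

test_that("enrichment = 1 leaves both compartments with the same mix", {
  prm <- census_params(n_cells = 4e4, aggregate_enrichment = 1, seed = 8)
  cc <- generate_cell_census(prm)
  pa <- prevalence(cc[cc$compartment == "aggregate", ])
  pm <- prevalence(cc[cc$compartment == "ambient", ])
  expect_equal(pa, pm, tolerance = 1.5)
})

test_that("infeasible enrichment is rejected", {
  expect_error(
    generate_cell_census(census_params(aggregate_enrichment = 3)),
    "negative")
})

test_that("census generation is seed-deterministic", {
  prm <- census_params(n_cells = 1000, seed = 33)
  expect_identical(generate_cell_census(prm), generate_cell_census(prm))
})
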