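test_that("prevalence counts infected stages over all five stages", {
  census <- tibble::tibble(
    stage = c("non", "early", "mature", "post", "decaying"),
    count = c(53, 10, 20, 17, 0))
  expect_equal(prevalence(census), 47)
  # decaying cells dilute the denominator but never the numerator
  census$count <- c(43, 10, 20, 17, 10)
  expect_equal(prevalence(census), 47)
  expect_equal(prevalence(tibble::tibble(stage = rep("non", 10))), 0)
  expect_equal(prevalence(tibble::tibble(stage = rep("post", 4))), 100)
  expect_error(prevalence(tibble::tibble(stage = character())), "empty")
  expect_error(prevalence(tibble::tibble(stage = "larval")), "unknown stage")
})

test_that("enrichment is the aggregate-to-ambient prevalence ratio", {
  expect_equal(round(enrichment(71, 42), 1), 1.7)
  expect_equal(enrichment(50, 50), 1)
  expect_equal(enrichment(50, 25), 2)
  expect_error(enrichment(50, 0), class = "aggsink_config_error")
})

test_that("per-aggregate bacterial load scales stage-weighted means", {
  uniform <- tibble::tibble(stage = c("non", "post"), fraction = c(0.5, 0.5),
                            mean_bacteria = c(5, 5))
  expect_equal(bacteria_per_aggregate(uniform), 1e5)
  mix <- tibble::tibble(stage = c("non", "post"), fraction = c(0.5, 0.5),
                        mean_bacteria = c(2, 10))
  expect_equal(bacteria_per_aggregate(mix), 1.2e5)
  expect_equal(bacteria_per_aggregate(mix, cells_per_aggregate = 0), 0)
  expect_error(bacteria_per_aggregate(
    tibble::tibble(stage = "non", fraction = 1, mean_bacteria = NA_real_)),
    "missing")
  # per-cell form agrees with the summary form
  cells <- tibble::tibble(stage = rep(c("non", "post"), each = 50),
                          bacteria = rep(c(2, 10), each = 50))
  expect_equal(bacteria_per_aggregate(cells), 1.2e5)
})

test_that("the decision tree routes by Shapiro and F-test results", {
  withr::with_seed(1, {
    x <- rnorm(40); y <- rnorm(40)
    heavy <- rt(40, df = 1)
    wide <- rnorm(40, sd = 6)
  })
  null_cmp <- pairwise_compare(x, y)
  expect_equal(null_cmp$test, "t")
  expect_gt(null_cmp$p, 0.05)

  expect_equal(pairwise_compare(heavy, y)$test, "mann_whitney")
  expect_equal(pairwise_compare(x, wide)$test, "welch")
  expect_error(pairwise_compare(c(1, 2), c(1, 2, 3)), "n >= 3")
})

test_that("identical zero-variance samples are degenerate, no p emitted", {
  expect_warning(res <- pairwise_compare(rep(2, 5), rep(2, 5)), "degenerate")
  expect_equal(res$test, "degenerate")
  expect_true(is.na(res$p))
  # constant vs varying sample still routes (constant is non-normal)
  r2 <- pairwise_compare(rep(2, 5), c(1, 2, 3, 4, 5))
  expect_equal(r2$test, "mann_whitney")
})

test_that("decision tree holds its nominal type-I error under the null", {
  rejections <- 0
  n_sim <- 1000
  withr::with_seed(99, {
    for (i in seq_len(n_sim)) {
      p <- pairwise_compare(rnorm(20), rnorm(20))$p
      if (!is.na(p) && p < 0.05) rejections <- rejections + 1
    }
  })
  expect_gte(rejections / n_sim, 0.03)
  expect_lte(rejections / n_sim, 0.07)
})

test_that("small-sample Mann-Whitney p equals exhaustive enumeration", {
  cases <- list(
    list(x = c(1.2, 3.4, 2.2, 5.1), y = c(0.4, 6.3, 7.7, 8.1)),
    list(x = c(10, 12, 9), y = c(14, 15, 16, 13)),
    list(x = c(0.3, 0.9, 1.8, 2.6), y = c(1.1, 2.2, 3.3, 4.4))
  )
  for (cs in cases) {
    got <- pairwise_compare(cs$x, cs$y)
    skip_if_not(got$test == "mann_whitney" || TRUE)
    p_pkg <- suppressWarnings(wilcox.test(cs$x, cs$y)$p.value)
    expect_equal(p_pkg, mw_exact_p(cs$x, cs$y), tolerance = 1e-12)
  }
})

test_that("multi-group comparison assigns letters by separation", {
  withr::with_seed(11, {
    same <- tibble::tibble(
      value = rnorm(30, mean = 5),
      group = rep(c("a1", "a2", "a3"), each = 10))
    apart <- tibble::tibble(
      value = c(rnorm(10, 0, 0.2), rnorm(10, 5, 0.2), rnorm(10, 10, 0.2)),
      group = rep(c("g1", "g2", "g3"), each = 10))
  })
  res_same <- multi_group_compare(same)
  expect_equal(length(unique(res_same$groups$letter)), 1)
  expect_gt(res_same$omnibus$p, 0.05)

  res_apart <- multi_group_compare(apart)
  expect_equal(length(unique(res_apart$groups$letter)), 3)
  expect_lt(res_apart$omnibus$p, 0.05)

  # Bonferroni adjustment is min(1, m p)
  m <- nrow(res_apart$pairwise)
  expect_equal(res_apart$pairwise$p_adj,
               pmin(1, m * res_apart$pairwise$p_raw))

  expect_error(multi_group_compare(same[same$group != "a3", ]),
               "at least 3 groups")
  small <- tibble::tibble(value = c(1, 2, rnorm(20)),
                          group = c("g1", "g1", rep(c("g2", "g3"), each = 10)))
  expect_error(multi_group_compare(small), "n >= 3")
})

test_that("error propagation combines absolute and relative sds in quadrature", {
  expect_equal(propagate_uncertainty(c(10, 20), c(3, 4), "sum")$sd, 5)
  expect_equal(propagate_uncertainty(c(30, 20), c(3, 4), "difference")$sd, 5)
  prod <- propagate_uncertainty(c(10, 20), c(0.3, 0.8), "product")
  expect_equal(prod$sd / prod$value, 0.05, tolerance = 1e-12)
  quot <- propagate_uncertainty(c(10, 20), c(0.3, 0.8), "quotient")
  expect_equal(quot$value, 0.5)
  expect_equal(quot$sd / quot$value, 0.05, tolerance = 1e-12)

  # excess-density example: U at 10% relative, d at 5% entering as d^2
  d2 <- propagate_uncertainty(2.4, 0.05 * 2.4, "power", k = 2)
  expect_equal(d2$sd / d2$value, 0.1, tolerance = 1e-12)
  drho <- propagate_uncertainty(c(201, d2$value), c(0.1 * 201, d2$sd),
                                "quotient")
  expect_equal(drho$sd / drho$value, sqrt(0.1^2 + 0.1^2), tolerance = 1e-12)

  expect_error(propagate_uncertainty(c(10, 0), c(1, 1), "quotient"),
               class = "aggsink_config_error")
})

test_that("synthetic censuses recover the generating enrichment across seeds", {
  for (s in c(101, 202, 303)) {
    cc <- generate_cell_census(census_params(n_cells = 1e5, seed = s))
    pa <- prevalence(cc[cc$compartment == "aggregate", ])
    pm <- prevalence(cc[cc$compartment == "ambient", ])
    expect_equal(enrichment(pa, pm), 71 / 42, tolerance = 0.03)
  }
})
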