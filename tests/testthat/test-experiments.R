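# Monte Carlo rejection-rate machinery.

test_that("rejection experiments are deterministic and bounded", {
  sc <- sc_scenario(0.2, 3, 2, 1)
  r1 <- rejection_rate_experiment(sc, "prism", 500, 500, replicates = 100,
                                  seed = 5)
  r2 <- rejection_rate_experiment(sc, "prism", 500, 500, replicates = 100,
                                  seed = 5)
  expect_identical(r1$rejection_rate, r2$rejection_rate)
  expect_gte(r1$rejection_rate, 0)
  expect_lte(r1$rejection_rate, 1)
  expect_equal(r1$mc_se,
               sqrt(r1$rejection_rate * (1 - r1$rejection_rate) /
                      (r1$replicates - r1$failed_replicates)))
})

test_that("alpha = 1 rejects every replicate", {
  sc <- sc_scenario(0.2, 3, 2, 1)
  r <- rejection_rate_experiment(sc, "prism", 200, 200, replicates = 50,
                                 alpha = 1, seed = 9)
  expect_equal(r$rejection_rate, 1)
})

test_that("null type I error is near nominal across the prevalence grid", {
  # scaled-down reproduction of the null curves for the proposed test:
  # eight prevalences, 2000 replicates each, 1000 cases / 1000 controls
  for (p in c(0.01, 0.02, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)) {
    sc <- sc_scenario(p, 3, 2, 1)
    r <- rejection_rate_experiment(sc, "prism", 1000, 1000,
                                   replicates = 2000, seed = 20 + round(100 * p))
    expect_lt(abs(r$rejection_rate - 0.05), 3 * sqrt(0.05 * 0.95 / 2000),
              label = sprintf("rate %.4f at prevalence %g", r$rejection_rate, p))
    expect_equal(r$failed_replicates, 0)
  }
})

test_that("comparator tests keep their directional character across the grid", {
  # one-sided risk-scale RERI is conservative wherever the disease is
  # non-rare (for rare diseases all scales coincide and its rate is near
  # nominal); odds-scale PRISM inflates once the disease is clearly non-rare
  for (p in c(0.05, 0.1, 0.2, 0.4)) {
    sc <- sc_scenario(p, 3, 2, 1)
    r <- rejection_rate_experiment(sc, "reri-risk", 5000, 5000,
                                   replicates = 400, seed = 1,
                                   alternative = "greater")
    expect_lt(r$rejection_rate, 0.05,
              label = sprintf("one-sided risk RERI rate %.3f at prevalence %g",
                              r$rejection_rate, p))
  }
  for (p in c(0.3, 0.4)) {
    sc <- sc_scenario(p, 3, 2, 1)
    r <- rejection_rate_experiment(sc, "prism-odds", 5000, 5000,
                                   replicates = 400, seed = 1)
    expect_gt(r$rejection_rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 400),
              label = sprintf("odds PRISM rate %.3f at prevalence %g",
                              r$rejection_rate, p))
  }
})

test_that("mean logPRISM estimate converges to the truth as samples grow", {
  sc <- sc_scenario(0.2, 3, 2, 1.171)
  truth <- log(1.171)
  mean_at <- function(n) {
    ests <- vapply(1:300, function(i) {
      s <- simulate_study(sc, n, n, vital_pop = Inf, seed = 1000 + i)
      log_prism(log_perils(s$table, s$prevalence))
    }, numeric(1))
    mean(ests)
  }
  m_small <- mean_at(200)
  m_big <- mean_at(5000)
  expect_lt(abs(m_big - truth), abs(m_small - truth) + 0.01)
  expect_equal(m_big, truth, tolerance = 0.05)
})

test_that("failed replicates are excluded, counted, and capped", {
  # tiny studies of a rare-profile scenario produce zero control cells for
  # the odds-scale RERI test often enough to exercise the bookkeeping
  sc <- sc_scenario(0.2, 3, 2, 1, exposure_prev = c(0.05, 0.05))
  r <- tryCatch(
    rejection_rate_experiment(sc, "reri-odds", 30, 30, replicates = 100,
                              seed = 2),
    error = function(e) e
  )
  if (inherits(r, "error")) {
    expect_match(conditionMessage(r), "too extreme")
  } else {
    expect_gt(r$failed_replicates, 0)
    expect_lte(r$failed_replicates, 20)
    expect_equal(r$rejections / (r$replicates - r$failed_replicates),
                 r$rejection_rate)
  }
})

test_that("prevalence sensitivity reproduces the exact baseline and reports all sizes", {
  sc <- sc_scenario(0.2, 3, 2, 1.171)
  grid <- prevalence_sensitivity_experiment(
    sc, "prism", 300, 300, source_sizes = c(1000, 1e6, Inf),
    replicates = 150, seed = 13)
  expect_length(grid, 3)
  expect_named(grid, c("1000", "1000000", "exact"))

  base <- rejection_rate_experiment(sc, "prism", 300, 300, vital_pop = Inf,
                                    replicates = 150, seed = 13)
  expect_identical(grid[["exact"]]$rejection_rate, base$rejection_rate)

  # a prevalence source as small as 1000 barely dents the power
  expect_lt(abs(grid[["1000"]]$rejection_rate -
                  grid[["exact"]]$rejection_rate),
            6 * grid[["exact"]]$mc_se)

  df <- as.data.frame(grid)
  expect_equal(nrow(df), 3)
  expect_true(all(c("rejection_rate", "mc_se", "prevalence_source") %in%
                    names(df)))
})

test_that("experiment inputs are validated", {
  sc <- sc_scenario(0.2, 3, 2, 1)
  expect_error(rejection_rate_experiment("x", "prism", 10, 10), "sc_scenario")
  expect_error(prevalence_sensitivity_experiment(sc, "prism", 10, 10,
                                                 source_sizes = 5), ">= 10")
})
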