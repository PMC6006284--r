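# The four interaction tests and the sc_test object contract.

test_that("prism_test reproduces the published hypertension analysis", {
  fit <- prism_test(tong_table(), tong_prevalence())
  expect_equal(round(fit$estimate, 3), 0.121)
  expect_equal(round(fit$conf.int[1], 3), -0.214, ignore_attr = TRUE)
  expect_equal(round(fit$conf.int[2], 3), 0.456, ignore_attr = TRUE)
  expect_equal(fit$p.value, 0.478, tolerance = 1e-3)
  expect_equal(fit$statistic, fit$estimate / sqrt(fit$variance))
})

test_that("a null table gives z = 0, p = 1 and a symmetric CI", {
  eq <- cc_table(c(10, 20, 30, 40), c(10, 20, 30, 40))
  for (m in c("prism", "prism-odds", "reri-risk")) {
    prev <- if (m == "prism-odds") NULL else prevalence(0.3)
    fit <- sc_test(eq, prev, method = m)
    expect_equal(fit$estimate, 0, tolerance = 1e-14)
    expect_equal(fit$p.value, 1, tolerance = 1e-12)
    expect_equal(unname(fit$conf.int[1]), -unname(fit$conf.int[2]),
                 tolerance = 1e-12)
  }
  # case counts proportional to control counts: all odds ratios are 1
  prop <- cc_table(2 * c(10, 20, 30, 40), c(10, 20, 30, 40))
  expect_equal(odds_reri_test(prop)$estimate, 0, tolerance = 1e-12)
})

test_that("odds-scale PRISM matches direct arithmetic and ignores prevalence scale", {
  fit <- odds_prism_test(tong_table())
  t_ref <- (20 / 311) / (18 / 622) - (13 / 311) / (24 / 622) -
    (161 / 311) / (261 / 622) + (117 / 311) / (319 / 622)
  expect_equal(fit$estimate, t_ref, tolerance = 1e-12)
  expect_equal(fit$estimate, 0.6387, tolerance = 1e-4)

  # the statistic is built from proportions, so a common scaling of the
  # control counts leaves the estimate unchanged while the extra controls
  # raise precision (larger |z|)
  scaled <- cc_table(c(20, 13, 161, 117), c(18, 24, 261, 319) * 7)
  sfit <- odds_prism_test(scaled)
  expect_equal(sfit$estimate, fit$estimate, tolerance = 1e-12)
  expect_gt(abs(sfit$statistic), abs(fit$statistic))
})

test_that("odds-scale RERI matches hand-computed odds ratios", {
  fit <- odds_reri_test(tong_table())
  or11 <- (20 * 319) / (117 * 18)
  or10 <- (13 * 319) / (117 * 24)
  or01 <- (161 * 319) / (117 * 261)
  expect_equal(or11, 3.029, tolerance = 1e-3)
  expect_equal(fit$estimate, or11 - or10 - or01 + 1, tolerance = 1e-12)
  expect_equal(fit$estimate, 0.871, tolerance = 1e-3)
  expect_error(odds_reri_test(cc_table(c(0, 13, 161, 117),
                                       c(18, 24, 261, 319))),
               "case count is zero")
})

test_that("risk-scale RERI chains through the prevalence-adjusted risks", {
  tab <- tong_table()
  prev <- tong_prevalence()
  fit <- risk_reri_test(tab, prev)
  odds <- cell_odds(tab, prev)$odds
  risk <- odds / (1 + odds)
  expect_equal(unname(risk["x0z0"]), 0.1982, tolerance = 1e-3)
  rr <- risk / risk["x0z0"]
  expect_equal(fit$estimate, unname(rr[1] - rr[2] - rr[3] + 1),
               tolerance = 1e-12)
  # equal risks in all cells: RERI = 0 whatever the prevalence
  eq <- cc_table(c(10, 20, 30, 40), c(10, 20, 30, 40))
  for (p in c(0.05, 0.3, 0.6)) {
    expect_equal(risk_reri_test(eq, prevalence(p))$estimate, 0,
                 tolerance = 1e-12)
  }
})

test_that("prism z converges to the odds-scale z in the rare-disease limit", {
  tab <- tong_table()
  z_odds <- odds_prism_test(tab)$statistic
  z_prism <- prism_test(tab, prevalence(1e-6, n = Inf))$statistic
  expect_lt(abs(z_prism - z_odds) / abs(z_odds), 1e-3)
})

test_that("sidedness is handled like a standard Z test", {
  tab <- tong_table()
  prev <- tong_prevalence()
  two <- prism_test(tab, prev)
  gt <- prism_test(tab, prev, alternative = "greater")
  lt <- prism_test(tab, prev, alternative = "less")
  expect_equal(gt$p.value, two$p.value / 2)       # estimate is positive
  expect_equal(gt$p.value + lt$p.value, 1)
  expect_equal(unname(gt$conf.int[2]), Inf)
  expect_equal(unname(lt$conf.int[1]), -Inf)
  # p monotone in the estimate magnitude
  stronger <- cc_table(c(30, 10, 161, 117), c(14, 28, 261, 319))
  expect_lt(prism_test(stronger, prev)$p.value, two$p.value)
})

test_that("sc_test validates inputs and demands a prevalence when needed", {
  tab <- tong_table()
  expect_error(prism_test(tab, NULL), "needs an overall disease prevalence")
  expect_error(risk_reri_test(tab, NULL), "needs an overall disease prevalence")
  expect_error(sc_test(tab, 0.2, alpha = 0), "'alpha'")
  expect_message(odds_prism_test(tab, prevalence = 0.2), "does not use")
  expect_error(sc_test("not a table", 0.2), "cc_table")
})

test_that("the fitted object supports the standard accessor generics", {
  fit <- prism_test(tong_table(), tong_prevalence())
  expect_named(coef(fit), "logPRISM")
  expect_equal(unname(coef(fit)), fit$estimate)
  expect_equal(dim(vcov(fit)), c(1L, 1L))
  ci95 <- confint(fit)
  expect_equal(unname(ci95[1, ]), unname(fit$conf.int), tolerance = 1e-12,
               ignore_attr = TRUE)
  ci90 <- confint(fit, level = 0.9)
  expect_true(ci90[1, 1] > ci95[1, 1] && ci90[1, 2] < ci95[1, 2])

  out <- capture.output(print(fit))
  expect_true(any(grepl("logPRISM", out)))
  expect_true(any(grepl("PRISM test", out)))
  sout <- capture.output(print(summary(fit)))
  expect_true(any(grepl("log_peril", sout)))

  draws <- simulate(fit, nsim = 50, seed = 3)
  expect_length(as.numeric(draws), 50)
  expect_identical(as.numeric(simulate(fit, nsim = 50, seed = 3)),
                   as.numeric(draws))
})
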