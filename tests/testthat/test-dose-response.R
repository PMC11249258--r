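test_that("Abbott's correction rescales, clips and degenerates as defined", {
  expect_equal(as.numeric(abbott_correct(0.55, 0.10)), 0.5)
  expect_equal(as.numeric(abbott_correct(0.37, 0)), 0.37)
  c2 <- abbott_correct(0.05, 0.10)
  expect_equal(as.numeric(c2), 0)
  expect_true(attr(c2, "clipped"))
  expect_error(abbott_correct(0.5, 1), "control")
  # monotone non-decreasing in p
  p <- seq(0, 1, by = 0.05)
  expect_false(is.unsorted(as.numeric(abbott_correct(p, 0.2))))
})

test_that("a log-symmetric response pattern pins the EC50 at the centre dose", {
  tb <- data.frame(concentration = c(0.1, 1, 10), n = 100,
                   responded = c(10, 50, 90))
  fit <- fit_probit(tb)
  expect_true(fit$converged)
  expect_equal(fit$ec50, 1, tolerance = 1e-6)
  expect_true(fit$ci[1] < fit$ec50 && fit$ec50 < fit$ci[2])
})

test_that("the probit optimum beats a dense grid search", {
  tb <- simulate_bioassay(0.077 * c(0.25, 0.5, 1, 2, 4, 8), 24, 4.7, 0.077,
                          seed = 41)
  fit <- fit_probit(tb)
  lc <- log10(tb$concentration)
  p_obs <- tb$responded / tb$n
  ll <- function(a, b) {
    mu <- pmin(1 - 1e-12, pmax(1e-12, pnorm(a + b * lc)))
    sum(tb$n * (p_obs * log(mu) + (1 - p_obs) * log(1 - mu)))
  }
  grid_a <- seq(fit$intercept - 3, fit$intercept + 3, length.out = 200)
  grid_b <- seq(max(0.1, fit$slope - 3), fit$slope + 3, length.out = 200)
  best_grid <- max(outer(grid_a, grid_b, Vectorize(ll)))
  expect_gte(fit$loglik + 1e-9, best_grid)
})

test_that("parameters are recovered from simulated bioassays", {
  tb <- simulate_bioassay(0.077 * c(0.25, 0.5, 1, 2, 4, 8), 24, 4.7, 0.077,
                          seed = 42)
  fit <- fit_probit(tb)
  expect_lt(abs(fit$ec50 - 0.077) / 0.077, 0.25)
  expect_lt(abs(fit$slope - 4.7), 2 * fit$slope_se)
})

test_that("complete separation is flagged with an interval estimate", {
  tb <- data.frame(concentration = c(0.01, 0.1, 1, 10), n = 24,
                   responded = c(0, 0, 24, 24))
  fit <- fit_probit(tb)
  expect_false(fit$converged)
  expect_equal(fit$ci, c(0.1, 1))
  expect_equal(fit$ec50, sqrt(0.1 * 1))
})

test_that("a control row triggers Abbott correction before fitting", {
  tb <- data.frame(concentration = c(0, 0.1, 1, 10), n = 100,
                   responded = c(10, 19, 55, 91))
  fit <- fit_probit(tb)
  expect_equal(fit$control_response, 0.1)
  expect_true(fit$converged)
  # corrected responses are symmetric around 1: (0.1,0.5,0.9)
  expect_equal(fit$ec50, 1, tolerance = 1e-6)
})

test_that("resistance ratios reproduce the published values and invert", {
  expect_equal(resistance_ratio(428, 0.077), 5560)
  expect_equal(resistance_ratio(2.97, 0.077), 38.6)
  expect_equal(resistance_ratio(5, 5), 1)
  expect_equal(resistance_ratio(428, 0.077) * resistance_ratio(0.077, 428),
               1, tolerance = 1e-2)
  expect_error(resistance_ratio(1, 0), "reference")
})

test_that("dominance h evaluates the survival-based formula", {
  expect_equal(as.numeric(dominance_h(0.1, 0.9, 0.1)), 0)
  expect_equal(as.numeric(dominance_h(0.1, 0.9, 0.9)), 1)
  expect_equal(as.numeric(dominance_h(0.05, 0.95, 0.50)), 0.5)
  expect_error(dominance_h(0.5, 0.5, 0.7), "undefined")
  oo <- dominance_h(0.2, 0.8, 0.9)
  expect_true(attr(oo, "out_of_range"))
  expect_gt(as.numeric(oo), 1)  # unclipped
})

test_that("dominance declines with concentration under strain probit models", {
  conc <- c(0.05, 0.25, 0.5, 1, 2, 10)
  tab <- data.frame(concentration = conc,
                    x = survival_from_probit(4.7, 0.077, conc),
                    y = survival_from_probit(4.7, 428, conc),
                    z = survival_from_probit(4.7, 0.27, conc))
  dc <- dominance_curve(tab)
  expect_gt(dc$h[1], 0.95)          # far below the F1 EC50: dominant
  expect_lt(dc$h[length(conc)], 0.05)  # far above: recessive
  expect_true(attr(dc, "decreasing"))
  # degenerate curves
  tab$z <- tab$x
  expect_equal(dominance_curve(tab)$h, rep(0, 6))
  tab$z <- tab$y
  expect_equal(dominance_curve(tab)$h, rep(1, 6))
})

test_that("monogenic recessive expectations match Mendelian arithmetic", {
  expect_equal(monogenic_expectation("backcross"), 0.5)
  expect_equal(monogenic_expectation("F2"), 0.75)
  expect_equal(monogenic_expectation("F1"), 1.0)
  expect_error(monogenic_expectation("F3"))
})

test_that("Fisher's exact test handles the complete-linkage table and small tables", {
  f <- fisher_exact(rbind(c(214, 0), c(0, 109)))
  expect_lt(f$log10_p, -88)
  expect_gt(f$log10_p, -89)
  expect_equal(fisher_exact(rbind(c(1, 1), c(1, 1)))$p, 1)
  expect_equal(fisher_exact(rbind(c(3, 1), c(1, 3)))$p, 34 / 70)
  z <- fisher_exact(rbind(c(0, 0), c(5, 3)))
  expect_equal(z$p, 1)
  expect_true(z$degenerate)
  expect_error(fisher_exact(rbind(c(-1, 1), c(1, 1))), "non-negative")
})

test_that("fisher_exact agrees with stats::fisher.test on random tables", {
  withr::with_seed(105, {
    for (i in 1:30) {
      tab <- matrix(rpois(4, 6), 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      expect_equal(fisher_exact(tab)$p, fisher.test(tab)$p.value,
                   tolerance = 1e-10)
    }
  })
})

test_that("observed-vs-expected tests report both exact constructions", {
  r <- observed_vs_expected_test(100, 50, 0.5)
  expect_equal(r$fisher$p, 1)  # identical rows
  r2 <- observed_vs_expected_test(20, 20, 0.5)
  # enumeration oracle for the exact binomial: sum of outcome
  # probabilities no larger than the observed outcome's
  probs <- dbinom(0:20, 20, 0.5)
  oracle <- sum(probs[probs <= probs[21] * (1 + 1e-7)])
  expect_equal(r2$binomial_p, oracle)
  # the published F2 test case: construction reported, table well-formed
  r3 <- observed_vs_expected_test(2304, 1797, 0.75)
  expect_equal(unname(r3$table["expected", 1]), 1728)
  expect_equal(r3$observed_prop, 0.78, tolerance = 0.001)
  expect_true(r3$fisher$p > 0 && r3$fisher$p < 1)
})
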