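test_that("contribution is the drop in MPE with propagated error", {
  est <- contribution(c(90, 90, 90), c(75, 75, 75))
  expect_equal(est$contribution, 15)
  expect_equal(est$se, 0)
  expect_equal(contribution(c(80, 82), c(80, 82))$contribution, 0)
  expect_error(contribution(numeric(0), 50), "empty")
  expect_error(contribution(c(50, 120), c(10, 20)), "\\[0, 100\\]")
  # dispersion: sqrt(sd1^2/n1 + sd2^2/n2)
  est2 <- contribution(c(88, 90, 92), c(70, 75, 80))
  expect_equal(est2$se, sqrt(var(c(88, 90, 92)) / 3 + var(c(70, 75, 80)) / 3))
})

test_that("delta MPE and delta (100-MPE) agree for all inputs", {
  set.seed(5)
  for (i in 1:25) {
    ctl <- runif(3, 0, 100)
    trt <- runif(3, 0, 100)
    a <- contribution(ctl, trt, "mpe")
    b <- contribution(ctl, trt, "unlabeled")
    expect_equal(abs(a$contribution), abs(b$contribution))
    expect_equal(a$se, b$se)
  }
})

test_that("unlabeled fraction is the MPE complement", {
  expect_equal(unlabeled_fraction(100), 0)
  expect_equal(unlabeled_fraction(0), 100)
  expect_equal(unlabeled_fraction(8), 92)
  expect_error(unlabeled_fraction(101), "\\[0, 100\\]")
})

test_that("2-HG reporter readout maps constructs to compartments", {
  m100 <- c(0, 0, 0, 0, 0, 1)  # fully labeled 2-HG
  ctl <- list(m100, m100, m100)
  est0 <- compartment_contribution("IDH2-R172K", ctl, ctl)
  expect_equal(est0$contribution, 0)
  expect_identical(est0$compartment, "mitochondrial")
  # planted 2% dilution of the mitochondrial pool
  dil <- c(0.02, 0, 0, 0, 0, 0.98)
  est2 <- compartment_contribution("IDH2-R172K", ctl, list(dil, dil, dil))
  expect_equal(est2$contribution, 2, tolerance = 1e-9)
  est1 <- compartment_contribution("IDH1-R132H", ctl, ctl)
  expect_identical(est1$compartment, "cytosolic")
  expect_error(compartment_contribution("IDH3", ctl, ctl), "unknown")
})

test_that("internal-standard quantitation is a linear ratio calculus", {
  expect_equal(absolute_quant(1e6, 1e6, 5, 5), 1)
  expect_equal(absolute_quant(0, 1e6, 5, 5), 0)
  expect_equal(absolute_quant(5e5, 1e6, 5, 5), 0.5)
  expect_error(absolute_quant(1, 0), "positive")
  # linear in analyte, inverse-linear in IS
  set.seed(2)
  a <- runif(10, 1e4, 1e7); is <- runif(10, 1e4, 1e7)
  expect_equal(absolute_quant(3 * a, is), 3 * absolute_quant(a, is))
  expect_equal(absolute_quant(a, 2 * is), absolute_quant(a, is) / 2)
})

test_that("reference normalization is a scale-invariant ratio", {
  expect_equal(normalize_to_reference(10, 10), 1)
  expect_equal(normalize_to_reference(20, 10), 2)
  a <- c(3, 8, 1); r <- c(2, 4, 5)
  expect_equal(normalize_to_reference(7 * a, 7 * r),
               normalize_to_reference(a, r))
  expect_error(normalize_to_reference(1, 0), "positive")
})

test_that("baseline normalization expresses rates as percent of basal mean", {
  expect_equal(baseline_normalize(rep(5, 8)), rep(100, 8))
  ser <- c(1, 1, 1, 2, 2)
  expect_equal(baseline_normalize(ser), c(100, 100, 100, 200, 200))
  expect_error(baseline_normalize(c(1, 2)), "longer")
  expect_error(baseline_normalize(c(0, 0, 0, 1)), "positive")
})

test_that("vehicle background subtraction aligns and averages", {
  expect_equal(background_subtract(c(1, 2, 3), c(1, 2, 3)), c(0, 0, 0))
  expect_equal(background_subtract(rep(-500, 4), rep(0, 4)), rep(-500, 4))
  expect_error(background_subtract(1:3, 1:4), "misaligned")
  exp_m <- rbind(c(-400, -500), c(-420, -520), c(-380, -480))
  veh <- c(10, 20)
  r <- background_subtract(exp_m, veh)
  expect_equal(r$mean, colMeans(exp_m) - veh)
  expect_equal(r$delta[2, ], exp_m[2, ] - veh)
})

test_that("Welch t statistics match the closed-form computation", {
  mat <- rbind(m1 = c(1, 2, 3, 2, 3, 4))
  g <- c("A", "A", "A", "B", "B", "B")
  res <- group_stats(mat, g, control = "A", treated = "B")
  # hand computation of the Welch test for {1,2,3} vs {2,3,4}
  t_stat <- (3 - 2) / sqrt(1 / 3 + 1 / 3)
  df <- (1 / 3 + 1 / 3)^2 / ((1 / 3)^2 / 2 + (1 / 3)^2 / 2)
  p_hand <- 2 * stats::pt(-abs(t_stat), df)
  expect_equal(res$p, p_hand, tolerance = 1e-12)
  expect_equal(res$log2fc, log2(3 / 2))
})

test_that("identical groups are never significant", {
  mat <- rbind(m1 = c(5, 6, 7, 5, 6, 7), m2 = rep(3, 6))
  g <- rep(c("A", "B"), each = 3)
  res <- group_stats(mat, g, "A", "B")
  expect_equal(res$log2fc, c(0, 0))
  expect_true(all(res$p > 0.99))
  expect_false(any(res$significant))
})

test_that("BH adjustment matches the step-up oracle and the volcano rule holds", {
  set.seed(9)
  n <- 12
  ctl <- matrix(rnorm(n * 3, 100, 5), n)
  trt <- ctl
  trt[1:3, ] <- trt[1:3, ] * 8  # strong planted changes
  mat <- cbind(ctl, trt)
  rownames(mat) <- paste0("m", 1:n)
  g <- rep(c("A", "B"), each = 3)
  res <- group_stats(mat, g, "A", "B")
  expect_equal(res$p_adj, oracle_bh(res$p), tolerance = 1e-12)
  expect_true(all(res$p_adj >= res$p - 1e-15))
  expect_true(all(res$p_adj <= 1))
  # monotone in raw p
  expect_true(all(diff(res$p_adj[order(res$p)]) >= -1e-15))
  expect_identical(res$significant,
                   !is.na(res$log2fc) & abs(res$log2fc) >= 1 &
                     res$p_adj < 0.05)
  expect_true(all(res$significant[1:3]))
})

test_that("non-positive group means flag the fold change as not computed", {
  mat <- rbind(m1 = c(0, 0, 0, 1, 2, 3))
  res <- group_stats(mat, rep(c("A", "B"), each = 3), "A", "B")
  expect_true(is.na(res$log2fc))
  expect_false(res$fc_computed)
  expect_false(res$significant)
})

test_that("injection stock arithmetic follows the dilution ratio", {
  expect_equal(injection_stock(1, 150, 25), 7)
  expect_equal(injection_stock(0.5, 150, 25), 3.5)
  expect_error(injection_stock(1, 150, 0), "invalid")
})
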