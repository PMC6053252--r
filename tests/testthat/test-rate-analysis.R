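test_that("the threshold-linear fitter recovers noiseless parameters exactly", {
  x <- 10:18
  f <- fit_threshold_linear(x, 0.5 * (x - 10))
  expect_equal(coef(f), c(m = 0.5, x0 = 10), tolerance = 1e-5)
  expect_lt(f$residual, 1e-8)
  f2 <- fit_threshold_linear(0:4, 0:4)
  expect_equal(coef(f2), c(m = 1, x0 = 0), tolerance = 1e-5)
  expect_equal(predict(f, c(10, 14, 8)), c(0, 2, 0), tolerance = 1e-4)
})

test_that("the fitter recovers parameters from noisy data", {
  set.seed(31)
  m <- 0.7; x0 <- 4
  est <- replicate(50, {
    x <- seq(4.5, 11, by = 0.5)
    y <- pmax(m * (x - x0), 0) + rnorm(length(x), sd = 0.2)
    coef(fit_threshold_linear(x, pmax(y, 0), cap = 5))
  })
  expect_lt(abs(mean(est["m", ]) - m), 3 * sd(est["m", ]) / sqrt(50) + 0.02)
  expect_lt(abs(mean(est["x0", ]) - x0), 3 * sd(est["x0", ]) / sqrt(50) + 0.1)
})

test_that("degenerate and insufficient fits are flagged", {
  expect_error(fit_threshold_linear(1:10, rep(6, 10)), "insufficient")
  f <- fit_threshold_linear(1:5, rep(0, 5))
  expect_true(f$degenerate)
  cl <- classify_inhibition(f)
  expect_equal(cl$label, "subtractive")
  expect_true(cl$degenerate)
})

test_that("classification uses a strict 2 spikes/s shift threshold", {
  mk <- function(x0) structure(list(m = 0.5, x0 = x0, residual = 0,
                                    n_points = 5, degenerate = FALSE, cap = 5),
                               class = "threshold_linear")
  expect_equal(classify_inhibition(mk(0))$label, "divisive")
  expect_equal(classify_inhibition(mk(2))$label, "divisive")   # boundary case
  expect_equal(classify_inhibition(mk(2.01))$label, "subtractive")
  ref <- mk(0.5)
  expect_equal(classify_inhibition(mk(2.4), reference = ref)$label, "divisive")
})

test_that("rate curves with inhibition disabled reproduce the reference branch", {
  p <- neuron_params(g_A = 20, g_SynE = 0.5, g_SynI = 0)
  cv <- compute_rate_curve(p, r_E = c(10, 30, 60), duration = 3000, seed = 6)
  expect_equal(cv$r_out_inh, cv$r_out_noinh)
})

test_that("rate curves expose the divisive/subtractive phenotypes", {
  # weak I_A: inhibited curve scaled down but responsive at the lowest rates
  cv20 <- compute_rate_curve(neuron_params(g_A = 20, g_SynE = 0.5, g_SynI = 1),
                             duration = 6000, seed = 8)
  expect_gt(cv20$r_out_inh[1], 0)
  f20 <- fit_threshold_linear(cv20)
  expect_lt(f20$m, 1)
  # strong I_A: inhibited curve silent below a nonzero input rate
  cv40 <- compute_rate_curve(neuron_params(g_A = 40, g_SynE = 0.5, g_SynI = 1),
                             duration = 6000, seed = 8)
  expect_equal(cv40$r_out_inh[cv40$r_E <= 15], rep(0, sum(cv40$r_E <= 15)))
  expect_gt(max(cv40$r_out_inh), 0)
})
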