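test_that("closed-form quantities of the periodic-inhibition analysis", {
  expect_equal(sigma_star(0.18, 50), exp(-3.6))
  expect_equal(sigma_star(0.18, 70), exp(-0.18 * 1000 / 70))
  expect_gt(sigma_star(1e-9, 50), 1 - 1e-6)          # no decay limit
  expect_error(sigma_star(0.18, 0), "positive")

  p <- neuron_params(g_SynE = 3, g_SynI = 5)
  expect_equal(quasi_steady_V(0, 0, p), -70)
  expect_equal(quasi_steady_V(1, 0, p), -17.5)
  expect_equal(quasi_steady_V(0, 1, p), -82.5)

  expect_equal(deadtime_rate(0, 10), 0)
  expect_equal(deadtime_rate(77, 0, 1), 77)
  expect_equal(deadtime_rate(100, 10, 1), 50)

  PI <- 20; bI <- 0.18
  expect_equal(rho_fraction(1, PI, bI), 1)
  expect_equal(rho_fraction(sigma_star(bI, 50), PI, bI), 0)
  expect_equal(rho_fraction(exp(-PI * bI / 2), PI, bI), 0.5)
  expect_error(rho_fraction(0, PI, bI), "positive")
})

test_that("nullcline roots satisfy the defining equation", {
  p <- reduced_drive()
  set.seed(5)
  for (k in 1:20) {
    V <- runif(1, -75, -20); b <- runif(1, 0.3, 0.9)
    sE <- runif(1); sI <- runif(1); gA <- runif(1, 0, 45)
    for (n in nullcline_n(V, b, sE, sI, gA, p)) {
      res <- p$g_L * (V - p$V_L) + p$g_K * n^4 * (V - p$V_K) +
        gA * gate_steady_state("a", V, p)^3 * b * (V - p$V_K) +
        p$g_Na * m_inf(V)^3 * (1 - n) * (V - p$V_Na) +
        p$g_SynE * sE * (V - p$V_E) + p$g_SynI * sI * (V - p$V_I)
      expect_lt(abs(res), 1e-8)
    }
  }
})

test_that("the nullcline branch moves as the slow variables dictate", {
  p <- reduced_drive()
  V <- seq(-65, -50, by = 5)
  base <- nullcline_branch(V, 0.6, 0.8, 0.3, 25, p)
  expect_true(all(nullcline_branch(V, 0.6, 0.9, 0.3, 25, p) > base))  # s_E up
  expect_true(all(nullcline_branch(V, 0.7, 0.8, 0.3, 25, p) < base))  # b up
  expect_true(all(nullcline_branch(V, 0.6, 0.8, 0.4, 25, p) < base))  # s_I up
  expect_true(all(nullcline_branch(V, 0.6, 0.8, 0.3, 30, p) < base))  # g_A up
})

test_that("the knee finder agrees with a dense-grid oracle", {
  p <- reduced_drive()
  set.seed(17)
  checked <- 0
  while (checked < 100) {
    b <- runif(1, 0.4, 0.85); sI <- runif(1, 0.02, 0.7)
    sE <- runif(1, 0.7, 1); gA <- runif(1, 10, 40)
    oracle <- knee_oracle_left(b, sE, sI, gA, p)
    if (is.null(oracle)) next
    k <- find_knee(b, sE, sI, gA, "left", p)
    expect_lt(abs(k$n - oracle), 1e-4)
    checked <- checked + 1
  }
})

test_that("left-knee levels are monotone in inhibition, input rate and g_A", {
  p <- reduced_drive()
  bt <- b_table(seq(0, 100, by = 25), params = p)
  ss <- sigma_star(p$beta_I, 50)
  kn_g <- vapply(c(15, 20, 25, 29), function(g)
    N_lk(ss, 0, g, bt$fun, p), numeric(1))
  expect_true(all(diff(kn_g) < 0))
  kn_r <- vapply(c(0, 25, 50, 100), function(re)
    N_lk(ss, re, 35, bt$fun, p), numeric(1))
  expect_true(all(diff(kn_r) > 0))
  kn_s <- vapply(c(ss, 0.2, 0.5), function(s)
    N_lk(s, 0, 20, bt$fun, p), numeric(1))
  expect_true(all(diff(kn_s) < 0))
})

test_that("the b-average approximation chain is consistent", {
  p <- reduced_drive(g_A = 40)
  expect_equal(b_average(0, "reduced", p), b_average(0, "reduced", p))
  # excitatory component at rest: b_inf(-70) = 1/2 exactly
  b0 <- b_average(0, "reduced", p)
  expect_gt(b0, 0.5)          # periodic hyperpolarisation de-inactivates
  grid <- c(0, 30, 100)
  br <- vapply(grid, b_average, numeric(1), method = "reduced", params = p,
               duration = 60000, seed = 2)
  expect_true(all(diff(br) < 0))
  bp <- vapply(grid, b_average, numeric(1), method = "passive", params = p,
               duration = 40000, seed = 2)
  bf <- vapply(grid, b_average, numeric(1), method = "full", params = p,
               duration = 40000, seed = 2)
  expect_true(all(abs(br - bp) < 0.05))
  expect_true(all(abs(bp - bf) < 0.05))
})

test_that("the critical conductance marks the loss of excitability", {
  p <- reduced_drive()
  g0 <- critical_gA(p)
  expect_lt(abs(attr(g0, "N_lk_residual")), 2e-3)
  g0_strong <- critical_gA(reduced_drive(g_SynI = 6))
  expect_lt(as.numeric(g0_strong), as.numeric(g0))
  # Gamma rises continuously from zero at the critical conductance
  bt <- b_table(seq(0, 60, by = 10), params = p)
  expect_equal(gamma_curve(as.numeric(g0) - 1, p, btab = bt), 0)
  expect_lt(gamma_curve(as.numeric(g0) + 0.05, p, btab = bt), 1.5)
  gg <- vapply(c(31, 34, 38), gamma_curve, numeric(1), params = p, btab = bt)
  expect_true(all(diff(gg) > 0))
})

test_that("the refractory fit recovers known dead times", {
  re <- seq(10, 150, by = 10)
  expect_equal(as.numeric(fit_refractory_R(re, deadtime_rate(re, 8))), 8,
               tolerance = 1e-3)
  expect_lt(as.numeric(fit_refractory_R(re, re)), 1e-3)
})

test_that("the firing-threshold fixed point solves the composed map", {
  p <- reduced_drive()
  bt <- b_table(seq(0, 100, by = 20), params = p)
  ctx15 <- reduced_context(15, p, btab = bt, R = 10)
  th <- vapply(c(10, 40, 80), function(re) {
    ft <- firing_threshold(re, 15, ctx15)
    expect_lt(ft$residual, 1e-6)
    expect_true(ft$theta >= 0 && ft$theta <= 1)
    ft$theta
  }, numeric(1))
  expect_lt(diff(range(th)), 0.05)       # nearly constant: purely divisive
  ctx35 <- reduced_context(35, p, btab = bt, R = 10)
  th35 <- vapply(c(10, 40, 80), function(re)
    firing_threshold(re, 35, ctx35)$theta, numeric(1))
  expect_gt(diff(range(th35)), 0.1)      # threshold rises with input rate
  expect_true(all(diff(th35) > 0))
})

test_that("spike-triggering inhibition levels in simulations stay near theta*", {
  p <- reduced_drive(g_A = 35)
  bt <- b_table(seq(0, 100, by = 20), params = p)
  ctx <- reduced_context(35, p, btab = bt, R = 10)
  for (re in c(60, 80)) {
    th <- firing_threshold(re, 35, ctx)$theta
    ex <- poisson_train(re, 8000, seed = 3)
    ih <- periodic_train(50, 8000)
    s <- simulate_neuron(p, ex, ih, 8000)
    trig <- vapply(s$spike_times, function(ts) max(ex$times[ex$times <= ts]),
                   numeric(1))
    expect_lte(max(gate_value(ih, p$beta_I, trig)), th + 0.1)
  }
})

test_that("the onset slope falls with g_A and the theory bounds simulation", {
  p <- reduced_drive()
  bt <- b_table(seq(0, 100, by = 20), params = p)
  ctx <- reduced_context(15, p, btab = bt, R = 10)
  sl <- vapply(c(0, 10, 20, 28), onset_slope, numeric(1), context = ctx)
  expect_true(all(diff(sl) < 0))
  expect_lte(sl[1], 1)
  g0 <- as.numeric(critical_gA(p, b0 = bt$fun(0)))
  expect_equal(onset_slope(g0 + 0.5, ctx), 0)
  # no-inhibition limit of the rate approximation is the pure dead-time law
  tc <- theory_rate_curve(c(10, 50, 100), 15, ctx, with_inhibition = FALSE)
  expect_equal(tc$r_out, deadtime_rate(c(10, 50, 100), ctx$R))
  # the approximation overestimates simulated rates (sampling tolerance)
  tci <- theory_rate_curve(c(40, 80), 15, ctx)
  sim <- vapply(c(40, 80), function(re)
    as.numeric(output_rate(reduced_drive(g_A = 15), re, 50, TRUE,
                           duration = 8000, seed = 4)), numeric(1))
  expect_true(all(tci$r_out > sim - 2))
})
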