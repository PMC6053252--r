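test_that("the compiled integrator matches an independent ODE solver", {
  skip_if_not_installed("deSolve")
  p <- neuron_params(g_A = 20, g_SynE = 0.5, g_SynI = 1)
  ex <- c(10, 23, 31, 55, 70); ih <- c(5, 25, 45, 65)
  rhs <- function(t, y, parms) {
    iE <- findInterval(t, ex); iI <- findInterval(t, ih)
    sE <- if (iE > 0) exp(-p$beta_E * (t - ex[iE])) else 0
    sI <- if (iI > 0) exp(-p$beta_I * (t - ih[iI])) else 0
    names(y) <- c("V", "n", "a", "b")
    list(point_rhs(t, y, p, sE, sI))
  }
  tt <- sort(unique(c(seq(0, 90, 0.01), ex, ih)))
  sol <- deSolve::lsoda(unname(rest_state(p)), tt, rhs, NULL,
                        rtol = 1e-10, atol = 1e-10)
  s <- simulate_neuron(p, ex, ih, 90, record_dt = 1)
  idx <- match(s$time, round(sol[, 1], 10))
  expect_lt(max(abs(sol[idx, 3] - s$n)), 1e-4)
  expect_lt(max(abs(sol[idx, 2] - s$V)), 0.5)   # steep spike flank
  sp <- detect_spikes(sol[, 1], sol[, 2])
  expect_equal(length(sp), length(s$spike_times))
  expect_lt(max(abs(sp - s$spike_times)), 0.01)
})

test_that("the input-free model is quiescent at rest", {
  s <- simulate_neuron(neuron_params(), NULL, NULL, 500)
  expect_length(s$spike_times, 0)
  expect_lt(abs(s$final_state[1] - rest_state(neuron_params())[["V"]]), 0.5)
})

test_that("a single excitatory event evokes one spike, later for weaker input", {
  lat <- vapply(c(0.2, 0.5, 1), function(g) {
    p <- neuron_params(g_A = 0, g_SynI = 0, g_SynE = g)
    s <- simulate_neuron(p, excit = 10, inhib = NULL, duration = 60)
    expect_length(s$spike_times, 1)
    s$spike_times[1] - 10
  }, numeric(1))
  expect_true(all(diff(lat) < 0))
  expect_gt(lat[1] - lat[3], 1)      # weakest input delayed by ~2 ms
  expect_lt(lat[1] - lat[3], 3)
})

test_that("spike detection interpolates crossings and honours the lockout", {
  expect_length(detect_spikes(0:10, rep(-70, 11)), 0)
  t <- seq(0, 10, by = 0.5)
  V <- -70 + 10 * t                      # crosses -20 at t = 5
  expect_equal(detect_spikes(t, V), 5, tolerance = 1e-10)
  # two upward crossings 1 ms apart, 2 ms lockout -> one spike
  t2 <- c(0, 1, 1.5, 2, 2.5, 3)
  V2 <- c(-70, 0, -70, 0, -70, -70)
  expect_length(detect_spikes(t2, V2, lockout = 2), 1)
  expect_length(detect_spikes(t2, V2, lockout = 0.1), 2)
})

test_that("spike counts are converged with respect to solver tolerance", {
  ex <- poisson_train(60, 4000, seed = 5)
  ih <- periodic_train(50, 4000)
  p <- neuron_params(g_A = 30)
  s1 <- simulate_neuron(p, ex, ih, 4000, abstol = 1e-8, reltol = 1e-6)
  s2 <- simulate_neuron(p, ex, ih, 4000, abstol = 5e-9, reltol = 5e-7)
  expect_equal(length(s1$spike_times), length(s2$spike_times))
  expect_lt(max(abs(s1$spike_times - s2$spike_times)), 0.05)
})

test_that("inhibition never raises the output rate at matched input seeds", {
  for (gA in c(20, 40)) {
    p <- neuron_params(g_A = gA, g_SynE = 0.5, g_SynI = 1)
    for (re in c(20, 60)) {
      r1 <- output_rate(p, re, 50, FALSE, duration = 4000, seed = 13)
      r2 <- output_rate(p, re, 50, TRUE, duration = 4000, seed = 13)
      expect_lte(r2, r1)
    }
  }
})

test_that("strong-drive spiking is one-to-one at low rates and monotone in r_E", {
  p <- reduced_drive(g_A = 0, g_SynI = 0)
  for (re in c(10, 20)) {
    r <- output_rate(p, re, 50, FALSE, duration = 10000, seed = 21)
    n <- attr(r, "spikes")
    expect_true(abs(n - re * 9.5) < 3 * sqrt(re * 9.5))  # Poisson band
  }
  rates <- vapply(c(10, 40, 80, 120), function(re)
    as.numeric(output_rate(p, re, 50, FALSE, duration = 6000, seed = 22)),
    numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("the strong-I_A dead zone silences low input rates under inhibition", {
  p <- neuron_params(g_A = 40, g_SynE = 0.5, g_SynI = 1)
  expect_equal(as.numeric(output_rate(p, 20, 50, TRUE, duration = 8000,
                                      seed = 2)), 0)
})
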