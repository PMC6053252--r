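test_that("steady-state gating curves have the stated half-points and directions", {
  expect_equal(gate_steady_state("n", -32), 0.5)
  expect_equal(gate_steady_state("a", -50), 0.5)
  expect_equal(gate_steady_state("b", -70), 0.5)
  expect_equal(tau_n_of_V(-80), 51)
  V <- seq(-100, 20, by = 5)
  expect_true(all(diff(gate_steady_state("n", V)) > 0))
  expect_true(all(diff(gate_steady_state("a", V)) > 0))
  expect_true(all(diff(gate_steady_state("b", V)) < 0))  # inactivation gate
})

test_that("ionic currents vanish at their reversal potentials", {
  p <- neuron_params()
  st <- c(V = -80, n = 0.4, a = 0.3, b = 0.5)
  I <- ionic_currents(st, p)
  expect_equal(unname(I["I_K"]), 0)
  expect_equal(unname(I["I_A"]), 0)
  st["V"] <- -70
  expect_equal(unname(ionic_currents(st, p)["I_L"]), 0)
  expect_equal(unname(ionic_currents(st, neuron_params(g_A = 0))["I_A"]), 0)
})

test_that("gating derivatives point toward their steady states", {
  p <- neuron_params()
  for (V in c(-80, -60, -40)) {
    st <- c(V = V, n = 0.5, a = 0.5, b = 0.5)
    d <- point_rhs(0, st, p)
    expect_equal(sign(d[["dn"]]), sign(gate_steady_state("n", V) - 0.5))
    expect_equal(sign(d[["da"]]), sign(gate_steady_state("a", V) - 0.5))
    expect_equal(sign(d[["db"]]), sign(gate_steady_state("b", V) - 0.5))
  }
  expect_error(point_rhs(0, c(V = NaN, n = 0, a = 0, b = 0), p), "finite")
})

test_that("the rest state is a fixed point of the input-free dynamics", {
  p <- neuron_params(g_A = 20)
  r <- rest_state(p)
  d <- point_rhs(0, r, p)
  expect_true(all(abs(d) < 1e-7))
})

test_that("a purely passive membrane relaxes exponentially to the leak reversal", {
  p <- neuron_params(g_K = 0, g_Na = 0, g_A = 0, g_SynI = 0, g_SynE = 0)
  s <- simulate_neuron(p, NULL, NULL, 8, y0 = c(-60, 0.5, 0.5, 0.5),
                       record_dt = 0.5)
  expect_equal(s$V, -70 + 10 * exp(-s$time), tolerance = 1e-6)
})

test_that("instantaneous-a and dynamic-a variants agree when g_A = 0", {
  ex <- poisson_train(30, 1500, seed = 4)
  p1 <- neuron_params(g_A = 0, g_SynI = 0)
  p2 <- neuron_params(g_A = 0, g_SynI = 0, instantaneous_a = TRUE)
  s1 <- simulate_neuron(p1, ex, NULL, 1500)
  s2 <- simulate_neuron(p2, ex, NULL, 1500)
  expect_equal(s1$spike_times, s2$spike_times, tolerance = 1e-6)
})

test_that("full-model trajectories converge to the reduced model as tau_a -> 0", {
  ex <- poisson_train(40, 2000, seed = 9)
  ih <- periodic_train(50, 2000)
  sI <- simulate_neuron(reduced_drive(g_A = 25), ex, ih, 2000)
  counts <- vapply(c(0.5, 0.1, 0.01), function(ta) {
    s <- simulate_neuron(neuron_params(g_A = 25, g_SynE = 3, g_SynI = 5,
                                       tau_a = ta), ex, ih, 2000)
    length(s$spike_times)
  }, numeric(1))
  nI <- length(sI$spike_times)
  expect_true(all(diff(abs(counts - nI)) <= 0))   # monotone approach
  expect_equal(counts[3], nI)
  s001 <- simulate_neuron(neuron_params(g_A = 25, g_SynE = 3, g_SynI = 5,
                                        tau_a = 0.01), ex, ih, 2000)
  expect_lt(max(abs(s001$spike_times - sI$spike_times)), 0.5)
})

test_that("gating variables remain inside the unit interval", {
  ex <- poisson_train(80, 3000, seed = 11)
  ih <- periodic_train(70, 3000)
  s <- simulate_neuron(neuron_params(g_A = 40), ex, ih, 3000, record_dt = 0.5)
  for (g in list(s$n, s$a, s$b))
    expect_true(all(g >= -1e-9 & g <= 1 + 1e-9))
})

test_that("cable axial currents are a discrete divergence and rest is uniform", {
  p <- neuron_params(g_L = 0, g_K = 0, g_Na = 0, g_A = 0, g_L_dend = 0)
  st <- c(seq(-80, -35, by = 5), 0.2, 0.3, 0.4)
  d <- cable_rhs(0, st, p)
  expect_equal(sum(d[1:10]), 0, tolerance = 1e-10)   # only axial terms remain
  s <- simulate_neuron(neuron_params(), NULL, NULL, 400, model = "cable")
  expect_true(all(abs(s$final_state[1:10] - -70) < 3))
  expect_error(simulate_neuron(neuron_params(cpt_in = 9, cpt_inhib = 9),
                               NULL, NULL, 10, model = "cable"), NA)
})

test_that("distal dendritic input arrives at the soma smaller and later", {
  peaks <- numeric(0); lats <- numeric(0)
  for (ci in c(1, 5, 9)) {
    p <- neuron_params(g_SynE = 0.3, g_SynI = 0, g_Na = 0, g_K = 0, g_A = 0,
                       cpt_in = ci)
    s <- simulate_neuron(p, excit = 10, inhib = NULL, duration = 80,
                         model = "cable", record_dt = 0.1)
    dep <- s$V[, 1] - s$V[1, 1]
    peaks <- c(peaks, max(dep))
    lats <- c(lats, s$time[which.max(dep)])
  }
  expect_true(all(diff(peaks) < 0))
  expect_true(all(diff(lats) > 0))
})

test_that("parameter sets validate and round-trip through JSON", {
  expect_error(neuron_params(g_A = -1), "non-negative")
  expect_error(neuron_params(nonsense = 1), "unknown")
  expect_error(neuron_params(cpt_in = 10), "cpt_in")
  p <- neuron_params(g_A = 37.5, tau_a = 0.5, instantaneous_a = TRUE)
  f <- withr::local_tempfile(fileext = ".json")
  write_params(p, f)
  expect_equal(read_params(f), p)
})
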