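#' Floor of the periodic inhibitory gate
#'
#' Between periodic inhibitory events the gate decays as
#' `exp(-beta_I t)`, so after the first event it never falls below
#' `sigma* = exp(-beta_I * P_I)` with period `P_I = 1000 / r_I` ms.
#'
#' @param beta_I inhibitory decay constant (1/ms).
#' @param r_I inhibitory rate (events/s).
#' @return `sigma*` in (0, 1).
#' @examples
#' sigma_star(0.18, 50)  # exp(-3.6)
#' @export
sigma_star <- function(beta_I, r_I) {
  if (r_I <= 0) stop("r_I must be positive")
  exp(-beta_I * 1000 / r_I)
}

#' Quasi-steady membrane voltage under fixed synaptic gates
#'
#' Treating voltage as fast and dropping the voltage-gated currents, the
#' membrane equation is linear and its equilibrium is the
#' conductance-weighted average of the leak and synaptic reversal
#' potentials.  Setting one gate to zero gives the single-input forms
#' used to drive the slow inactivation variable.
#'
#' @param s_E,s_I synaptic gate values in \[0, 1\] (vectorised).
#' @param params a [neuron_params()] list.
#' @return Voltage (mV).
#' @export
quasi_steady_V <- function(s_E, s_I, params = neuron_params()) {
  (params$g_L * params$V_L + params$g_SynE * s_E * params$V_E +
     params$g_SynI * s_I * params$V_I) /
    (params$g_L + params$g_SynE * s_E + params$g_SynI * s_I)
}

#' Average of the slow A-current inactivation variable
#'
#' The inactivation variable `b` evolves on a 150 ms time scale and is
#' replaced by its average along solutions.  Three estimates of
#' increasing reduction are available:
#' \describe{
#'   \item{`"full"`}{time-average of `b` from a full-model simulation with
#'     both inputs on (depends on `params$g_A`).}
#'   \item{`"passive"`}{simulations with `g_A = g_K = g_Na = 0`, run once
#'     with only excitation and once with only inhibition, combined as
#'     `b_I + b_E(r_E) - b_E(0)`.}
#'   \item{`"reduced"`}{the scalar equation
#'     `b' = phi_b (b_inf(V(t)) - b) / tau_b` driven by the quasi-steady
#'     single-input voltages, combined the same way.  This is the value
#'     used throughout the knee analysis.}
#' }
#' With no input the voltage sits at the leak reversal, where
#' `b_inf(-70) = 1/2`, so the excitation-at-zero baseline is exactly 0.5.
#'
#' @param r_E excitatory rate (events/s).
#' @param method `"reduced"`, `"passive"` or `"full"`.
#' @param params a [neuron_params()] list (the reduced-analysis drive is
#'   `g_SynE = 3`, `g_SynI = 5`).
#' @param r_I inhibitory rate (events/s).
#' @param duration simulated time (ms) for the Poisson-driven excitatory
#'   component.
#' @param seed seed for the excitatory train.
#' @return Estimated average of `b` in (0, 1).
#' @export
b_average <- function(r_E, method = c("reduced", "passive", "full"),
                      params = neuron_params(g_SynE = 3, g_SynI = 5),
                      r_I = 50, duration = 100000, seed = 1) {
  method <- match.arg(method)
  if (r_E < 0) stop("r_E must be non-negative")
  if (method == "reduced") {
    bI <- b_component_reduced(NULL, params, r_I, periodic = TRUE)
    bE <- if (r_E == 0) 0.5 else
      b_component_reduced(r_E, params, r_I, periodic = FALSE,
                          duration = duration, seed = seed)
    return(bI + bE - 0.5)
  }
  if (method == "passive") {
    pp <- params; pp$g_A <- 0; pp$g_K <- 0; pp$g_Na <- 0
    inh <- periodic_train(r_I, 8000)
    bI <- simulate_neuron(pp, NULL, inh, 8000, transient = 1500)$b_mean
    bE <- if (r_E == 0) 0.5 else {
      exc <- poisson_train(r_E, duration, seed = seed)
      simulate_neuron(pp, exc, NULL, duration, transient = 1500)$b_mean
    }
    return(bI + bE - 0.5)
  }
  exc <- poisson_train(r_E, duration, seed = seed)
  inh <- periodic_train(r_I, duration)
  simulate_neuron(params, exc, inh, duration, transient = 1500)$b_mean
}

# scalar b-equation driven by the quasi-steady single-input voltage
b_component_reduced <- function(r_E, params, r_I, periodic,
                                duration = 8000, seed = 1) {
  if (periodic) {
    ev <- periodic_train(r_I, duration)$times
    beta <- params$beta_I; g <- params$g_SynI; Vr <- params$V_I
    tr <- max(10 * params$tau_b, duration / 4)
  } else {
    ev <- poisson_train(r_E, duration, seed = seed)$times
    beta <- params$beta_E; g <- params$g_SynE; Vr <- params$V_E
    tr <- 10 * params$tau_b
  }
  .sim_b_quasi_cpp(unclass(params), ev, beta, g, Vr, 0.5,
                   duration, tr, 0.05)$b_mean
}

#' Table of reduced b averages over an excitatory-rate grid
#'
#' Precomputes `b*_av(r_E)` on a grid and returns a linear interpolant;
#' the inhibitory component is computed once.
#'
#' @param r_E_grid grid of excitatory rates (events/s) starting at 0.
#' @inheritParams b_average
#' @return List with `r_E`, `b`, and `fun` (the interpolating function,
#'   constant beyond the grid ends).
#' @export
b_table <- function(r_E_grid = seq(0, 100, by = 10),
                    params = neuron_params(g_SynE = 3, g_SynI = 5),
                    r_I = 50, duration = 100000, seed = 1) {
  bI <- b_component_reduced(NULL, params, r_I, periodic = TRUE)
  bE <- vapply(r_E_grid, function(re) {
    if (re == 0) 0.5 else
      b_component_reduced(re, params, r_I, periodic = FALSE,
                          duration = duration, seed = seed)
  }, numeric(1))
  b <- bI + bE - 0.5
  list(r_E = r_E_grid, b = b,
       fun = stats::approxfun(r_E_grid, b, rule = 2))
}

#' V-nullcline of the reduced model
#'
#' With instantaneous A-current activation the condition `dV/dt = 0` at
#' fixed `b`, `s_E`, `s_I` is a quartic in the recovery variable `n`:
#' `g_K (V - V_K) n^4 - g_Na m^3 (V - V_Na) n + [rest] = 0`.
#' `nullcline_n()` returns all real roots at a single voltage (values
#' below 0 or above 1 are analytic continuations of the curve and are
#' retained deliberately).  `nullcline_branch()` returns the largest real
#' root, which traces the physiologically relevant branch as a
#' single-valued function of `V`.
#'
#' @param V voltage (mV); scalar for `nullcline_n`, vector for
#'   `nullcline_branch`.
#' @param b inactivation level in (0, 1).
#' @param s_E,s_I synaptic gate values.
#' @param g_A A-current maximal conductance (mS/cm^2).
#' @param params a [neuron_params()] list (supplies the remaining
#'   conductances and the synaptic strengths).
#' @return `nullcline_n`: sorted numeric vector of real roots (possibly
#'   empty); `nullcline_branch`: numeric vector of the branch values
#'   (`NA` where no real root exists).
#' @export
nullcline_n <- function(V, b, s_E, s_I, g_A, params = neuron_params()) {
  stopifnot(length(V) == 1)
  A <- params$g_K * (V - params$V_K)
  m3 <- m_inf(V)^3
  B <- params$g_Na * m3 * (V - params$V_Na)
  a3 <- gate_steady_state("a", V, params)^3
  const <- params$g_L * (V - params$V_L) +
    g_A * a3 * b * (V - params$V_K) + B +
    params$g_SynE * s_E * (V - params$V_E) +
    params$g_SynI * s_I * (V - params$V_I)
  if (abs(A) < 1e-14) {            # V = V_K: the quartic degenerates
    if (abs(B) < 1e-14) return(numeric(0))
    return(const / B - 0)          # -B n + const = 0 up to sign below
  }
  r <- polyroot(c(const, -B, 0, 0, A))
  sort(Re(r[abs(Im(r)) < 1e-7 * (1 + abs(Re(r)))]))
}

#' @rdname nullcline_n
#' @export
nullcline_branch <- function(V, b, s_E, s_I, g_A, params = neuron_params()) {
  vapply(V, function(v) {
    r <- nullcline_n(v, b, s_E, s_I, g_A, params)
    if (length(r)) max(r) else NA_real_
  }, numeric(1))
}

#' Locate a knee (fold) of the V-nullcline
#'
#' Along the branch `n(V)` the left knee is the interior local minimum
#' separating the left and middle branches — the spike-initiation
#' criterion: an excitatory input evokes a spike only if the current `n`
#' lies below this fold.  The right knee is the local maximum beyond it,
#' from which the trajectory jumps down at the end of the active phase.
#' The fold is bracketed on a coarse voltage grid and refined by
#' golden-section search; its `n` value may be negative (the curve is
#' continued below `n = 0`, where the neuron cannot fire at all).
#'
#' @inheritParams nullcline_n
#' @param side `"left"` or `"right"`.
#' @param V_range search interval (mV).
#' @param dV coarse bracketing resolution (mV).
#' @return Object of class `"knee_point"`: list with `V`, `n`, `side`.
#' @export
find_knee <- function(b, s_E, s_I, g_A, side = c("left", "right"),
                      params = neuron_params(), V_range = NULL, dV = 0.25) {
  side <- match.arg(side)
  if (is.null(V_range))
    V_range <- if (side == "left") c(-75, -15) else c(-45, 50)
  f <- function(v) nullcline_branch(v, b, s_E, s_I, g_A, params)
  Vall <- seq(V_range[1], V_range[2], by = dV)
  nall <- f(Vall)
  ok <- !is.na(nall)
  if (sum(ok) < 3) stop("no knee: nullcline branch absent in V range")
  # work on the contiguous real segment starting at the low-V end
  last <- if (all(ok)) length(ok) else which(!ok)[1] - 1
  if (last < 3) stop("no knee: nullcline branch absent in V range")
  Vg <- Vall[seq_len(last)]; ng <- nall[seq_len(last)]
  sgn <- if (side == "left") 1 else -1
  d <- diff(sgn * ng)
  i <- which(d[-length(d)] < 0 & d[-1] > 0) + 1  # interior local extremum
  if (length(i)) {
    i <- if (side == "left") i[1] else i[length(i)]
    o <- stats::optimize(function(v) {
      val <- sgn * f(v)
      if (is.na(val)) 1e10 else val
    }, c(Vg[i - 1], Vg[i + 1]), tol = 1e-8)
    return(structure(list(V = o$minimum, n = sgn * o$objective, side = side),
                     class = "knee_point"))
  }
  # no interior extremum: if the branch terminates inside the range the
  # two largest roots collide there -- the fold itself is the knee
  # (approached decreasing on the left side, increasing on the right)
  if (last < length(Vall) &&
      ((side == "left" && d[length(d)] < 0) ||
       (side == "right" && d[length(d)] > 0))) {
    lo <- Vg[last]; hi <- Vall[last + 1]
    for (k in 1:40) {
      mid <- (lo + hi) / 2
      if (is.na(f(mid))) hi <- mid else lo <- mid
    }
    return(structure(list(V = lo, n = f(lo), side = side),
                     class = "knee_point"))
  }
  stop("no knee: branch has no interior fold on the ", side, " side")
}

#' @export
print.knee_point <- function(x, ...) {
  cat(sprintf("%s knee: V = %.3f mV, n = %.5f\n", x$side, x$V, x$n))
  invisible(x)
}

#' Left-knee level N_lk as a function of inhibition, input rate and g_A
#'
#' Convenience wrapper evaluating the left knee of the `s_E = 1`
#' nullcline with `b` replaced by the reduced average `b*_av(r_E)`.
#'
#' @param s_I inhibitory gate value.
#' @param r_E excitatory rate (events/s), mapped through `b_fun`.
#' @param g_A A-current conductance (mS/cm^2).
#' @param b_fun function `r_E -> b*_av` (e.g. `b_table()$fun`).
#' @param params a [neuron_params()] list.
#' @return The `n` value at the left knee (may be negative).
#' @export
N_lk <- function(s_I, r_E, g_A, b_fun, params = neuron_params(g_SynE = 3,
                                                              g_SynI = 5)) {
  find_knee(b_fun(r_E), s_E = 1, s_I = s_I, g_A = g_A, side = "left",
            params = params)$n
}

#' Critical A-current conductance for loss of excitability
#'
#' The neuron cannot respond to any excitatory input once the left knee
#' of the `s_E = 1` nullcline (evaluated at the inhibitory-gate floor
#' `sigma*` and `r_E = 0`) falls below `n = 0`.  The critical conductance
#' `g_A0` is the root of `g_A -> N_lk(sigma*, 0, g_A)`, found by
#' bisection.  Below `g_A0` inhibition is divisive (the neuron responds
#' to arbitrarily low input rates); above it, subtractive.
#'
#' @param params a [neuron_params()] list with the reduced-analysis drive.
#' @param r_I inhibitory rate (events/s).
#' @param b0 the average inactivation at `r_E = 0`; computed from the
#'   reduced scalar equation when `NULL`.
#' @param bracket search interval for `g_A` (mS/cm^2).
#' @param tol bisection tolerance.
#' @return `g_A0` (mS/cm^2) with attributes `N_lk_residual` and `b0`.
#' @export
critical_gA <- function(params = neuron_params(g_SynE = 3, g_SynI = 5),
                        r_I = 50, b0 = NULL, bracket = c(5, 60), tol = 1e-3) {
  if (is.null(b0)) b0 <- b_average(0, "reduced", params, r_I)
  ss <- sigma_star(params$beta_I, r_I)
  f <- function(g) find_knee(b0, 1, ss, g, "left", params)$n
  lo <- f(bracket[1]); hi <- f(bracket[2])
  if (lo * hi > 0) stop("no excitability transition in the g_A bracket")
  root <- stats::uniroot(f, bracket, tol = tol)$root
  structure(root, N_lk_residual = f(root), b0 = b0)
}

#' Minimum responsive input rate Gamma(g_A)
#'
#' For `g_A` above the critical conductance the left knee at the
#' inhibitory floor is below zero at low input rates and rises through
#' zero as `r_E` grows (via the decreasing inactivation average
#' `b*_av(r_E)`).  `Gamma(g_A)` is the input rate at which the knee
#' crosses zero: below it the reduced model cannot fire at all; at or
#' below the critical conductance the function is 0.
#'
#' @inheritParams critical_gA
#' @param g_A A-current conductance (mS/cm^2).
#' @param btab a [b_table()] list (built with defaults when `NULL`).
#' @param r_E_max upper search limit (events/s).
#' @return Minimum responsive rate (events/s).
#' @export
gamma_curve <- function(g_A, params = neuron_params(g_SynE = 3, g_SynI = 5),
                        r_I = 50, btab = NULL, r_E_max = 100) {
  if (is.null(btab)) btab <- b_table(params = params, r_I = r_I)
  ss <- sigma_star(params$beta_I, r_I)
  f <- function(re) find_knee(btab$fun(re), 1, ss, g_A, "left", params)$n
  if (f(0) >= 0) return(0)
  if (f(r_E_max) < 0)
    stop("left knee stays below zero up to r_E = ", r_E_max)
  stats::uniroot(f, c(0, r_E_max), tol = 1e-3)$root
}

#' Dead-time-modified Poisson output rate
#'
#' Thinning a Poisson input of rate `r_E` by an absolute refractory
#' interval `R` gives `r_out = r_E / (1 + r_E R)`; a further factor `rho`
#' is the fraction of time inhibition permits spiking.
#'
#' @param r_E input rate (events/s), vectorised.
#' @param R dead time (ms).
#' @param rho responsive fraction in \[0, 1\].
#' @return Output rate (spikes/s).
#' @export
deadtime_rate <- function(r_E, R, rho = 1) {
  if (any(R < 0)) stop("R must be non-negative")
  r_E * rho / (1 + r_E * R / 1000)
}

#' Fraction of the inhibitory period below a gate threshold
#'
#' With periodic inhibition the gate is `exp(-beta_I t)` within each
#' period, so it lies below `theta` for the fraction
#' `1 + log(theta) / (P_I beta_I)` of the time (natural logarithm,
#' clipped to \[0, 1\]).  At `theta = sigma*` the fraction is exactly 0
#' and at `theta = 1` exactly 1.
#'
#' @param theta gate threshold in (0, 1\].
#' @param P_I inhibitory period (ms).
#' @param beta_I inhibitory decay constant (1/ms).
#' @return Fraction in \[0, 1\].
#' @export
rho_fraction <- function(theta, P_I, beta_I) {
  if (any(theta <= 0)) stop("theta must be positive")
  pmin(1, pmax(0, 1 + log(theta) / (P_I * beta_I)))
}

#' Fit the refractory dead time from a no-inhibition rate curve
#'
#' Least-squares fit of `r_out = r_E / (1 + r_E R)` to paired input and
#' output rates, as a one-parameter bounded line search.
#'
#' @param r_E,r_out paired rates (events/s, spikes/s), or a `rate_curve`
#'   as `r_E` (its no-inhibition column is used).
#' @param R_max upper bound of the search (ms).
#' @return Fitted `R` (ms) with attribute `sse`.
#' @export
fit_refractory_R <- function(r_E, r_out = NULL, R_max = 200) {
  if (inherits(r_E, "rate_curve")) {
    r_out <- r_E$r_out_noinh; r_E <- r_E$r_E
  }
  stopifnot(length(r_E) == length(r_out))
  o <- stats::optimize(function(R) sum((r_out - deadtime_rate(r_E, R))^2),
                       c(0, R_max), tol = 1e-6)
  structure(o$minimum, sse = o$objective)
}

#' Assemble the reduced-theory context
#'
#' Precomputes every ingredient of the dead-time-modified Poisson rate
#' approximation at a given `g_A`: the inhibitory-gate floor `sigma*`,
#' the period `P_I`, the `b*_av(r_E)` interpolant, the right-knee level
#' `N_rk` (treated as a constant, evaluated at `s_E = 1`,
#' `s_I = sigma*`, `b = b*_av(0)`), the silent-phase time constant
#' `tau_0 = tau_n(V_L)`, and the refractory dead time `R` (fitted from a
#' simulated no-inhibition curve when not supplied).
#'
#' @param g_A A-current conductance (mS/cm^2).
#' @param params a [neuron_params()] list (reduced-analysis drive).
#' @param r_I inhibitory rate (events/s).
#' @param btab optional precomputed [b_table()].
#' @param R dead time (ms); fitted when `NULL`.
#' @param tau_0 silent-phase time constant (ms); default `tau_n(-70)`.
#' @param fit_duration duration (ms) per point of the R-fit curve.
#' @param seed seed for the R-fit simulations.
#' @return List of class `"reduced_context"`.
#' @export
reduced_context <- function(g_A, params = neuron_params(g_SynE = 3, g_SynI = 5,
                                                        instantaneous_a = TRUE),
                            r_I = 50, btab = NULL, R = NULL, tau_0 = NULL,
                            fit_duration = 10000, seed = 1) {
  if (is.null(btab)) btab <- b_table(params = params, r_I = r_I)
  ss <- sigma_star(params$beta_I, r_I)
  if (is.null(tau_0)) tau_0 <- tau_n_of_V(params$V_L)
  if (is.null(R)) {
    p <- params; p$g_A <- g_A
    cv <- compute_rate_curve(p, r_E = seq(10, 150, by = 10), r_I = r_I,
                             duration = fit_duration, seed = seed)
    R <- as.numeric(fit_refractory_R(cv))
  }
  N_rk <- find_knee(btab$fun(0), 1, ss, g_A, "right", params)$n
  structure(list(g_A = g_A, sigma_star = ss, P_I = 1000 / r_I,
                 beta_I = params$beta_I, btab = btab, N_rk = N_rk,
                 tau_0 = tau_0, phi_n = params$phi_n, R = R,
                 params = params),
            class = "reduced_context")
}

#' @export
print.reduced_context <- function(x, ...) {
  cat(sprintf(paste0("Reduced-theory context (g_A = %g):\n",
                     "  sigma* = %.5f, P_I = %g ms, N_rk = %.4f,\n",
                     "  tau_0 = %.2f ms, R = %.2f ms, b*_av(0) = %.4f\n"),
              x$g_A, x$sigma_star, x$P_I, x$N_rk, x$tau_0, x$R,
              x$btab$fun(0)))
  invisible(x)
}

#' Firing threshold from the fixed point of the knee and recovery maps
#'
#' The firing threshold `theta` is the inhibitory-gate value above which
#' an excitatory event fails to evoke a spike.  It is computed as a fixed
#' point of two maps: `Theta(n_av)` inverts the left-knee relation
#' (`s_I` such that `N_lk(s_I, r_E, g_A) = n_av`), and `N(theta)` gives
#' the average recovery level
#' `n_av = N_rk exp(-1000 phi_n / (tau_0 r_out))` with `r_out` from the
#' dead-time-modified Poisson rate at responsive fraction
#' `rho(theta)`.  The composition is a continuous self-map of \[0, 1\],
#' solved by bisection.
#'
#' When no `s_I` in (0, 1] attains the requested knee level the map is
#' clamped at the nearer boundary and the result flagged.
#'
#' @param r_E excitatory rate (events/s).
#' @param g_A A-current conductance; must match `context$g_A`.
#' @param context a [reduced_context()].
#' @return List with `theta`, `n_av`, `r_out` (theory rate, spikes/s),
#'   `rho`, `residual`, `clamped`.
#' @export
firing_threshold <- function(r_E, g_A, context) {
  stopifnot(inherits(context, "reduced_context"))
  if (!isTRUE(all.equal(g_A, context$g_A)))
    stop("context was built for g_A = ", context$g_A)
  ctx <- context
  clamped <- FALSE
  knee_n <- function(sI) tryCatch(
    find_knee(ctx$btab$fun(r_E), 1, sI, g_A, "left", ctx$params)$n,
    error = function(e) -1e3)  # knee lost below the plane: cannot fire
  Theta <- function(n_av) {
    f <- function(sI) knee_n(sI) - n_av
    lo <- 1e-6
    flo <- f(lo); fhi <- f(1)
    if (flo < 0) { clamped <<- TRUE; return(lo) }  # even weakest inhibition blocks
    if (fhi > 0) return(1)                         # firing survives full inhibition
    stats::uniroot(f, c(lo, 1), tol = 1e-7)$root
  }
  Nmap <- function(theta) {
    rho <- rho_fraction(theta, ctx$P_I, ctx$beta_I)
    r_out <- deadtime_rate(r_E, ctx$R, rho)
    if (r_out <= 0) return(0)
    ctx$N_rk * exp(-1000 * ctx$phi_n / (ctx$tau_0 * r_out))
  }
  g <- function(n) n - Nmap(Theta(n))
  lo <- 0; hi <- 1
  if (g(lo) > 0) { n_star <- 0 } else {
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < 1e-9) break
    }
    n_star <- (lo + hi) / 2
  }
  theta <- Theta(n_star)
  rho <- rho_fraction(theta, ctx$P_I, ctx$beta_I)
  list(theta = theta, n_av = n_star,
       r_out = deadtime_rate(r_E, ctx$R, rho), rho = rho,
       residual = abs(n_star - Nmap(theta)), clamped = clamped)
}

#' Slope of the input/output curve at firing onset
#'
#' Differentiating the dead-time-modified rate approximation at
#' `r_E = 0` gives `1 + log(theta_0) / (P_I beta_I)` where `theta_0` is
#' the firing threshold at zero input rate (the `s_I` level at which the
#' left knee sits exactly at `n = 0`).  The slope is clipped below at 0;
#' it reaches 0 precisely at the critical conductance.
#'
#' @inheritParams firing_threshold
#' @return Dimensionless onset slope in \[0, 1\].
#' @export
onset_slope <- function(g_A, context) {
  stopifnot(inherits(context, "reduced_context"))
  ctx <- context
  f <- function(sI) find_knee(ctx$btab$fun(0), 1, sI, g_A, "left",
                              ctx$params)$n
  lo <- 1e-6
  if (f(lo) < 0) return(0)       # knee below zero even without inhibition
  if (f(1) > 0) return(1)        # full inhibition cannot block firing
  theta0 <- stats::uniroot(f, c(lo, 1), tol = 1e-7)$root
  max(0, 1 + log(theta0) / (ctx$P_I * ctx$beta_I))
}

#' Theoretical input/output curve from the dead-time approximation
#'
#' Evaluates the dead-time-modified Poisson rate with the
#' inhibition-dependent responsive fraction obtained from the
#' fixed-point firing threshold at every grid point.  With the threshold
#' forced to 1 (no inhibition) it reduces to `r_E / (1 + r_E R)`.
#'
#' @param r_E_grid excitatory rates (events/s).
#' @inheritParams firing_threshold
#' @param with_inhibition logical; `FALSE` gives the pure dead-time curve.
#' @return Data frame with `r_E`, `r_out`, `theta`, `rho`.
#' @export
theory_rate_curve <- function(r_E_grid, g_A, context, with_inhibition = TRUE) {
  rows <- lapply(r_E_grid, function(re) {
    if (!with_inhibition)
      return(data.frame(r_E = re, r_out = deadtime_rate(re, context$R),
                        theta = 1, rho = 1))
    ft <- firing_threshold(re, g_A, context)
    data.frame(r_E = re, r_out = ft$r_out, theta = ft$theta, rho = ft$rho)
  })
  do.call(rbind, rows)
}
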