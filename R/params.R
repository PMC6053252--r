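#' Model parameters for the point neuron and soma-dendrite cable
#'
#' Builds the full parameter set of the conductance-based model: membrane
#' constants, gating kinetics for the delayed-rectifier activation `n` and
#' the A-current activation/inactivation pair `a`/`b`, synaptic reversal
#' potentials and decay constants, and the passive-cable constants used by
#' the multi-compartment variant.  All values default to the standard set;
#' any field can be overridden by name.
#'
#' Units are mV, ms, mS/cm^2, uA/cm^2 and uF/cm^2 throughout; input rates
#' are expressed in events/s and converted internally (an inhibitory rate
#' `r_I` corresponds to a period `P_I = 1000 / r_I` ms).
#'
#' The slope entries `sigma_n`, `sigma_a`, `sigma_b` are stored as
#' magnitudes; the direction of each steady-state sigmoid is fixed by the
#' physiology of the gate (activation gates `n` and `a` increase with
#' voltage, the inactivation gate `b` decreases).
#'
#' @param ... named overrides of any default, e.g. `g_A = 40`,
#'   `instantaneous_a = TRUE`, `tau_a = 0.5`.
#' @return A named list of class `"neuron_params"`.
#' @examples
#' p <- neuron_params(g_A = 40, g_SynE = 0.5, g_SynI = 1)
#' p$g_A
#' @export
neuron_params <- function(...) {
  p <- list(
    # membrane
    C = 1, g_L = 1, g_K = 45, g_Na = 37, g_A = 20,
    V_L = -70, V_K = -80, V_Na = 55,
    # gating (slopes as magnitudes, see Details)
    phi_n = 0.75, theta_n = -32, sigma_n = 8,
    phi_a = 1, theta_a = -50, sigma_a = 20, tau_a = 2,
    phi_b = 1, theta_b = -70, sigma_b = 6, tau_b = 150,
    # synapses
    g_SynE = 0.5, g_SynI = 1, V_E = 0, V_I = -85,
    beta_E = 0.2, beta_I = 0.18,
    # reduced-model flag: a = a_inf(V)
    instantaneous_a = FALSE,
    # cable
    n_comp = 10, g_L_dend = 0.1, g_Ax = 10, cpt_in = 1, cpt_inhib = 0
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  cond <- c("g_L", "g_K", "g_Na", "g_A", "g_SynE", "g_SynI", "g_L_dend", "g_Ax")
  if (any(unlist(p[cond]) < 0)) stop("conductances must be non-negative")
  if (p$C <= 0) stop("capacitance must be positive")
  if (p$tau_a <= 0 || p$tau_b <= 0) stop("gating time constants must be positive")
  if (p$beta_E <= 0 || p$beta_I <= 0) stop("synaptic decay rates must be positive")
  if (p$cpt_in < 1 || p$cpt_in > p$n_comp - 1) stop("cpt_in must be in 1..9")
  if (p$cpt_inhib < 0 || p$cpt_inhib > p$n_comp - 1) stop("cpt_inhib must be in 0..9")
  class(p) <- "neuron_params"
  p
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("Conductance-based neuron parameters\n")
  cat(sprintf("  g_A = %g, g_K = %g, g_Na = %g, g_L = %g mS/cm^2\n",
              x$g_A, x$g_K, x$g_Na, x$g_L))
  cat(sprintf("  g_SynE = %g, g_SynI = %g mS/cm^2;  tau_a = %g ms\n",
              x$g_SynE, x$g_SynI, x$tau_a))
  cat(sprintf("  A-current activation: %s\n",
              if (x$instantaneous_a) "instantaneous (a = a_inf(V))" else "dynamic"))
  invisible(x)
}

#' Steady-state gating curves and voltage-dependent time constants
#'
#' `gate_steady_state()` evaluates the logistic steady-state function of a
#' gating variable at voltage `V`: the delayed-rectifier activation `n` and
#' A-current activation `a` increase with voltage, the A-current
#' inactivation `b` decreases; each equals 1/2 at its half-activation
#' voltage.  `tau_n_of_V()` is the voltage-dependent time constant of `n`;
#' `m_inf()` the instantaneous sodium activation.
#'
#' @param gate one of `"n"`, `"a"`, `"b"`.
#' @param V membrane potential (mV), vectorised.
#' @param params a [neuron_params()] list.
#' @return Gating values in (0, 1), or time constants in ms.
#' @examples
#' gate_steady_state("n", -32)  # 0.5 at the half-activation voltage
#' @export
gate_steady_state <- function(gate, V, params = neuron_params()) {
  gate <- match.arg(gate, c("n", "a", "b"))
  th <- params[[paste0("theta_", gate)]]
  sg <- params[[paste0("sigma_", gate)]]
  dir <- if (gate == "b") -1 else 1
  1 / (1 + exp(-dir * (V - th) / sg))
}

#' @rdname gate_steady_state
#' @export
tau_n_of_V <- function(V) 1 + 100 / (1 + exp((V + 80) / 26))

#' @rdname gate_steady_state
#' @export
m_inf <- function(V) 1 / (1 + exp(-(V + 30) / 15))

#' Ionic membrane currents
#'
#' Evaluates the four intrinsic currents at a given state: leak
#' `I_L = g_L (V - V_L)`, delayed-rectifier `I_K = g_K n^4 (V - V_K)`,
#' A-type `I_A = g_A a^3 b (V - V_K)` and sodium
#' `I_Na = g_Na m_inf(V)^3 (1 - n)(V - V_Na)` (sodium inactivation is
#' slaved to `h = 1 - n`).  When `params$instantaneous_a` is set, `a` is
#' replaced by `a_inf(V)`.
#'
#' @param state named numeric vector or list with `V`, `n`, `a`, `b`.
#' @param params a [neuron_params()] list.
#' @return Named vector `c(I_L, I_K, I_A, I_Na)` in uA/cm^2.
#' @export
ionic_currents <- function(state, params = neuron_params()) {
  V <- state[["V"]]; n <- state[["n"]]; b <- state[["b"]]
  a <- if (isTRUE(params$instantaneous_a)) gate_steady_state("a", V, params)
       else state[["a"]]
  m <- m_inf(V)
  c(I_L  = params$g_L * (V - params$V_L),
    I_K  = params$g_K * n^4 * (V - params$V_K),
    I_A  = params$g_A * a^3 * b * (V - params$V_K),
    I_Na = params$g_Na * m^3 * (1 - n) * (V - params$V_Na))
}

#' Point-neuron right-hand side
#'
#' Time derivatives of `(V, n, a, b)` for the one-compartment model with
#' synaptic gate values supplied as instantaneous numbers (the gates decay
#' in closed form between events and are not part of the ODE state).
#' Primarily useful for phase-plane work and as a reference for the
#' compiled integrator.
#'
#' @param t time (ms); unused (the system is autonomous between events).
#' @param state named vector with `V`, `n`, `a`, `b`.
#' @param params a [neuron_params()] list.
#' @param s_E,s_I synaptic gate values in \[0, 1\].
#' @return Named vector of derivatives `(dV, dn, da, db)`.
#' @export
point_rhs <- function(t, state, params = neuron_params(), s_E = 0, s_I = 0) {
  if (!all(is.finite(unlist(state)))) stop("non-finite state")
  V <- state[["V"]]; n <- state[["n"]]; b <- state[["b"]]
  I <- ionic_currents(state, params)
  I_syn <- params$g_SynE * s_E * (V - params$V_E) +
           params$g_SynI * s_I * (V - params$V_I)
  dV <- (-sum(I) - I_syn) / params$C
  dn <- params$phi_n * (gate_steady_state("n", V, params) - n) / tau_n_of_V(V)
  da <- if (isTRUE(params$instantaneous_a)) 0 else
    params$phi_a * (gate_steady_state("a", V, params) - state[["a"]]) / params$tau_a
  db <- params$phi_b * (gate_steady_state("b", V, params) - b) / params$tau_b
  c(dV = dV, dn = dn, da = da, db = db)
}

#' Soma-dendrite cable right-hand side
#'
#' Derivatives for the 10-compartment model: compartment 1 is the soma and
#' carries all voltage-gated currents; compartments 2-10 form a passive
#' dendrite with leak `g_L_dend` and the common leak reversal.  The axial
#' current stencil is a discrete divergence, so it sums to zero over
#' compartments.  Excitation enters the dendritic compartment
#' `cpt_in + 1`; inhibition enters the soma when `cpt_inhib = 0`, else
#' compartment `cpt_inhib + 1`.
#'
#' @param t time (ms); unused.
#' @param state numeric vector `c(V_1..V_10, n, a, b)`.
#' @inheritParams point_rhs
#' @return Numeric vector of derivatives, same layout as `state`.
#' @export
cable_rhs <- function(t, state, params = neuron_params(), s_E = 0, s_I = 0) {
  nc <- params$n_comp
  V <- state[1:nc]; n <- state[nc + 1]; b <- state[nc + 3]
  a <- if (isTRUE(params$instantaneous_a)) gate_steady_state("a", V[1], params)
       else state[nc + 2]
  I_ax <- numeric(nc)
  I_ax[1] <- params$g_Ax * (V[1] - V[2])
  I_ax[nc] <- params$g_Ax * (V[nc] - V[nc - 1])
  j <- 2:(nc - 1)
  I_ax[j] <- params$g_Ax * (-V[j - 1] + 2 * V[j] - V[j + 1])
  m <- m_inf(V[1])
  I_soma <- params$g_L * (V[1] - params$V_L) +
    params$g_K * n^4 * (V[1] - params$V_K) +
    params$g_A * a^3 * b * (V[1] - params$V_K) +
    params$g_Na * m^3 * (1 - n) * (V[1] - params$V_Na)
  dV <- numeric(nc)
  dV[1] <- -(I_soma + I_ax[1])
  dV[-1] <- -(params$g_L_dend * (V[-1] - params$V_L) + I_ax[-1])
  exc <- params$cpt_in + 1L
  dV[exc] <- dV[exc] - params$g_SynE * s_E * (V[exc] - params$V_E)
  inh <- params$cpt_inhib + 1L
  dV[inh] <- dV[inh] - params$g_SynI * s_I * (V[inh] - params$V_I)
  dV <- dV / params$C
  dn <- params$phi_n * (gate_steady_state("n", V[1], params) - n) / tau_n_of_V(V[1])
  da <- if (isTRUE(params$instantaneous_a)) 0 else
    params$phi_a * (gate_steady_state("a", V[1], params) - state[nc + 2]) / params$tau_a
  db <- params$phi_b * (gate_steady_state("b", V[1], params) - b) / params$tau_b
  c(dV, dn, da, db)
}

#' Resting equilibrium of the input-free model
#'
#' Finds the rest state by root-finding on the steady-state current
#' balance: with gates at their voltage-dependent steady states the
#' membrane equation reduces to a scalar function of `V`.
#'
#' @param params a [neuron_params()] list.
#' @param interval voltage bracket (mV) for the root search.
#' @return Named vector `c(V, n, a, b)` at rest.
#' @export
rest_state <- function(params = neuron_params(), interval = c(-90, -40)) {
  f <- function(V) {
    st <- c(V = V,
            n = gate_steady_state("n", V, params),
            a = gate_steady_state("a", V, params),
            b = gate_steady_state("b", V, params))
    -sum(ionic_currents(st, params))
  }
  Vg <- seq(interval[1], interval[2], by = 0.25)
  fv <- vapply(Vg, f, numeric(1))
  i <- which(fv[-1] * fv[-length(fv)] <= 0)
  if (!length(i)) stop("no resting equilibrium in the search interval")
  V0 <- stats::uniroot(f, c(Vg[i[1]], Vg[i[1] + 1]), tol = 1e-10)$root
  c(V = V0,
    n = gate_steady_state("n", V0, params),
    a = gate_steady_state("a", V0, params),
    b = gate_steady_state("b", V0, params))
}

#' Serialize / restore a parameter set
#'
#' Parameter sets round-trip through flat JSON so that every experiment
#' output can embed its full configuration.
#'
#' @param params a [neuron_params()] list.
#' @param path file path.
#' @return `write_params()` returns `path` invisibly; `read_params()`
#'   returns a validated [neuron_params()] list.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "neuron_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(neuron_params, p)
}
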