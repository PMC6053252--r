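#' Simulate the point-neuron or cable model driven by event trains
#'
#' Integrates the model between consecutive synaptic events with an
#' embedded Runge-Kutta 5(4) pair; synaptic gates are evaluated in closed
#' form within each smooth segment and reset to one at event times (the
#' membrane state is continuous across events, only the gates jump).
#' Spikes are detected during integration as upward crossings of
#' `spike_threshold` on the soma voltage separated by at least `lockout`
#' ms, with linear interpolation of the crossing time.
#'
#' @param params a [neuron_params()] list.
#' @param excit,inhib [event_train][poisson_train] objects (or numeric
#'   event-time vectors); either may be `NULL` for no input.
#' @param duration simulated time (ms).
#' @param model `"point"` or `"cable"`.
#' @param y0 initial state; default is the resting equilibrium (cable
#'   compartments all start at the common leak reversal).
#' @param transient initial stretch (ms) excluded from the time-average of
#'   the inactivation variable `b` reported in the result.
#' @param spike_threshold,lockout spike criterion (mV, ms).  Any threshold
#'   between the subthreshold envelope and the spike overshoot gives
#'   identical counts; -20 mV is robust to slow depolarising ramps.
#' @param abstol,reltol local error tolerances of the adaptive stepper.
#' @param record_dt if positive, state traces are recorded every
#'   `record_dt` ms; if 0 only spikes and summary values are kept.
#' @return An object of class `"neuron_sim"`: list with `spike_times`,
#'   `b_mean`, `final_state`, solver counters, and when recording, `time`
#'   plus trace columns (`V`, `n`, `a`, `b`; for the cable a matrix `V` of
#'   one column per compartment).
#' @examples
#' p <- neuron_params(g_A = 0, g_SynI = 0)
#' s <- simulate_neuron(p, excit = 100, inhib = NULL, duration = 50,
#'                      record_dt = 0.05)
#' length(s$spike_times)  # one spike from a single strong input
#' @export
simulate_neuron <- function(params, excit = NULL, inhib = NULL, duration,
                            model = c("point", "cable"), y0 = NULL,
                            transient = 0, spike_threshold = -20, lockout = 2,
                            abstol = 1e-8, reltol = 1e-6, record_dt = 0) {
  model <- match.arg(model)
  if (duration <= 0) stop("duration must be positive")
  tE <- event_times(excit)
  tI <- event_times(inhib)
  if (is.null(y0)) {
    r <- rest_state(params)
    y0 <- if (model == "point") unname(r)
          else c(rep(params$V_L, params$n_comp), r[["n"]], r[["a"]], r[["b"]])
  }
  fn <- if (model == "point") .sim_point_cpp else .sim_cable_cpp
  out <- fn(unclass(params), tE, tI, y0, duration, transient,
            spike_threshold, lockout, abstol, reltol, record_dt)
  res <- list(spike_times = out$spike_times, b_mean = out$b_mean,
              final_state = out$final_state, n_steps = out$n_steps,
              n_reject = out$n_reject, duration = duration,
              model = model, params = params)
  if (!is.null(out$time)) {
    res$time <- out$time
    S <- out$states
    if (model == "point") {
      res$V <- S[, 1]; res$n <- S[, 2]; res$a <- S[, 3]; res$b <- S[, 4]
    } else {
      nc <- params$n_comp
      res$V <- S[, 1:nc, drop = FALSE]
      res$n <- S[, nc + 1]; res$a <- S[, nc + 2]; res$b <- S[, nc + 3]
    }
  }
  class(res) <- "neuron_sim"
  res
}

event_times <- function(x) {
  if (is.null(x)) return(numeric(0))
  if (inherits(x, "event_train")) return(x$times)
  as.numeric(x)
}

#' @export
print.neuron_sim <- function(x, ...) {
  cat(sprintf("%s-model simulation: %g ms, %d spikes (%.2f spikes/s)\n",
              x$model, x$duration, length(x$spike_times),
              1000 * length(x$spike_times) / x$duration))
  invisible(x)
}

#' @export
plot.neuron_sim <- function(x, compartment = 1, ...) {
  if (is.null(x$time)) stop("simulation was run without trace recording")
  V <- if (is.matrix(x$V)) x$V[, compartment] else x$V
  graphics::plot(x$time, V, type = "l", xlab = "time (ms)",
                 ylab = "V (mV)", ...)
  if (length(x$spike_times))
    graphics::points(x$spike_times, rep(max(V), length(x$spike_times)),
                     pch = 3, col = 2)
  invisible(x)
}

#' Detect spikes in a voltage trace
#'
#' Upward crossings of a threshold separated by at least a lockout
#' interval, with linear interpolation of the crossing times.  The
#' compiled simulator applies the same criterion at full integrator
#' resolution; this function serves recorded or external traces.
#'
#' @param time,V trace (ms, mV) on an increasing time grid.
#' @param threshold crossing level (mV).
#' @param lockout minimum inter-spike separation (ms).
#' @return Numeric vector of spike times (ms).
#' @export
detect_spikes <- function(time, V, threshold = -20, lockout = 2) {
  stopifnot(length(time) == length(V))
  up <- which(V[-1] >= threshold & V[-length(V)] < threshold)
  if (!length(up)) return(numeric(0))
  frac <- (threshold - V[up]) / (V[up + 1] - V[up])
  cand <- time[up] + frac * (time[up + 1] - time[up])
  out <- cand[1]
  for (tc in cand[-1]) if (tc >= out[length(out)] + lockout) out <- c(out, tc)
  out
}

#' Output firing rate under Poisson excitation and periodic inhibition
#'
#' Runs one simulation with freshly generated input trains and returns the
#' firing rate over the analysis window `[transient, duration]`.
#'
#' @param params a [neuron_params()] list; `params$g_SynI` is forced to 0
#'   when `with_inhibition` is `FALSE`.
#' @param r_E excitatory Poisson rate (events/s).
#' @param r_I inhibitory rate (events/s).
#' @param with_inhibition logical.
#' @param duration,transient window control (ms).
#' @param seed integer seed for the excitatory train (and the inhibitory
#'   train in `"poisson"` mode, offset to an independent sub-stream).
#' @param inhib_mode `"periodic"` (default) or `"poisson"`.
#' @param model `"point"` or `"cable"`.
#' @param ... passed to [simulate_neuron()].
#' @return Firing rate (spikes/s) with attribute `"spikes"` (count).
#' @export
output_rate <- function(params, r_E, r_I = 50, with_inhibition = TRUE,
                        duration = 20000, transient = 500, seed = NULL,
                        inhib_mode = c("periodic", "poisson"),
                        model = "point", ...) {
  inhib_mode <- match.arg(inhib_mode)
  if (duration <= transient) stop("duration must exceed transient")
  exc <- poisson_train(r_E, duration, seed = seed)
  inh <- if (!with_inhibition) NULL
  else if (inhib_mode == "periodic") periodic_train(r_I, duration)
  else poisson_train(r_I, duration,
                     seed = if (is.null(seed)) NULL else seed + 777L,
                     kind = "inhibitory")
  p <- params
  if (!with_inhibition) p$g_SynI <- 0
  sim <- simulate_neuron(p, exc, inh, duration, model = model, ...)
  nsp <- sum(sim$spike_times >= transient)
  r <- 1000 * nsp / (duration - transient)
  attr(r, "spikes") <- nsp
  r
}
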