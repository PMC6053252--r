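#' Default excitatory-rate grid for input/output curves
#'
#' Denser below 20 events/s so that the threshold-linear fit window
#' (inhibited rates below 5 spikes/s) always contains enough points, then
#' steps of 5 up to 100 events/s.
#'
#' @return Numeric vector of excitatory rates (events/s).
#' @export
default_rate_grid <- function() c(seq(2.5, 20, by = 2.5), seq(25, 100, by = 5))

#' Input/output firing-rate curve with and without inhibition
#'
#' For each excitatory rate in the grid, simulates the model twice with
#' matched input seeds: once with inhibition off (`g_SynI = 0`) and once
#' with the periodic (or Poisson) inhibitory train on.
#'
#' @param params a [neuron_params()] list.
#' @param r_E grid of excitatory rates (events/s).
#' @param r_I inhibitory rate (events/s).
#' @param duration,transient simulated time and discarded transient (ms)
#'   per grid point.
#' @param seed base seed; point `i` uses `seed * 1000 + i` so curves with
#'   equal `seed` share input realisations across parameter sets.
#' @param inhib_mode `"periodic"` or `"poisson"`.
#' @param model `"point"` or `"cable"`.
#' @return Object of class `"rate_curve"`: a data frame with columns
#'   `r_E`, `r_out_noinh`, `r_out_inh` plus attributes `params`, `seed`,
#'   `duration`, `r_I`, `inhib_mode`, `model`.
#' @export
compute_rate_curve <- function(params, r_E = default_rate_grid(), r_I = 50,
                               duration = 10000, transient = 500, seed = 1,
                               inhib_mode = "periodic", model = "point") {
  if (!length(r_E)) stop("r_E grid is empty")
  run <- function(i, inh) output_rate(params, r_E[i], r_I, inh,
                                      duration = duration,
                                      transient = transient,
                                      seed = seed * 1000L + i,
                                      inhib_mode = inhib_mode, model = model)
  d <- data.frame(
    r_E = r_E,
    r_out_noinh = vapply(seq_along(r_E), run, numeric(1), inh = FALSE),
    r_out_inh = vapply(seq_along(r_E), run, numeric(1), inh = TRUE))
  structure(d, class = c("rate_curve", "data.frame"),
            params = params, seed = seed, duration = duration, r_I = r_I,
            inhib_mode = inhib_mode, model = model)
}

#' @export
print.rate_curve <- function(x, ...) {
  cat(sprintf("Rate curve (%s model, %s inhibition at %g events/s):\n",
              attr(x, "model"), attr(x, "inhib_mode"), attr(x, "r_I")))
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.rate_curve <- function(x, ...) {
  graphics::plot(x$r_E, x$r_out_noinh, pch = 1,
                 xlab = "excitatory input rate (events/s)",
                 ylab = "output rate (spikes/s)",
                 ylim = range(0, x$r_out_noinh), ...)
  graphics::points(x$r_E, x$r_out_inh, pch = 16)
  graphics::legend("topleft", c("no inhibition", "inhibition"),
                   pch = c(1, 16), bty = "n")
  invisible(x)
}

#' Threshold-linear fit of inhibited versus uninhibited output rates
#'
#' Fits `y = [m (x - x0)]+` by derivative-free simplex least squares
#' (Nelder-Mead) to the points whose inhibited rate `y` lies below
#' `cap` spikes/s.  `x` is the output rate without inhibition, `y` the
#' rate with inhibition; a divisive effect shows as `m < 1` with `x0`
#' near zero, a subtractive effect as a rightward shift `x0 > 0`.
#'
#' When every in-window `y` is zero, `x0` is unbounded above the data
#' range; the fit is flagged `degenerate` and `x0` is reported as the
#' largest in-window `x` (a lower bound).
#'
#' @param x,y paired output rates (spikes/s), or a `rate_curve` as `x`.
#' @param cap fit-window cap (spikes/s).
#' @return Object of class `"threshold_linear"` with elements `m`, `x0`,
#'   `residual` (sum of squares), `n_points`, `degenerate`, `cap`.
#' @examples
#' f <- fit_threshold_linear(10:18, 0.5 * (10:18 - 10))
#' coef(f)  # m = 0.5, x0 = 10
#' @export
fit_threshold_linear <- function(x, y = NULL, cap = 5) {
  if (inherits(x, "rate_curve")) {
    y <- x$r_out_inh; x <- x$r_out_noinh
  }
  stopifnot(length(x) == length(y))
  w <- y < cap
  if (sum(w) < 3)
    stop("insufficient data: fewer than 3 points with inhibited rate below ",
         cap, " spikes/s")
  xi <- x[w]; yi <- y[w]
  if (all(yi == 0)) {
    fit <- list(m = 0, x0 = max(xi), residual = 0, n_points = sum(w),
                degenerate = TRUE, cap = cap)
    class(fit) <- "threshold_linear"
    return(fit)
  }
  sse <- function(th) sum((yi - pmax(th[1] * (xi - th[2]), 0))^2)
  # simplex search from two starts: identity line and a crude secant
  i0 <- which.min(yi); i1 <- which.max(yi)
  m0 <- if (xi[i1] > xi[i0]) (yi[i1] - yi[i0]) / (xi[i1] - xi[i0]) else 1
  starts <- list(c(1, 0), c(max(m0, 1e-3), xi[i0] - yi[i0] / max(m0, 1e-3)))
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, sse, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  fit <- list(m = max(best$par[1], 0), x0 = best$par[2], residual = best$value,
              n_points = sum(w), degenerate = FALSE, cap = cap)
  class(fit) <- "threshold_linear"
  fit
}

#' @export
print.threshold_linear <- function(x, ...) {
  cat(sprintf(
    "Threshold-linear fit y = [m (x - x0)]+ : m = %.3f, x0 = %.2f spikes/s\n",
    x$m, x$x0))
  cat(sprintf("  %d points in window (y < %g), residual SS = %.3g%s\n",
              x$n_points, x$cap, x$residual,
              if (x$degenerate) "  [degenerate: no firing in window]" else ""))
  invisible(x)
}

#' @export
coef.threshold_linear <- function(object, ...) c(m = object$m, x0 = object$x0)

#' @export
predict.threshold_linear <- function(object, newdata, ...) {
  pmax(object$m * (newdata - object$x0), 0)
}

#' Classify the effect of inhibition as divisive or subtractive
#'
#' Subtractive inhibition right-shifts the threshold-linear relation
#' between inhibited and uninhibited output rates; the label is
#' `"subtractive"` when the x-intercept shift exceeds `threshold`
#' spikes/s (strictly), else `"divisive"`.  The reference intercept is 0
#' unless a no-inhibition reference fit is supplied.  Right-shifted
#' responses may also show slope reduction ("mixed" responses); both `m`
#' and the shift are retained so this remains visible.  A degenerate fit
#' (no firing anywhere in the window) is classified subtractive and
#' flagged.
#'
#' @param fit a [fit_threshold_linear()] result, or a `rate_curve` (fitted
#'   with defaults first).
#' @param reference optional `threshold_linear` fit of the no-inhibition
#'   relation; its `x0` is subtracted before thresholding.
#' @param threshold classification threshold (spikes/s).
#' @return Object of class `"inhibition_class"`: list with `label`,
#'   `x0_shift`, `m`, `degenerate`, `threshold`.
#' @export
classify_inhibition <- function(fit, reference = NULL, threshold = 2) {
  if (inherits(fit, "rate_curve")) fit <- fit_threshold_linear(fit)
  stopifnot(inherits(fit, "threshold_linear"))
  ref_x0 <- if (is.null(reference)) 0 else reference$x0
  shift <- fit$x0 - ref_x0
  label <- if (fit$degenerate || shift > threshold) "subtractive" else "divisive"
  structure(list(label = label, x0_shift = shift, m = fit$m,
                 degenerate = fit$degenerate, threshold = threshold),
            class = "inhibition_class")
}

#' @export
print.inhibition_class <- function(x, ...) {
  cat(sprintf("Inhibition is %s (x0 shift = %.2f spikes/s, slope m = %.3f)%s\n",
              x$label, x$x0_shift, x$m,
              if (x$degenerate) " [no firing under inhibition]" else ""))
  invisible(x)
}

#' Boundary between divisive and subtractive inhibition in (g_SynE, g_A)
#'
#' For each excitatory conductance in `g_SynE`, scans `g_A` in ascending
#' order, classifies each parameter set from a full rate-curve sweep, and
#' records the smallest `g_A` at which inhibition is subtractive.  Works
#' for the point neuron (optionally with a different A-current activation
#' time constant `tau_a`) and for the cable model (where the excitatory
#' input site `cpt_in` is the quantity of interest).
#'
#' @param g_SynE,g_A ascending grids of conductances (mS/cm^2).
#' @param params base [neuron_params()]; `g_SynE` and `g_A` are
#'   overridden pointwise.
#' @param r_E,r_I,duration,seed,inhib_mode,model passed to
#'   [compute_rate_curve()].
#' @param cap,threshold fit window and classification threshold.
#' @return Data frame with columns `g_SynE` and `g_A_boundary` (`NA` when
#'   no `g_A` in the grid is subtractive).
#' @export
map_boundary <- function(g_SynE, g_A, params = neuron_params(),
                         r_E = default_rate_grid(), r_I = 50,
                         duration = 10000, seed = 1,
                         inhib_mode = "periodic", model = "point",
                         cap = 5, threshold = 2) {
  stopifnot(!is.unsorted(g_SynE), !is.unsorted(g_A))
  bound <- vapply(g_SynE, function(ge) {
    for (ga in g_A) {
      p <- params; p$g_SynE <- ge; p$g_A <- ga
      cv <- compute_rate_curve(p, r_E, r_I, duration = duration, seed = seed,
                               inhib_mode = inhib_mode, model = model)
      cl <- tryCatch(classify_inhibition(fit_threshold_linear(cv, cap = cap),
                                         threshold = threshold),
                     error = function(e) NULL)
      if (!is.null(cl) && cl$label == "subtractive") return(ga)
    }
    NA_real_
  }, numeric(1))
  data.frame(g_SynE = g_SynE, g_A_boundary = bound)
}
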