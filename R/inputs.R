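#' Synaptic event trains
#'
#' Synaptic drive consists of point events: excitatory events at Poisson
#' times with rate `r_E`, and inhibitory events that are periodic with rate
#' `r_I` (Poisson-timed inhibition is available as a control).  Each event
#' resets its conductance gate to one, after which the gate decays
#' exponentially; the gates are evaluated in closed form between events.
#'
#' `poisson_train()` draws exponentially distributed inter-event intervals
#' with mean `1000 / rate` ms; `periodic_train()` places events at
#' `first_event + k * 1000 / rate` for `k = 0, 1, ...` within the duration.
#'
#' @param rate nominal event rate (events/s); `rate = 0` gives an empty
#'   Poisson train.
#' @param duration train length (ms).
#' @param seed optional integer seed; when given the draw is reproducible
#'   and the caller's RNG state is untouched.
#' @param kind `"excitatory"` or `"inhibitory"` (bookkeeping only).
#' @param first_event phase of the periodic train (ms).
#' @return An object of class `"event_train"`: a list with `times`
#'   (strictly increasing, ms), `kind`, `rate`, `mode`, `duration` and
#'   `seed`.
#' @examples
#' periodic_train(50, 100)$times  # 0, 20, 40, 60, 80, 100
#' @export
poisson_train <- function(rate, duration, seed = NULL, kind = "excitatory") {
  if (rate < 0) stop("rate must be non-negative")
  if (duration <= 0) stop("duration must be positive")
  times <- if (rate == 0) numeric(0) else {
    draw <- function() {
      # draw in blocks until past the duration
      out <- numeric(0); t <- 0
      repeat {
        k <- max(64L, ceiling(rate * duration / 1000 * 0.25))
        gaps <- stats::rexp(k, rate = rate / 1000)
        out <- c(out, t + cumsum(gaps))
        t <- out[length(out)]
        if (t > duration) break
      }
      out[out <= duration]
    }
    if (is.null(seed)) draw() else with_seed(seed, draw())
  }
  new_event_train(times, kind, rate, "poisson", duration, seed)
}

#' @rdname poisson_train
#' @export
periodic_train <- function(rate, duration, first_event = 0,
                           kind = "inhibitory") {
  if (rate <= 0) stop("rate must be positive")
  if (duration <= 0) stop("duration must be positive")
  times <- if (first_event > duration) numeric(0) else
    seq(first_event, duration, by = 1000 / rate)
  new_event_train(times, kind, rate, "periodic", duration, NULL)
}

new_event_train <- function(times, kind, rate, mode, duration, seed) {
  kind <- match.arg(kind, c("excitatory", "inhibitory"))
  structure(list(times = as.numeric(times), kind = kind, rate = rate,
                 mode = mode, duration = duration, seed = seed),
            class = "event_train")
}

#' @export
print.event_train <- function(x, ...) {
  cat(sprintf("%s event train: %d events in %g ms (%s, nominal %g events/s)\n",
              x$kind, length(x$times), x$duration, x$mode, x$rate))
  invisible(x)
}

# evaluate a function under a temporary seed, restoring the RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Reset-and-decay synaptic gate
#'
#' Evaluates the conductance gating variable of an event train at times
#' `t`: the gate is 1 at each event time and decays as
#' `exp(-beta * (t - t_last))` afterwards, where `t_last` is the most
#' recent event at or before `t`.  Before any event the gate is 0 (the
#' model starts from rest with no synaptic history).
#'
#' @param train an [event_train][poisson_train] object (or a numeric vector
#'   of event times).
#' @param beta decay constant (1/ms).
#' @param t query times (ms), vectorised.
#' @return Gate values in \[0, 1\].
#' @examples
#' tr <- periodic_train(50, 100)
#' gate_value(tr, 0.18, 20)  # reset to 1 at the event
#' @export
gate_value <- function(train, beta, t) {
  times <- if (inherits(train, "event_train")) train$times else as.numeric(train)
  if (any(t < 0)) stop("t must be non-negative")
  if (length(times) == 0) return(rep(0, length(t)))
  idx <- findInterval(t, times)
  out <- numeric(length(t))
  hit <- idx > 0
  out[hit] <- exp(-beta * (t[hit] - times[idx[hit]]))
  out
}

#' Read and write event trains as CSV
#'
#' Two-column plain-text interchange format: `time_ms`, `kind`.
#'
#' @param train an event train, or for reading, a file path.
#' @param path file path.
#' @return `read_event_train()` returns an `event_train`; metadata not
#'   stored in the CSV (rate, mode) is reconstructed approximately.
#' @export
write_event_train <- function(train, path) {
  stopifnot(inherits(train, "event_train"))
  utils::write.csv(data.frame(time_ms = train$times, kind = train$kind),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_event_train
#' @export
read_event_train <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time_ms", "kind") %in% names(d)))
  times <- sort(d$time_ms)
  dur <- if (length(times)) max(times) else 0
  rate <- if (dur > 0) length(times) / dur * 1000 else 0
  new_event_train(times, d$kind[1], rate, "poisson", dur, NULL)
}
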