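#' @include AllClasses.R
NULL

## segment slopes (state units per microsecond) implied by a schedule:
## initialDecrement per tick on segment 1, halved after each halving point
.leakSlopes <- function(schedule) {
  k <- length(schedule@halvingPoints)
  (schedule@initialDecrement / schedule@tickUs) / 2^(0:k)
}

#' Piece-wise linear leak amount for an elapsed interval
#'
#' Total state decrement accumulated over \code{elapsedUs} microseconds
#' under the bit-shift leak schedule: the initial decrement-per-tick rate
#' applies up to the first halving point, half of it up to the second, and
#' so on. The value is unclamped; callers clamp the resulting state at zero.
#'
#' @param schedule a [LeakSchedule-class].
#' @param elapsedUs elapsed time(s) in microseconds (vectorized).
#' @return numeric leak amount(s) in state units.
#' @export
leakAmount <- function(schedule, elapsedUs) {
  slopes <- .leakSlopes(schedule)
  brk <- schedule@halvingPoints
  edges <- c(0, brk, Inf)
  amt <- numeric(length(elapsedUs))
  for (k in seq_along(slopes)) {
    lo <- edges[k]; hi <- edges[k + 1]
    amt <- amt + slopes[k] * pmax(0, pmin(elapsedUs, hi) - lo)
  }
  amt
}

#' Fit a bit-shift leak schedule to an exponential decay
#'
#' Chooses the initial decrement of a piece-wise linear leak whose slope
#' halves at breakpoints spaced one half-life (\eqn{\tau \ln 2}) apart, so
#' that the clamped linear decay of a state of size \code{x0} tracks
#' \eqn{x_0 e^{-t/\tau}} with minimal worst-case error. The achieved maximum
#' absolute deviation over \code{[0, horizon]} is recorded in the schedule's
#' \code{fitError} slot.
#'
#' @param tauUs exponential time constant in microseconds.
#' @param x0 reference initial state the fit targets (default 100 units).
#' @param nSegments number of linear segments (default 3, i.e. 2 halvings).
#' @param tickUs tick length (default 500 us).
#' @param horizonUs fit/evaluation horizon (default \code{5 * tauUs}).
#' @return a [LeakSchedule-class] with \code{fitError} filled in.
#' @examples
#' sch <- fitLeakSchedule(12000)   # tau = 12 ms
#' sch@fitError                     # worst-case deviation for x0 = 100
#' @export
fitLeakSchedule <- function(tauUs, x0 = 100, nSegments = 3, tickUs = 500,
                            horizonUs = 5 * tauUs) {
  halfLife <- tauUs * log(2)
  brk <- halfLife * seq_len(nSegments - 1)
  tt <- seq(0, horizonUs, by = tickUs)
  target <- x0 * exp(-tt / tauUs)
  maxdev <- function(d0) {
    sch <- new("LeakSchedule", tickUs = tickUs, initialDecrement = d0,
               halvingPoints = brk, targetTau = tauUs,
               fitError = NA_real_)
    approxed <- pmax(0, x0 - leakAmount(sch, tt))
    max(abs(approxed - target))
  }
  ## slope of the exponential at 0 is x0/tau per us -> d0 near x0*tick/tau
  opt <- stats::optimize(maxdev, interval = c(0.2, 2) * x0 * tickUs / tauUs)
  new("LeakSchedule", tickUs = tickUs, initialDecrement = opt$minimum,
      halvingPoints = brk, targetTau = tauUs, fitError = opt$objective)
}

#' Time after which a full-scale state has leaked to rest
#'
#' Smallest elapsed time at which the schedule has drained a state of size
#' \code{x0}; used as the natural inter-symbol time ("leak to rest").
#'
#' @param schedule a [LeakSchedule-class].
#' @param x0 state size to drain (default 100).
#' @return elapsed microseconds.
#' @export
leakRestTime <- function(schedule, x0 = 100) {
  slopes <- .leakSlopes(schedule)
  brk <- c(schedule@halvingPoints, Inf)
  drained <- 0; t0 <- 0
  for (k in seq_along(slopes)) {
    seg <- (x0 - drained) / slopes[k]               # time left at this slope
    if (t0 + seg <= brk[k]) return(t0 + seg)
    drained <- drained + slopes[k] * (brk[k] - t0)
    t0 <- brk[k]
  }
  t0
}

#' Apply lazy leak to a neuron state
#'
#' Reduces both counters by the piece-wise linear leak for the elapsed time
#' since \code{lastUpdate}, clamps them at zero, and stamps \code{now}.
#' Leak is evaluated lazily, only when an event touches the neuron.
#'
#' @param state a [NeuronState-class].
#' @param now current time in microseconds; must be \code{>= lastUpdate}.
#' @param schedule a [LeakSchedule-class].
#' @return the updated [NeuronState-class].
#' @export
applyLeak <- function(state, now, schedule) {
  if (now < state@lastUpdate)
    stop("temporal ordering violated: now (", now,
         ") < lastUpdate (", state@lastUpdate, ")")
  amt <- leakAmount(schedule, now - state@lastUpdate)
  state@firingCounter <- max(0, state@firingCounter - amt)
  state@learningCounter <- max(0, state@learningCounter - amt)
  state@lastUpdate <- now
  state
}

#' Process one input event through a neuron
#'
#' Leak is applied first; a weight-1 event then increments both counters by
#' one. The neuron fires when the firing counter reaches its threshold and
#' triggers STDP when the learning counter reaches the STDP threshold (with
#' \code{dualThreshold} off, the STDP trigger simply mirrors firing). A
#' counter that crossed its threshold resets to zero; on firing the firing
#' threshold grows by \code{thIncrement} up to the ceiling \code{xThMax},
#' and on an STDP trigger the STDP threshold grows by
#' \code{stdpThIncrement}.
#'
#' @param state a [NeuronState-class].
#' @param weight the 1-bit synaptic weight of the event's source (0 or 1).
#' @param now event time in microseconds.
#' @param config a [NeuronConfig-class].
#' @param schedule a [LeakSchedule-class]; NULL disables leak.
#' @return list with elements \code{state} (updated [NeuronState-class]),
#'   \code{fired} and \code{stdpTriggered} (logicals).
#' @export
processInputEvent <- function(state, weight, now, config,
                              schedule = NULL) {
  stopifnot(weight %in% c(0, 1))
  if (!is.null(schedule)) state <- applyLeak(state, now, schedule)
  else state@lastUpdate <- now
  if (weight == 1) {
    state@firingCounter <- state@firingCounter + 1
    state@learningCounter <- state@learningCounter + 1
  }
  fired <- state@firingCounter >= state@firingThreshold
  if (fired) {
    state@firingCounter <- 0
    state@firingThreshold <- min(state@firingThreshold + config@thIncrement,
                                 config@xThMax)
  }
  if (config@dualThreshold) {
    stdpTriggered <- state@learningCounter >= state@stdpThreshold
    if (stdpTriggered) {
      state@learningCounter <- 0
      state@stdpThreshold <- state@stdpThreshold + config@stdpThIncrement
    }
  } else {
    stdpTriggered <- fired
    if (fired) state@learningCounter <- 0
  }
  list(state = state, fired = fired, stdpTriggered = stdpTriggered)
}

#' Lateral-inhibition reset
#'
#' Winner-take-all losers are reset: both counters go to zero; thresholds
#' and the leak timestamp are untouched. Idempotent.
#'
#' @param state a [NeuronState-class].
#' @return the reset [NeuronState-class].
#' @export
inhibit <- function(state) {
  state@firingCounter <- 0
  state@learningCounter <- 0
  state
}
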