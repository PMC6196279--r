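#' @import methods
NULL

## ---------------------------------------------------------------------------
## AER event streams
## ---------------------------------------------------------------------------

#' EventStream: an address-event representation (AER) spike stream
#'
#' The universal currency of the simulator: a sequence of timestamped address
#' events. Timestamps are integer microseconds (stored as numeric to allow
#' long recordings), addresses are 0-based source indices into an address
#' space of declared size. Pixel sources carry an optional \code{geometry}
#' (rows, cols); flattening is row-major, 0-based:
#' \code{address = r * cols + c}.
#'
#' @slot timestamps numeric, non-negative, non-decreasing (microseconds).
#' @slot addresses integer, 0-based, all \code{< addressSpace}.
#' @slot polarity integer, length 0 or same length as \code{addresses}.
#' @slot addressSpace integer(1), size of the address space.
#' @slot geometry integer of length 0 or 2: \code{c(rows, cols)}.
#'
#' @examples
#' s <- EventStream(timestamps = c(0, 10, 20), addresses = c(5L, 7L, 5L),
#'                  addressSpace = 16L)
#' nEvents(s)
#' @export
setClass("EventStream",
  representation(timestamps = "numeric", addresses = "integer",
                 polarity = "integer", addressSpace = "integer",
                 geometry = "integer"),
  prototype(timestamps = numeric(0), addresses = integer(0),
            polarity = integer(0), addressSpace = 1L, geometry = integer(0)))

setValidity("EventStream", function(object) {
  msg <- character(0)
  n <- length(object@timestamps)
  if (length(object@addresses) != n)
    msg <- c(msg, "timestamps and addresses must have equal length")
  if (length(object@polarity) != 0L && length(object@polarity) != n)
    msg <- c(msg, "polarity must be empty or match the number of events")
  if (n > 0 && any(object@timestamps < 0))
    msg <- c(msg, "timestamps must be non-negative")
  if (n > 1 && any(diff(object@timestamps) < 0))
    msg <- c(msg, "timestamps must be non-decreasing")
  if (length(object@addressSpace) != 1L || object@addressSpace < 1L)
    msg <- c(msg, "addressSpace must be a positive scalar")
  if (n > 0 && (any(object@addresses < 0L) ||
                any(object@addresses >= object@addressSpace)))
    msg <- c(msg, "addresses must lie in [0, addressSpace)")
  if (length(object@geometry) == 2L &&
      prod(object@geometry) != object@addressSpace)
    msg <- c(msg, "geometry rows*cols must equal addressSpace")
  if (length(object@geometry) %in% c(0L, 2L) == FALSE)
    msg <- c(msg, "geometry must have length 0 or 2")
  if (length(msg)) msg else TRUE
})

#' @rdname EventStream-class
#' @param timestamps,addresses,polarity,addressSpace,geometry see slots.
#' @export
EventStream <- function(timestamps = numeric(0), addresses = integer(0),
                        addressSpace, polarity = integer(0),
                        geometry = integer(0)) {
  new("EventStream", timestamps = as.numeric(timestamps),
      addresses = as.integer(addresses), polarity = as.integer(polarity),
      addressSpace = as.integer(addressSpace),
      geometry = as.integer(geometry))
}

## ---------------------------------------------------------------------------
## Neuron model
## ---------------------------------------------------------------------------

#' LeakSchedule: piece-wise linear (bit-shift) leak approximation
#'
#' Hardware neurons approximate the exponential leak of a LIF neuron by
#' subtracting a fixed decrement per tick and halving that decrement (a bit
#' shift) at fixed elapsed-time breakpoints. The schedule is data: a starting
#' decrement, a tick, and the halving points.
#'
#' @slot tickUs numeric(1), tick length in microseconds.
#' @slot initialDecrement numeric(1), state units subtracted per tick on the
#'   first segment; strictly positive.
#' @slot halvingPoints numeric, strictly increasing elapsed-time breakpoints
#'   (microseconds) at which the decrement is divided by 2.
#' @slot targetTau numeric(1), the exponential time constant (us) the
#'   schedule approximates (documentation only).
#' @slot fitError numeric(1), maximum absolute deviation from the target
#'   exponential recorded by [fitLeakSchedule()] (NA when hand-built).
#' @export
setClass("LeakSchedule",
  representation(tickUs = "numeric", initialDecrement = "numeric",
                 halvingPoints = "numeric", targetTau = "numeric",
                 fitError = "numeric"),
  prototype(tickUs = 500, initialDecrement = 1, halvingPoints = numeric(0),
            targetTau = NA_real_, fitError = NA_real_))

setValidity("LeakSchedule", function(object) {
  msg <- character(0)
  if (object@tickUs <= 0) msg <- c(msg, "tickUs must be positive")
  if (object@initialDecrement <= 0)
    msg <- c(msg, "initialDecrement must be strictly positive")
  hp <- object@halvingPoints
  if (length(hp) && (any(hp <= 0) || any(diff(hp) <= 0)))
    msg <- c(msg, "halvingPoints must be strictly increasing and positive")
  if (length(msg)) msg else TRUE
})

#' NeuronConfig: thresholds and homeostasis parameters
#'
#' @slot xThInit numeric(1), initial firing threshold (> 0).
#' @slot xThMax numeric(1), threshold ceiling (>= xThInit).
#' @slot thIncrement numeric(1), per-spike threshold increment (>= 0).
#' @slot dualThreshold logical(1), keep separate learning and inference
#'   states/thresholds (hardware-emulation mode).
#' @slot stdpThInit numeric(1), initial STDP threshold (dual mode).
#' @slot stdpThIncrement numeric(1), STDP-threshold growth per update
#'   (the hardware increments by exactly 1).
#' @export
setClass("NeuronConfig",
  representation(xThInit = "numeric", xThMax = "numeric",
                 thIncrement = "numeric", dualThreshold = "logical",
                 stdpThInit = "numeric", stdpThIncrement = "numeric"),
  prototype(xThInit = 10, xThMax = 100, thIncrement = 1,
            dualThreshold = FALSE, stdpThInit = 10, stdpThIncrement = 1))

setValidity("NeuronConfig", function(object) {
  msg <- character(0)
  if (object@xThInit <= 0) msg <- c(msg, "xThInit must be > 0")
  if (object@xThMax < object@xThInit)
    msg <- c(msg, "xThMax must be >= xThInit")
  if (object@thIncrement < 0) msg <- c(msg, "thIncrement must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname NeuronConfig-class
#' @param xThInit,xThMax,thIncrement,dualThreshold,stdpThInit,stdpThIncrement
#'   see slots.
#' @export
NeuronConfig <- function(xThInit = 10, xThMax = 100, thIncrement = 1,
                         dualThreshold = FALSE, stdpThInit = xThInit,
                         stdpThIncrement = 1) {
  new("NeuronConfig", xThInit = xThInit, xThMax = xThMax,
      thIncrement = thIncrement, dualThreshold = dualThreshold,
      stdpThInit = stdpThInit, stdpThIncrement = stdpThIncrement)
}

#' NeuronState: counters, thresholds and the last-leak time of one neuron
#'
#' States are restricted to non-negative values and clamped at zero; the
#' firing threshold is bounded by the configured ceiling.
#'
#' @slot firingCounter numeric(1), inference state (>= 0).
#' @slot learningCounter numeric(1), learning state (>= 0).
#' @slot firingThreshold numeric(1).
#' @slot stdpThreshold numeric(1).
#' @slot lastUpdate numeric(1), microseconds of the last leak evaluation.
#' @export
setClass("NeuronState",
  representation(firingCounter = "numeric", learningCounter = "numeric",
                 firingThreshold = "numeric", stdpThreshold = "numeric",
                 lastUpdate = "numeric"),
  prototype(firingCounter = 0, learningCounter = 0, firingThreshold = 10,
            stdpThreshold = 10, lastUpdate = 0))

setValidity("NeuronState", function(object) {
  msg <- character(0)
  if (object@firingCounter < 0 || object@learningCounter < 0)
    msg <- c(msg, "counters must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @rdname NeuronState-class
#' @param config a [NeuronConfig-class] providing the initial thresholds.
#' @export
NeuronState <- function(config = NeuronConfig()) {
  new("NeuronState", firingCounter = 0, learningCounter = 0,
      firingThreshold = config@xThInit, stdpThreshold = config@stdpThInit,
      lastUpdate = 0)
}

## ---------------------------------------------------------------------------
## STDP
## ---------------------------------------------------------------------------

#' StdpKernel: the STDP learning-function zoo
#'
#' Time-based kernels are functions of the spike-time difference
#' \eqn{\Delta t = t_{post} - t_{pre}} (microseconds); order-based kernels of
#' the rank difference \eqn{\Delta n}. In stochastic (1-bit) mode the
#' magnitudes \code{aPlus}/\code{aMinus} are probabilities in [0, 1].
#'
#' Shapes: \code{"classic"} (exponential decay on both branches),
#' \code{"rectangular"}, \code{"narrow-potentiation"} (potentiate only within
#' \code{0 < delta <= tP}, depress elsewhere in the window),
#' \code{"symmetric-hebbian"} (potentiate near coincidence, no depression),
#' \code{"symmetric-narrow"} (potentiate within \code{|delta| <= tP}, depress
#' in the rest of the window). The window bounds \code{tMax}/\code{tMin} may
#' be \code{Inf} (the undiscriminating-depressing limit).
#'
#' @slot mode character(1), "time" or "order".
#' @slot shape character(1), one of the shapes above.
#' @slot aPlus,aMinus numeric(1), branch magnitudes (probabilities when used
#'   with 1-bit weights; both in [0, 1]).
#' @slot tP numeric(1), narrow potentiation window (us or events).
#' @slot tMax,tMin numeric(1), list/window bounds (post-after-pre and
#'   pre-after-post side, both >= 0, possibly Inf).
#' @slot tauPlus,tauMinus numeric(1), decay constants of the classic shape.
#' @export
setClass("StdpKernel",
  representation(mode = "character", shape = "character",
                 aPlus = "numeric", aMinus = "numeric", tP = "numeric",
                 tMax = "numeric", tMin = "numeric",
                 tauPlus = "numeric", tauMinus = "numeric"),
  prototype(mode = "order", shape = "narrow-potentiation", aPlus = 1,
            aMinus = 1, tP = 10, tMax = Inf, tMin = 0,
            tauPlus = NA_real_, tauMinus = NA_real_))

setValidity("StdpKernel", function(object) {
  msg <- character(0)
  if (!object@mode %in% c("time", "order"))
    msg <- c(msg, "mode must be 'time' or 'order'")
  shapes <- c("classic", "rectangular", "narrow-potentiation",
              "symmetric-hebbian", "symmetric-narrow")
  if (!object@shape %in% shapes)
    msg <- c(msg, paste("shape must be one of:", paste(shapes, collapse = ", ")))
  if (abs(object@aPlus) > 1 || abs(object@aMinus) > 1)
    msg <- c(msg, "|aPlus| and |aMinus| must be <= 1")
  if (object@tMax < 0 || object@tMin < 0 || object@tP < 0)
    msg <- c(msg, "windows must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @rdname StdpKernel-class
#' @param mode,shape,aPlus,aMinus,tP,tMax,tMin,tauPlus,tauMinus see slots.
#' @export
StdpKernel <- function(mode = c("order", "time"),
                       shape = c("narrow-potentiation", "classic",
                                 "rectangular", "symmetric-hebbian",
                                 "symmetric-narrow"),
                       aPlus = 1, aMinus = 1, tP = 10, tMax = Inf, tMin = 0,
                       tauPlus = NA_real_, tauMinus = NA_real_) {
  mode <- match.arg(mode)
  shape <- match.arg(shape)
  if (shape == "classic") {
    if (is.na(tauPlus)) tauPlus <- if (is.finite(tMax)) tMax / 3 else tP
    if (is.na(tauMinus)) tauMinus <- if (is.finite(tMin)) tMin / 3 else tP
  }
  new("StdpKernel", mode = mode, shape = shape, aPlus = aPlus,
      aMinus = aMinus, tP = tP, tMax = tMax, tMin = tMin,
      tauPlus = tauPlus, tauMinus = tauMinus)
}

#' PreBuffer: bounded circular list of recent pre-synaptic addresses
#'
#' Order-based mode keeps no timestamps: just the addresses in order of
#' arrival (oldest first). The oldest entry is evicted on overflow.
#'
#' @slot capacity integer(1), the "buffer size".
#' @slot entries integer, 0-based addresses, oldest first,
#'   \code{length <= capacity}.
#' @export
setClass("PreBuffer",
  representation(capacity = "integer", entries = "integer"),
  prototype(capacity = 250L, entries = integer(0)))

setValidity("PreBuffer", function(object) {
  msg <- character(0)
  if (object@capacity < 1L) msg <- c(msg, "capacity must be >= 1")
  if (length(object@entries) > object@capacity)
    msg <- c(msg, "entries exceed capacity")
  if (length(msg)) msg else TRUE
})

#' @rdname PreBuffer-class
#' @param capacity buffer size; \code{entries} initial content.
#' @param entries integer vector of 0-based addresses, oldest first.
#' @export
PreBuffer <- function(capacity, entries = integer(0)) {
  new("PreBuffer", capacity = as.integer(capacity),
      entries = as.integer(entries))
}

#' BinaryWeights: a pre x post bit matrix with a per-neuron popcount budget
#'
#' Every synapse is a single bit. Under deterministic normalization the
#' number of active (value-1) synapses per post-synaptic neuron (the column
#' popcount, \eqn{W_{sum}}) is held exactly at \code{wSumTarget} after each
#' STDP update.
#'
#' @slot bits integer matrix (nPre x nPost) with entries in {0, 1}.
#' @slot wSumTarget integer(1), the popcount budget per neuron.
#' @export
setClass("BinaryWeights",
  representation(bits = "matrix", wSumTarget = "integer"),
  prototype(bits = matrix(0L, 1, 1), wSumTarget = 1L))

setValidity("BinaryWeights", function(object) {
  msg <- character(0)
  b <- object@bits
  if (!is.integer(b)) msg <- c(msg, "bits must be an integer matrix")
  else if (length(b) && !all(b %in% c(0L, 1L)))
    msg <- c(msg, "bits must be 0 or 1")
  if (object@wSumTarget < 0L || object@wSumTarget > nrow(b))
    msg <- c(msg, "wSumTarget must lie in [0, nPre]")
  if (length(msg)) msg else TRUE
})

#' @rdname BinaryWeights-class
#' @param bits,wSumTarget see slots.
#' @export
BinaryWeights <- function(bits, wSumTarget) {
  storage.mode(bits) <- "integer"
  new("BinaryWeights", bits = bits, wSumTarget = as.integer(wSumTarget))
}

#' StdpConfig: parameters of the stochastic 1-bit STDP rule
#'
#' @slot pLtp numeric(1), potentiation probability in [0, 1].
#' @slot bufferSize integer(1), capacity of the population pre-buffer.
#' @slot numberOfPotentiation integer(1), how many of the most recent
#'   buffered events are used for LTP; must be <= bufferSize.
#' @slot normalization character(1), "deterministic" (popcount restored to
#'   the budget after every update) or "stochastic" (each active weight
#'   depressed with the normalized probability, popcount wanders around the
#'   budget).
#' @slot flush logical(1), empty the pre-buffer after each update.
#' @slot protectBuffered logical(1), exclude synapses named in the buffer
#'   from depression within the same update (the hardware rescans all
#'   weights, i.e. FALSE).
#' @slot probabilityScale character(1), "float" (R RNG, probabilities as
#'   reals) or "int1024" (10-bit integer probabilities compared against an
#'   LFSR sample, as in the hardware).
#' @export
setClass("StdpConfig",
  representation(pLtp = "numeric", bufferSize = "integer",
                 numberOfPotentiation = "integer", normalization = "character",
                 flush = "logical", protectBuffered = "logical",
                 probabilityScale = "character"),
  prototype(pLtp = 0.8, bufferSize = 250L, numberOfPotentiation = 250L,
            normalization = "deterministic", flush = TRUE,
            protectBuffered = TRUE, probabilityScale = "float"))

setValidity("StdpConfig", function(object) {
  msg <- character(0)
  if (object@pLtp < 0 || object@pLtp > 1)
    msg <- c(msg, "pLtp must lie in [0, 1]")
  if (object@bufferSize < 1L) msg <- c(msg, "bufferSize must be >= 1")
  if (object@numberOfPotentiation > object@bufferSize)
    msg <- c(msg, "numberOfPotentiation must be <= bufferSize")
  if (!object@normalization %in% c("deterministic", "stochastic"))
    msg <- c(msg, "normalization must be 'deterministic' or 'stochastic'")
  if (!object@probabilityScale %in% c("float", "int1024"))
    msg <- c(msg, "probabilityScale must be 'float' or 'int1024'")
  if (length(msg)) msg else TRUE
})

#' @rdname StdpConfig-class
#' @param pLtp,bufferSize,numberOfPotentiation,normalization,flush,protectBuffered,probabilityScale
#'   see slots.
#' @export
StdpConfig <- function(pLtp = 0.8, bufferSize = 250,
                       numberOfPotentiation = bufferSize,
                       normalization = c("deterministic", "stochastic"),
                       flush = TRUE, protectBuffered = TRUE,
                       probabilityScale = c("float", "int1024")) {
  new("StdpConfig", pLtp = pLtp, bufferSize = as.integer(bufferSize),
      numberOfPotentiation = as.integer(numberOfPotentiation),
      normalization = match.arg(normalization), flush = flush,
      protectBuffered = protectBuffered,
      probabilityScale = match.arg(probabilityScale))
}

## ---------------------------------------------------------------------------
## Networks and experiments
## ---------------------------------------------------------------------------

#' FeNetwork: a trained feature-extraction population
#'
#' Bundles the 1-bit weight matrix with the per-neuron thresholds and the
#' configuration the population was trained under.
#'
#' @slot weights a [BinaryWeights-class].
#' @slot firingThresholds numeric, per-neuron firing thresholds.
#' @slot stdpThresholds numeric, per-neuron STDP thresholds (dual mode).
#' @slot neuronConfig a [NeuronConfig-class].
#' @slot stdpConfig a [StdpConfig-class].
#' @slot leak a [LeakSchedule-class].
#' @export
setClass("FeNetwork",
  representation(weights = "BinaryWeights", firingThresholds = "numeric",
                 stdpThresholds = "numeric", neuronConfig = "NeuronConfig",
                 stdpConfig = "StdpConfig", leak = "LeakSchedule"))

setValidity("FeNetwork", function(object) {
  n <- ncol(object@weights@bits)
  if (length(object@firingThresholds) != n ||
      length(object@stdpThresholds) != n)
    "threshold vectors must have one entry per neuron" else TRUE
})

#' TuningCurve: per-neuron firing rate against stimulus angle
#'
#' @slot angles numeric, stimulus orientations in degrees.
#' @slot rates matrix (neurons x angles), firing rates in events/second,
#'   all non-negative.
#' @export
setClass("TuningCurve",
  representation(angles = "numeric", rates = "matrix"))

setValidity("TuningCurve", function(object) {
  msg <- character(0)
  if (ncol(object@rates) != length(object@angles))
    msg <- c(msg, "rates must have one column per angle")
  if (any(object@rates < 0)) msg <- c(msg, "rates must be non-negative")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Classifiers
## ---------------------------------------------------------------------------

#' SimpleClassifier: teacher-driven STDP output layer
#'
#' A conventional (non-binary, non-stochastic) STDP classifier in which the
#' post-synaptic spike is replaced by a teacher signal naming the correct
#' class. The weight sum of each class column is renormalized to a fixed
#' budget after every update.
#'
#' @slot weights integer matrix (features x classes), non-negative.
#' @slot wSumTarget numeric(1), per-class column-sum budget.
#' @slot learnRate numeric(1), integer potentiation amount per update.
#' @slot bufferSize integer(1), capacity of the FE-spike pre-buffer.
#' @slot buffer integer, buffered FE neuron indices (0-based, oldest first).
#' @export
setClass("SimpleClassifier",
  representation(weights = "matrix", wSumTarget = "numeric",
                 learnRate = "numeric", bufferSize = "integer",
                 buffer = "integer"))

setValidity("SimpleClassifier", function(object) {
  msg <- character(0)
  if (any(object@weights < 0)) msg <- c(msg, "weights must be non-negative")
  if (length(object@buffer) > object@bufferSize)
    msg <- c(msg, "buffer exceeds capacity")
  if (length(msg)) msg else TRUE
})

#' SnnClassifier: a frame-trained softmax classifier converted to LIF neurons
#'
#' Conversion scales the (non-negative) weight matrix by a constant k and
#' sets every output neuron's threshold to k.
#'
#' @slot weights integer matrix (features x classes), scaled by k.
#' @slot threshold numeric(1), equal to the scaling constant k.
#' @slot resetMode character(1), "subtract" (reset by threshold
#'   subtraction, the rate-preserving conversion) or "zero".
#' @export
setClass("SnnClassifier",
  representation(weights = "matrix", threshold = "numeric",
                 resetMode = "character"),
  prototype(resetMode = "subtract"))

setValidity("SnnClassifier", function(object) {
  msg <- character(0)
  if (object@threshold <= 0) msg <- c(msg, "threshold must be positive")
  if (!object@resetMode %in% c("subtract", "zero"))
    msg <- c(msg, "resetMode must be 'subtract' or 'zero'")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Encoding
## ---------------------------------------------------------------------------

#' EncodingConfig: Poisson rate-coding parameters
#'
#' The whole population fires at a constant total rate; per-pixel rates are
#' proportional to intensity. Exactly one of \code{totalSpikes} (events per
#' sample) or \code{durationUs} must be set.
#'
#' @slot totalRate numeric(1), events/second for the whole population (> 0).
#' @slot totalSpikes integer(1), events per sample, or NA.
#' @slot durationUs numeric(1), sample duration in microseconds, or NA.
#' @slot istUs numeric(1), inter-symbol time in microseconds.
#' @export
setClass("EncodingConfig",
  representation(totalRate = "numeric", totalSpikes = "integer",
                 durationUs = "numeric", istUs = "numeric"),
  prototype(totalRate = 20000, totalSpikes = 1000L, durationUs = NA_real_,
            istUs = 60000))

setValidity("EncodingConfig", function(object) {
  msg <- character(0)
  if (object@totalRate <= 0) msg <- c(msg, "totalRate must be > 0")
  if (is.na(object@totalSpikes) == is.na(object@durationUs))
    msg <- c(msg, "exactly one of totalSpikes and durationUs must be set")
  if (object@istUs < 0) msg <- c(msg, "istUs must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @rdname EncodingConfig-class
#' @param totalRate,totalSpikes,durationUs,istUs see slots.
#' @export
EncodingConfig <- function(totalRate = 20000, totalSpikes = 1000L,
                           durationUs = NA_real_, istUs = 60000) {
  new("EncodingConfig", totalRate = totalRate,
      totalSpikes = as.integer(totalSpikes),
      durationUs = as.numeric(durationUs), istUs = istUs)
}

## ---------------------------------------------------------------------------
## Hardware model
## ---------------------------------------------------------------------------

#' CycleCostModel: clock-cycle accounting of the hardware STDP unit
#'
#' Closed-form model of the steady-state cycle counts of the STDP unit: a
#' circular pre-buffer with a 3-cycle read latency, synaptic memory with a
#' 3-cycle read latency, a 1-cycle pipeline pad and a 25-cycle serial
#' divider.
#'
#' @slot synapseCount integer(1), synapses per neuron (default 1024).
#' @slot bufferReadLatency,weightReadLatency,pipelinePad,dividerLatency
#'   integer(1) cycle latencies.
#' @slot clockHz numeric(1), clock frequency in Hz.
#' @export
setClass("CycleCostModel",
  representation(synapseCount = "integer", bufferReadLatency = "integer",
                 weightReadLatency = "integer", pipelinePad = "integer",
                 dividerLatency = "integer", clockHz = "numeric"),
  prototype(synapseCount = 1024L, bufferReadLatency = 3L,
            weightReadLatency = 3L, pipelinePad = 1L, dividerLatency = 25L,
            clockHz = 1e8))

setValidity("CycleCostModel", function(object) {
  lat <- c(object@synapseCount, object@bufferReadLatency,
           object@weightReadLatency, object@pipelinePad,
           object@dividerLatency)
  if (any(lat < 1L)) "all latencies must be positive integers" else TRUE
})

#' @rdname CycleCostModel-class
#' @param synapseCount,bufferReadLatency,weightReadLatency,pipelinePad,dividerLatency,clockHz
#'   see slots.
#' @export
CycleCostModel <- function(synapseCount = 1024, bufferReadLatency = 3,
                           weightReadLatency = 3, pipelinePad = 1,
                           dividerLatency = 25, clockHz = 1e8) {
  new("CycleCostModel", synapseCount = as.integer(synapseCount),
      bufferReadLatency = as.integer(bufferReadLatency),
      weightReadLatency = as.integer(weightReadLatency),
      pipelinePad = as.integer(pipelinePad),
      dividerLatency = as.integer(dividerLatency), clockHz = clockHz)
}

#' Lfsr16: a 16-bit linear-feedback shift register
#'
#' Fibonacci LFSR with XOR feedback; with maximal taps the state orbit
#' visits every nonzero 16-bit value (period 2^16 - 1). Draws are the low
#' 10 bits of the state, compared against 10-bit integer probabilities.
#'
#' @slot state integer(1), nonzero 16-bit register value.
#' @slot taps integer, 1-based feedback bit positions (bit 16 = MSB);
#'   default \code{c(16, 15, 13, 4)}, a maximal-length polynomial.
#' @export
setClass("Lfsr16",
  representation(state = "integer", taps = "integer"),
  prototype(state = 1L, taps = c(16L, 15L, 13L, 4L)))

setValidity("Lfsr16", function(object) {
  msg <- character(0)
  if (object@state == 0L || object@state < 0L || object@state > 65535L)
    msg <- c(msg, "state must be a nonzero 16-bit value")
  if (any(object@taps < 1L) || any(object@taps > 16L))
    msg <- c(msg, "taps must lie in 1..16")
  if (length(msg)) msg else TRUE
})

#' @rdname Lfsr16-class
#' @param state,taps see slots.
#' @export
Lfsr16 <- function(state = 1L, taps = c(16L, 15L, 13L, 4L)) {
  new("Lfsr16", state = as.integer(state), taps = as.integer(taps))
}
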