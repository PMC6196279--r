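#' @include AllClasses.R AllGenerics.R stdp-binary.R neuron.R
NULL

#' Construct a feature-extraction network
#'
#' @param weights a [BinaryWeights-class] (nPre x nPost).
#' @param neuronConfig a [NeuronConfig-class]; initial thresholds are taken
#'   from it unless given explicitly.
#' @param stdpConfig a [StdpConfig-class].
#' @param leak a [LeakSchedule-class].
#' @param firingThresholds,stdpThresholds optional per-neuron initial
#'   thresholds.
#' @return a [FeNetwork-class].
#' @export
FeNetwork <- function(weights, neuronConfig = NeuronConfig(),
                      stdpConfig = StdpConfig(),
                      leak = fitLeakSchedule(12000),
                      firingThresholds = NULL, stdpThresholds = NULL) {
  n <- ncol(weights@bits)
  if (is.null(firingThresholds))
    firingThresholds <- rep(neuronConfig@xThInit, n)
  if (is.null(stdpThresholds))
    stdpThresholds <- rep(neuronConfig@stdpThInit, n)
  new("FeNetwork", weights = weights, firingThresholds = firingThresholds,
      stdpThresholds = stdpThresholds, neuronConfig = neuronConfig,
      stdpConfig = stdpConfig, leak = leak)
}

#' Run an event stream through a population
#'
#' The event-driven workhorse: integrates every input event through the
#' fully connected population with lazy piece-wise linear leak, optional
#' winner-take-all lateral inhibition, homeostatic threshold adaptation and
#' (during learning) the stochastic 1-bit STDP rule with the population
#' pre-buffer. Weight updates are delegated to [applyBinaryStdp()]'s single
#' implementation.
#'
#' @param network a [FeNetwork-class].
#' @param stream an [EventStream-class] whose address space matches the
#'   network input size.
#' @param learn enable plasticity (STDP updates and, in dual-threshold
#'   mode, STDP-threshold growth).
#' @param wta enable winner-take-all lateral inhibition.
#' @param adaptThresholds enable homeostatic firing-threshold growth.
#' @param leakOn enable the leak (disable for purely order-driven tests).
#' @param wtaPolicy tie-break: "lowest" (deterministic) or "random".
#' @param recordSpikes also return the individual output spikes.
#' @param verbose show per-update STDP log messages (the deterministic-LTD
#'   fallback is muffled by default; it is routine when the active input
#'   region is larger than the popcount budget).
#' @return list with \code{network} (updated [FeNetwork-class]),
#'   \code{spikeCounts} (integer per neuron), \code{stdpCounts},
#'   \code{spikes} (data.frame of \code{time}, \code{neuron} when
#'   recorded).
#' @export
runNetwork <- function(network, stream, learn = FALSE, wta = learn,
                       adaptThresholds = learn, leakOn = TRUE,
                       wtaPolicy = c("lowest", "random"),
                       recordSpikes = FALSE, verbose = FALSE) {
  stopifnot(is(network, "FeNetwork"), is(stream, "EventStream"))
  wtaPolicy <- match.arg(wtaPolicy)
  if (stream@addressSpace != nrow(network@weights@bits))
    stop("stream address space (", stream@addressSpace,
         ") does not match network input size (",
         nrow(network@weights@bits), ")")
  cfgN <- network@neuronConfig
  cfgS <- network@stdpConfig
  wst <- network@weights@wSumTarget
  cb <- function(j, buf, col) {
    if (verbose) .binaryStdpVector(col, buf, cfgS, wst)
    else withCallingHandlers(
      .binaryStdpVector(col, buf, cfgS, wst),
      bitsnnLtdFallback = function(c) invokeRestart("muffleMessage"))
  }
  res <- cpp_run_events(
    stream@addresses, stream@timestamps,
    network@weights@bits + 0L,                 # force a copy
    network@firingThresholds + 0.0,
    network@stdpThresholds + 0.0,
    cfgN@xThMax, cfgN@thIncrement,
    cfgN@dualThreshold, cfgN@stdpThIncrement,
    learn, wta, wtaPolicy == "random", adaptThresholds,
    leakOn, network@leak@halvingPoints, .leakSlopes(network@leak),
    cfgS@bufferSize, cfgS@flush, recordSpikes, cb)
  network@weights@bits <- res$weights
  network@firingThresholds <- res$firingThresholds
  network@stdpThresholds <- res$stdpThresholds
  out <- list(network = network, spikeCounts = res$spikeCounts,
              stdpCounts = res$stdpCounts)
  if (recordSpikes)
    out$spikes <- data.frame(time = res$spikeTimes,
                             neuron = res$spikeNeurons)
  out
}
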