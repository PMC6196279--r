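#' @include AllClasses.R AllGenerics.R
NULL

#' Random 1-bit weight matrices
#'
#' Draws initial binary weights. By default each neuron (column) receives
#' exactly \code{wSum} active synapses at uniformly random positions — the
#' "random fixed 1-bit weights with fixed W_sum" baseline. With
#' \code{constrained = FALSE}, bits are independent Bernoulli draws with
#' mean \code{wSum / nPre}.
#'
#' @param nPre,nPost matrix dimensions.
#' @param wSum per-neuron popcount budget.
#' @param constrained enforce exactly \code{wSum} ones per column.
#' @return a [BinaryWeights-class].
#' @export
randomBinaryWeights <- function(nPre, nPost, wSum, constrained = TRUE) {
  bits <- matrix(0L, nPre, nPost)
  if (constrained) {
    for (j in seq_len(nPost))
      bits[sample.int(nPre, wSum), j] <- 1L
  } else {
    bits[] <- as.integer(stats::runif(nPre * nPost) < wSum / nPre)
  }
  BinaryWeights(bits, wSum)
}

#' Stochastic update of a single 1-bit weight
#'
#' The elementary stochastic rule: for a positive probability \code{p}, the
#' weight is set to 1 when the uniform draw \code{u <= p}; for a negative
#' \code{p} it is set to 0 when \code{u <= |p|}; otherwise it is unchanged.
#' Idempotent on already-set targets. Vectorized over all arguments.
#'
#' @param w current bit(s), 0 or 1.
#' @param p signed probability(ies) in [-1, 1].
#' @param u uniform draw(s) in [0, 1].
#' @return updated bit(s).
#' @export
stochasticBitUpdate <- function(w, p, u) {
  if (any(p < -1 | p > 1)) stop("p must lie in [-1, 1]")
  set1 <- p > 0 & u <= p
  set0 <- p < 0 & u <= -p
  out <- as.integer(w)
  out[set1] <- 1L
  out[set0] <- 0L
  out
}

#' Normalized 10-bit LTD probability
#'
#' The hardware computes the depression probability on a 10-bit integer
#' scale as \code{floor(1024 * (actual - expected) / actual)}, where
#' \code{actual} is the current number of active weights of the neuron and
#' \code{expected} the popcount budget. When \code{actual <= expected} no
#' depression is needed and 0 is returned.
#'
#' @param actualActive current active-weight count (\eqn{W_{sum}}).
#' @param expectedActive target active-weight count.
#' @return integer in [0, 1024].
#' @examples
#' ltdProbability1024(200, 180)   # floor(1024 * 20 / 200) = 102
#' @export
ltdProbability1024 <- function(actualActive, expectedActive) {
  stopifnot(actualActive >= 0, expectedActive >= 0)
  if (actualActive <= expectedActive) return(0L)
  as.integer(floor(1024 * (actualActive - expectedActive) / actualActive))
}

## ---------------------------------------------------------------------------
## The 1-bit "undiscriminating depressing" STDP step
## ---------------------------------------------------------------------------

## classed message so that long training runs can muffle the (expected)
## fallback log while interactive callers still see it
.signalLtdFallback <- function(txt) {
  message(structure(
    class = c("bitsnnLtdFallback", "message", "condition"),
    list(message = paste0(txt, "\n"), call = NULL)))
}

## Pure core, fully determined by the injected random draws; this is the
## single implementation behind applyBinaryStdp and the simulator callback.
##   bits      integer vector of nPre bits (one neuron's column)
##   buffered  0-based addresses used for LTP (most-recent tail, duplicates
##             allowed; each entry costs one draw, setting is idempotent)
##   uLtp      uniform draws, one per buffered entry
##   ltdOrder  a permutation of seq_len(nPre): victim priority for
##             deterministic normalization
##   uLtd      uniform draws, one per active bit (increasing index order),
##             for stochastic normalization
.binaryStdpCore <- function(bits, buffered, config, uLtp,
                            ltdOrder = NULL, uLtd = NULL,
                            wSumTarget) {
  pLtp <- config@pLtp
  if (config@probabilityScale == "int1024")
    pLtp <- floor(pLtp * 1024) / 1024
  ## Phase 1 - LTP: potentiate buffered synapses with probability pLtp
  if (length(buffered)) {
    hit <- buffered[uLtp <= pLtp] + 1L
    bits[hit] <- 1L
  }
  ## Phase 2 - LTD: depress down toward the popcount budget
  pop <- sum(bits)
  dW <- pop - wSumTarget
  protected <- if (config@protectBuffered && length(buffered))
    unique(buffered + 1L) else integer(0)
  if (dW > 0) {
    if (config@normalization == "deterministic") {
      eligible <- ltdOrder[bits[ltdOrder] == 1L &
                           !(ltdOrder %in% protected)]
      if (length(eligible) < dW) {
        ## not enough depressible synapses outside the buffer: fall back to
        ## buffered active synapses as well
        .signalLtdFallback(paste0(
          "deterministic LTD: only ", length(eligible),
          " unprotected active synapses for dW = ", dW,
          "; depressing buffered synapses too"))
        extra <- ltdOrder[bits[ltdOrder] == 1L & (ltdOrder %in% protected)]
        eligible <- c(eligible, extra)
      }
      victims <- eligible[seq_len(min(dW, length(eligible)))]
      bits[victims] <- 0L
    } else {
      p1024 <- ltdProbability1024(pop, wSumTarget)
      targets <- which(bits == 1L)
      targets <- targets[!(targets %in% protected)]
      if (length(targets)) {
        hit <- targets[uLtd[seq_along(targets)] <= p1024 / 1024]
        bits[hit] <- 0L
      }
    }
  }
  bits
}

## Draw-generating wrapper over .binaryStdpCore operating on a plain bit
## vector; used directly as the simulator's STDP callback.
.binaryStdpVector <- function(bits, bufferEntries, config, wSumTarget) {
  buffered <- utils::tail(bufferEntries, config@numberOfPotentiation)
  uLtp <- if (length(buffered)) stats::runif(length(buffered)) else numeric(0)
  if (config@normalization == "deterministic") {
    .binaryStdpCore(bits, buffered, config, uLtp,
                    ltdOrder = sample.int(length(bits)),
                    wSumTarget = wSumTarget)
  } else {
    .binaryStdpCore(bits, buffered, config, uLtp,
                    uLtd = stats::runif(sum(bits == 1L) + length(buffered)),
                    wSumTarget = wSumTarget)
  }
}

#' Apply one stochastic 1-bit STDP update to a neuron
#'
#' Implements the "undiscriminating depressing" order-based 1-bit rule that
#' runs whenever a neuron produces an STDP trigger. Phase 1 (LTP): each of
#' the up-to-\code{numberOfPotentiation} most recent addresses in the
#' population pre-buffer is potentiated to 1 with probability \code{pLtp}.
#' Phase 2 (LTD): the neuron's active-weight count is pushed back toward
#' the budget \eqn{W_{sum}} — deterministically (exactly
#' \eqn{\Delta W = popcount - W_{sum}} victims cleared, chosen uniformly at
#' random among active synapses not named in the buffer) or stochastically
#' (every active synapse cleared with probability
#' \code{ltdProbability1024 / 1024}). LTP never clears a bit and LTD never
#' sets one. Buffer flushing (Phase 3) is the caller's responsibility via
#' [flushBuffer()], since the buffer is shared by the population.
#'
#' @param weights a [BinaryWeights-class].
#' @param neuronIndex 1-based column index of the updated neuron.
#' @param buffer a [PreBuffer-class] of the population.
#' @param config a [StdpConfig-class].
#' @return the updated [BinaryWeights-class].
#' @seealso [applyBinaryStdpHw()] for the LFSR-driven hardware-emulation
#'   path, [pushPre()], [flushBuffer()].
#' @export
applyBinaryStdp <- function(weights, neuronIndex, buffer, config) {
  stopifnot(is(weights, "BinaryWeights"), is(buffer, "PreBuffer"))
  bits <- weights@bits[, neuronIndex]
  weights@bits[, neuronIndex] <-
    .binaryStdpVector(bits, buffer@entries, config, weights@wSumTarget)
  weights
}

#' Hardware-emulation STDP update driven by a 16-bit LFSR
#'
#' Same rule as [applyBinaryStdp()] but on the 10-bit integer probability
#' scale: each decision compares the low 10 bits of an LFSR draw against
#' the integer probability (accept when \code{sample < p1024}), exactly as
#' the hardware STDP unit does. The LFSR steps once per decision. This path
#' never protects buffered synapses from depression: the hardware LTD
#' rescans all weights.
#'
#' @inheritParams applyBinaryStdp
#' @param lfsr a [Lfsr16-class].
#' @return list with \code{weights} (updated [BinaryWeights-class]) and
#'   \code{lfsr} (advanced [Lfsr16-class]).
#' @export
applyBinaryStdpHw <- function(weights, neuronIndex, buffer, config, lfsr) {
  bits <- weights@bits[, neuronIndex]
  pLtp1024 <- as.integer(floor(config@pLtp * 1024))
  buffered <- utils::tail(buffer@entries, config@numberOfPotentiation)
  for (a in buffered) {
    step <- lfsrNext(lfsr)
    lfsr <- step$lfsr
    if (step$sample < pLtp1024) bits[a + 1L] <- 1L
  }
  pop <- sum(bits)
  if (config@normalization == "deterministic") {
    dW <- pop - weights@wSumTarget
    if (dW > 0) {
      active <- which(bits == 1L)
      ## serial random victim selection from the LFSR stream
      while (dW > 0 && length(active)) {
        step <- lfsrNext(lfsr)
        lfsr <- step$lfsr
        k <- (step$sample %% length(active)) + 1L
        bits[active[k]] <- 0L
        active <- active[-k]
        dW <- dW - 1L
      }
    }
  } else {
    p1024 <- ltdProbability1024(pop, weights@wSumTarget)
    if (p1024 > 0) {
      for (i in which(bits == 1L)) {
        step <- lfsrNext(lfsr)
        lfsr <- step$lfsr
        if (step$sample < p1024) bits[i] <- 0L
      }
    }
  }
  weights@bits[, neuronIndex] <- bits
  list(weights = weights, lfsr = lfsr)
}

#' Push an address into a pre-buffer
#'
#' Appends the address; the oldest entry is evicted when the capacity is
#' exceeded (circular-buffer semantics).
#'
#' @param buffer a [PreBuffer-class].
#' @param address 0-based pre-synaptic address(es).
#' @return the updated [PreBuffer-class].
#' @export
pushPre <- function(buffer, address) {
  e <- c(buffer@entries, as.integer(address))
  n <- length(e)
  if (n > buffer@capacity) e <- e[(n - buffer@capacity + 1L):n]
  buffer@entries <- e
  buffer
}

#' Empty a pre-buffer (list flushing)
#'
#' After an STDP update the recent history that triggered it can be
#' discarded so it does not contribute to learning for other output events.
#'
#' @param buffer a [PreBuffer-class].
#' @return the emptied [PreBuffer-class].
#' @export
flushBuffer <- function(buffer) {
  buffer@entries <- integer(0)
  buffer
}

#' Winner-take-all resolution
#'
#' Picks exactly one winner among the neurons that crossed threshold on the
#' same input event; all other population members are to be reset via
#' [inhibit()]. Tie-break policy: \code{"lowest"} (deterministic lowest
#' index) or \code{"random"} (seeded uniform draw).
#'
#' @param candidates non-empty vector of neuron indices.
#' @param policy "lowest" or "random".
#' @return the winning index.
#' @export
wtaResolve <- function(candidates, policy = c("lowest", "random")) {
  policy <- match.arg(policy)
  if (!length(candidates)) stop("empty candidate list")
  if (policy == "lowest") min(candidates)
  else candidates[sample.int(length(candidates), 1L)]
}
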