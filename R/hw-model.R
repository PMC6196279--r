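#' @include AllClasses.R
NULL

#' LTP phase cycle count
#'
#' The LTP processor reads the most recent buffered addresses and
#' potentiates each in one pipelined cycle; the pipeline overhead is the
#' circular-buffer read latency plus the synaptic-memory read latency plus
#' one write-bus pad cycle (3 + 3 + 1 = 7 at the defaults). Total:
#' \code{overhead + numPotentiation}, i.e. 7 + 1024 = 1031 cycles in the
#' worst case.
#'
#' @param numPotentiation events used for LTP (0..synapseCount).
#' @param model a [CycleCostModel-class].
#' @return clock cycles.
#' @export
ltpCycles <- function(numPotentiation, model = CycleCostModel()) {
  if (numPotentiation < 0 || numPotentiation > model@synapseCount)
    stop("numPotentiation must lie in [0, ", model@synapseCount, "]")
  model@bufferReadLatency + model@weightReadLatency + model@pipelinePad +
    numPotentiation
}

#' LTD phase cycle count
#'
#' The LTD processor first reads all synaptic weights to count the active
#' ones (synapseCount + read latency cycles), runs the serial divider to
#' form the normalized depression probability, then rescans and depresses
#' all weights (synapseCount + pipeline overhead cycles). At the defaults:
#' 1024 + 3 + 25 + 1024 + 7 = 2083 cycles.
#'
#' @param model a [CycleCostModel-class].
#' @return clock cycles.
#' @export
ltdCycles <- function(model = CycleCostModel()) {
  pipeline <- model@bufferReadLatency + model@weightReadLatency +
    model@pipelinePad
  (model@synapseCount + model@weightReadLatency) + model@dividerLatency +
    (model@synapseCount + pipeline)
}

#' Total STDP process cycle count
#'
#' LTP plus LTD; at the default latencies this is
#' \code{2090 + numPotentiation} cycles (worst case 3114 for 1024
#' potentiations, 2180 for the 90-event buffer).
#'
#' @inheritParams ltpCycles
#' @return clock cycles.
#' @export
stdpTotalCycles <- function(numPotentiation, model = CycleCostModel()) {
  ltpCycles(numPotentiation, model) + ltdCycles(model)
}

#' STDP-unit saturation rate
#'
#' The shared STDP unit serves one trigger per \code{stdpTotalCycles}
#' clock cycles, so it saturates at \code{clockHz / stdpTotalCycles} STDP
#' output events per second; while saturated, further STDP output events
#' are ignored and training just takes longer.
#'
#' @inheritParams ltpCycles
#' @return events per second.
#' @export
saturationRate <- function(model = CycleCostModel(), numPotentiation) {
  model@clockHz / stdpTotalCycles(numPotentiation, model)
}

#' Advance a 16-bit LFSR by one step
#'
#' One shift of the Fibonacci LFSR; the returned sample is the low 10 bits
#' of the new state, the value the hardware compares against 10-bit
#' integer probabilities (accept when \code{sample < p1024}).
#'
#' @param lfsr an [Lfsr16-class] (nonzero state).
#' @return list with \code{lfsr} (advanced) and \code{sample} (integer in
#'   [0, 1023]).
#' @export
lfsrNext <- function(lfsr) {
  step <- cpp_lfsr_sequence(lfsr@state, lfsr@taps, 1L)
  lfsr@state <- step$state[1]
  list(lfsr = lfsr, sample = step$sample[1])
}

#' Enumerate an LFSR orbit
#'
#' @param lfsr an [Lfsr16-class].
#' @param n number of steps.
#' @return list with integer vectors \code{state} and \code{sample}
#'   (low 10 bits) of length \code{n}.
#' @export
lfsrSequence <- function(lfsr, n) {
  cpp_lfsr_sequence(lfsr@state, lfsr@taps, as.integer(n))
}

#' Hardware resource-scaling model
#'
#' Linear resource model of a hidden layer with \code{nInputs} inputs,
#' \code{nHidden} neurons and \code{nBits} weight resolution:
#' \deqn{R_{syn} = \alpha_{syn} N_i N_h n_b,\quad
#'       R_h = \alpha_h N_h n_b,\quad R_{ov} = \alpha_{ov} n_b.}
#' With overhead negligible, equal hardware resources require the product
#' \eqn{N_h \times n_b} to stay constant — e.g. 256 neurons at 1 bit align
#' with 32 neurons at 8 bits.
#'
#' @param nInputs,nHidden,nBits layer dimensions and weight resolution.
#' @param alphas named numeric: \code{syn}, \code{h}, \code{ov}
#'   proportionality constants.
#' @return named numeric: \code{Rsyn}, \code{Rh}, \code{Rov},
#'   \code{core} (Rsyn + Rh), \code{total}.
#' @export
resourceModel <- function(nInputs, nHidden, nBits,
                          alphas = c(syn = 1, h = 1, ov = 1)) {
  stopifnot(nInputs > 0, nHidden > 0, nBits > 0)
  Rsyn <- alphas[["syn"]] * nInputs * nHidden * nBits
  Rh <- alphas[["h"]] * nHidden * nBits
  Rov <- alphas[["ov"]] * nBits
  c(Rsyn = Rsyn, Rh = Rh, Rov = Rov, core = Rsyn + Rh,
    total = Rsyn + Rh + Rov)
}

#' Cycle/saturation sweep table
#'
#' Convenience for the \code{hwcost} command-line view: cycle counts and
#' saturation rates over a sweep of potentiation counts.
#'
#' @param numPotentiation integer vector to sweep.
#' @param model a [CycleCostModel-class].
#' @return data.frame with \code{numPotentiation}, \code{ltpCycles},
#'   \code{ltdCycles}, \code{totalCycles}, \code{saturationEps}.
#' @export
hwCostTable <- function(numPotentiation = c(0, 90, 250, 512, 1024),
                        model = CycleCostModel()) {
  data.frame(
    numPotentiation = numPotentiation,
    ltpCycles = vapply(numPotentiation, ltpCycles, numeric(1),
                       model = model),
    ltdCycles = ltdCycles(model),
    totalCycles = vapply(numPotentiation, stdpTotalCycles, numeric(1),
                         model = model),
    saturationEps = vapply(numPotentiation, function(n)
      saturationRate(model, n), numeric(1)))
}
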