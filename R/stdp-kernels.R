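#' @include AllClasses.R
NULL

#' Evaluate an STDP learning function
#'
#' Returns \eqn{\xi(\Delta)} for the configured kernel shape, where
#' \code{delta} is \eqn{t_{post} - t_{pre}} (time mode, microseconds) or the
#' rank difference (order mode). Positive values potentiate, negative values
#' depress; the function is zero outside the kernel windows
#' \code{[-tMin, tMax]}.
#'
#' @param kernel a [StdpKernel-class].
#' @param delta signed time or rank difference(s); vectorized.
#' @return signed magnitude(s), probabilities in stochastic (1-bit) use.
#' @examples
#' k <- StdpKernel("order", "narrow-potentiation", aPlus = 0.8,
#'                 aMinus = 0.5, tP = 5)
#' kernelEval(k, c(3, 8, -2))   # +0.8, -0.5, -0.5
#' @export
kernelEval <- function(kernel, delta) {
  aP <- kernel@aPlus; aM <- kernel@aMinus
  tP <- kernel@tP; tMax <- kernel@tMax; tMin <- kernel@tMin
  inPos <- delta > 0 & delta <= tMax
  inNeg <- delta < 0 & -delta <= tMin
  out <- numeric(length(delta))
  switch(kernel@shape,
    "classic" = {
      out[inPos] <- aP * exp(-delta[inPos] / kernel@tauPlus)
      out[inNeg] <- -aM * exp(delta[inNeg] / kernel@tauMinus)
    },
    "rectangular" = {
      out[inPos] <- aP
      out[inNeg] <- -aM
    },
    "narrow-potentiation" = {
      ## potentiate only in the narrow positive window, depress elsewhere
      ## inside the kernel window (incl. delta == 0 and the negative side)
      out[inPos & delta <= tP] <- aP
      out[inPos & delta > tP] <- -aM
      out[inNeg] <- -aM
      out[delta == 0 & tMin >= 0] <- -aM
    },
    "symmetric-hebbian" = {
      out[abs(delta) <= tP & (inPos | inNeg | delta == 0)] <- aP
      out[delta == 0] <- aP
    },
    "symmetric-narrow" = {
      near <- abs(delta) <= tP
      out[near & (inPos | inNeg | delta == 0)] <- aP
      out[delta == 0] <- aP
      out[!near & (inPos | inNeg)] <- -aM
    })
  out
}

#' StdpEngine: bounded pre/post event-list STDP computation
#'
#' The engine stores recent pre- and post-synaptic events in bounded lists.
#' In time mode, entries expire once older than the kernel windows
#' (\code{tMax} for the pre-list, \code{tMin} for the post-list); in order
#' mode the lists are bounded by rank distance and no timestamps are kept,
#' only a global arrival counter. For every new event the opposite list is
#' scanned and one signed weight-update command is emitted per matching
#' entry (or only for the most recent one when \code{mostRecentOnly}).
#'
#' @slot kernel a [StdpKernel-class].
#' @slot preKeys,postKeys numeric event keys (timestamps in time mode,
#'   global ranks in order mode).
#' @slot preAddr,postAddr integer neuron indices.
#' @slot counter numeric(1), global arrival rank.
#' @slot mostRecentOnly logical(1).
#' @export
setClass("StdpEngine",
  representation(kernel = "StdpKernel", preKeys = "numeric",
                 preAddr = "integer", postKeys = "numeric",
                 postAddr = "integer", counter = "numeric",
                 mostRecentOnly = "logical"),
  prototype(preKeys = numeric(0), preAddr = integer(0),
            postKeys = numeric(0), postAddr = integer(0), counter = 0,
            mostRecentOnly = FALSE))

#' @rdname StdpEngine-class
#' @param kernel a [StdpKernel-class].
#' @param mostRecentOnly emit an update only for the most recent opposite
#'   entry instead of all of them.
#' @export
StdpEngine <- function(kernel, mostRecentOnly = FALSE) {
  new("StdpEngine", kernel = kernel, mostRecentOnly = mostRecentOnly)
}

## key of an incoming event and eviction of expired entries
.engineKey <- function(engine, now) {
  if (engine@kernel@mode == "time") now else engine@counter
}

.evict <- function(keys, addr, key, window) {
  keep <- (key - keys) <= window
  list(keys = keys[keep], addr = addr[keep])
}

#' Feed one pre-synaptic event to an STDP engine
#'
#' Stores the event in the pre-list, evicts expired entries from both lists
#' and emits one signed update per stored post-synaptic event within the
#' kernel window (\eqn{\Delta = key_{post} - key_{pre} \le 0} here).
#'
#' @param engine a [StdpEngine-class].
#' @param preAddress 0-based pre-synaptic index.
#' @param now event timestamp in microseconds (ignored for ordering in
#'   order mode, where only arrival rank matters).
#' @return list with \code{engine} (updated) and \code{updates}, a
#'   data.frame with columns \code{pre}, \code{post}, \code{dw}.
#' @export
onPreEvent <- function(engine, preAddress, now) {
  engine@counter <- engine@counter + 1
  key <- .engineKey(engine, now)
  ev <- .evict(engine@postKeys, engine@postAddr, key, engine@kernel@tMin)
  engine@postKeys <- ev$keys; engine@postAddr <- ev$addr
  scan <- seq_along(engine@postKeys)
  if (engine@mostRecentOnly && length(scan)) scan <- length(scan)
  dw <- kernelEval(engine@kernel, engine@postKeys[scan] - key)
  keep <- dw != 0
  updates <- data.frame(pre = rep(as.integer(preAddress), sum(keep)),
                        post = engine@postAddr[scan][keep], dw = dw[keep])
  engine@preKeys <- c(engine@preKeys, key)
  engine@preAddr <- c(engine@preAddr, as.integer(preAddress))
  ev <- .evict(engine@preKeys, engine@preAddr, key, engine@kernel@tMax)
  engine@preKeys <- ev$keys; engine@preAddr <- ev$addr
  list(engine = engine, updates = updates)
}

#' Feed one post-synaptic event to an STDP engine
#'
#' Stores the event in the post-list and emits one signed update per stored
#' pre-synaptic event within the kernel window
#' (\eqn{\Delta = key_{post} - key_{pre} \ge 0}).
#'
#' @inheritParams onPreEvent
#' @param postAddress 0-based post-synaptic index.
#' @return list with \code{engine} and \code{updates} as in [onPreEvent()].
#' @export
onPostEvent <- function(engine, postAddress, now) {
  engine@counter <- engine@counter + 1
  key <- .engineKey(engine, now)
  ev <- .evict(engine@preKeys, engine@preAddr, key, engine@kernel@tMax)
  engine@preKeys <- ev$keys; engine@preAddr <- ev$addr
  scan <- seq_along(engine@preKeys)
  if (engine@mostRecentOnly && length(scan)) scan <- length(scan)
  dw <- kernelEval(engine@kernel, key - engine@preKeys[scan])
  keep <- dw != 0
  updates <- data.frame(pre = engine@preAddr[scan][keep],
                        post = rep(as.integer(postAddress), sum(keep)),
                        dw = dw[keep])
  engine@postKeys <- c(engine@postKeys, key)
  engine@postAddr <- c(engine@postAddr, as.integer(postAddress))
  ev <- .evict(engine@postKeys, engine@postAddr, key, engine@kernel@tMin)
  engine@postKeys <- ev$keys; engine@postAddr <- ev$addr
  list(engine = engine, updates = updates)
}
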