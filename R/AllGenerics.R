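#' @include AllClasses.R
NULL

#' Accessors for EventStream
#'
#' @param x an [EventStream-class].
#' @return \code{eventTimes}: numeric microseconds; \code{eventAddresses}:
#'   0-based integer addresses; \code{eventPolarity}: integer (length 0 when
#'   absent); \code{addressSpace}: integer(1); \code{geometry}: integer of
#'   length 0 or 2; \code{nEvents}: integer(1).
#' @name EventStream-accessors
NULL

#' @rdname EventStream-accessors
#' @export
setGeneric("eventTimes", function(x) standardGeneric("eventTimes"))
#' @rdname EventStream-accessors
#' @export
setGeneric("eventAddresses", function(x) standardGeneric("eventAddresses"))
#' @rdname EventStream-accessors
#' @export
setGeneric("eventPolarity", function(x) standardGeneric("eventPolarity"))
#' @rdname EventStream-accessors
#' @export
setGeneric("addressSpace", function(x) standardGeneric("addressSpace"))
#' @rdname EventStream-accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))
#' @rdname EventStream-accessors
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @rdname EventStream-accessors
setMethod("eventTimes", "EventStream", function(x) x@timestamps)
#' @rdname EventStream-accessors
setMethod("eventAddresses", "EventStream", function(x) x@addresses)
#' @rdname EventStream-accessors
setMethod("eventPolarity", "EventStream", function(x) x@polarity)
#' @rdname EventStream-accessors
setMethod("addressSpace", "EventStream", function(x) x@addressSpace)
#' @rdname EventStream-accessors
setMethod("geometry", "EventStream", function(x) x@geometry)
#' @rdname EventStream-accessors
setMethod("nEvents", "EventStream", function(x) length(x@timestamps))

#' @rdname EventStream-accessors
#' @aliases length,EventStream-method
setMethod("length", "EventStream", function(x) length(x@timestamps))

setMethod("show", "EventStream", function(object) {
  cat("EventStream with", length(object@timestamps), "events,",
      "address space", object@addressSpace, "\n")
  if (length(object@geometry) == 2L)
    cat("  geometry:", object@geometry[1], "x", object@geometry[2], "\n")
  if (length(object@timestamps)) {
    cat("  time span:", object@timestamps[1], "-",
        object@timestamps[length(object@timestamps)], "us\n")
  }
})

#' Accessors for BinaryWeights
#'
#' @param x a [BinaryWeights-class].
#' @return \code{weightBits}: the integer bit matrix (nPre x nPost);
#'   \code{popcounts}: integer vector of per-neuron active-synapse counts;
#'   \code{wSumTarget}: the popcount budget.
#' @name BinaryWeights-accessors
NULL

#' @rdname BinaryWeights-accessors
#' @export
setGeneric("weightBits", function(x) standardGeneric("weightBits"))
#' @rdname BinaryWeights-accessors
#' @export
setGeneric("popcounts", function(x) standardGeneric("popcounts"))
#' @rdname BinaryWeights-accessors
#' @export
setGeneric("wSumTarget", function(x) standardGeneric("wSumTarget"))

#' @rdname BinaryWeights-accessors
setMethod("weightBits", "BinaryWeights", function(x) x@bits)
#' @rdname BinaryWeights-accessors
setMethod("popcounts", "BinaryWeights", function(x) colSums(x@bits))
#' @rdname BinaryWeights-accessors
setMethod("wSumTarget", "BinaryWeights", function(x) x@wSumTarget)

setMethod("show", "BinaryWeights", function(object) {
  cat("BinaryWeights:", nrow(object@bits), "pre x", ncol(object@bits),
      "post, W_sum target", object@wSumTarget, "\n")
  cat("  popcounts:", paste(utils::head(colSums(object@bits), 8),
                            collapse = " "),
      if (ncol(object@bits) > 8) "..." else "", "\n")
})

setMethod("show", "PreBuffer", function(object) {
  cat("PreBuffer:", length(object@entries), "/", object@capacity,
      "entries\n")
})

setMethod("show", "LeakSchedule", function(object) {
  cat("LeakSchedule: decrement", object@initialDecrement, "per",
      object@tickUs, "us tick, halving at",
      paste(object@halvingPoints, collapse = ", "), "us\n")
  if (!is.na(object@targetTau))
    cat("  approximates exp decay, tau =", object@targetTau, "us",
        if (!is.na(object@fitError))
          paste0("(max fit error ", signif(object@fitError, 3), ")"),
        "\n")
})

setMethod("show", "FeNetwork", function(object) {
  cat("FeNetwork:", nrow(object@weights@bits), "inputs ->",
      ncol(object@weights@bits), "neurons\n")
  cat("  firing thresholds:",
      paste(utils::head(object@firingThresholds, 8), collapse = " "), "\n")
  cat("  W_sum target:", object@weights@wSumTarget, ", normalization:",
      object@stdpConfig@normalization, "\n")
})

setMethod("show", "TuningCurve", function(object) {
  cat("TuningCurve:", nrow(object@rates), "neurons x",
      length(object@angles), "angles\n")
  pref <- object@angles[apply(object@rates, 1, which.max)]
  cat("  preferred angles:", paste(pref, collapse = " "), "deg\n")
})

setMethod("show", "CycleCostModel", function(object) {
  cat("CycleCostModel:", object@synapseCount, "synapses, clock",
      object@clockHz / 1e6, "MHz\n")
  cat("  LTD cycles:", ltdCycles(object), "\n")
})

setMethod("show", "Lfsr16", function(object) {
  cat("Lfsr16: state", object@state, ", taps",
      paste(object@taps, collapse = ","), "\n")
})

setMethod("show", "SnnClassifier", function(object) {
  cat("SnnClassifier:", nrow(object@weights), "features ->",
      ncol(object@weights), "classes, threshold k =", object@threshold,
      "(", object@resetMode, "reset )\n")
})

setMethod("show", "SimpleClassifier", function(object) {
  cat("SimpleClassifier:", nrow(object@weights), "features ->",
      ncol(object@weights), "classes, column budget", object@wSumTarget, "\n")
})
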