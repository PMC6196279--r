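#' @include AllClasses.R AllGenerics.R network.R
NULL

#' Construct a teacher-driven STDP classifier
#'
#' @param nFeatures number of FE-layer neurons feeding the classifier.
#' @param nClasses number of output classes.
#' @param wSumTarget per-class column-sum budget (default 8-bit scale:
#'   32 * nFeatures / nClasses is a reasonable order; here simply
#'   \code{4 * nFeatures}).
#' @param learnRate integer potentiation amount per buffered feature.
#' @param bufferSize capacity of the FE-spike buffer.
#' @return a [SimpleClassifier-class] with uniform initial weights summing
#'   to the budget.
#' @export
SimpleClassifier <- function(nFeatures, nClasses,
                             wSumTarget = 4 * nFeatures, learnRate = 8,
                             bufferSize = 64) {
  w0 <- matrix(as.integer(round(wSumTarget / nFeatures)),
               nFeatures, nClasses)
  new("SimpleClassifier", weights = w0, wSumTarget = wSumTarget,
      learnRate = learnRate, bufferSize = as.integer(bufferSize),
      buffer = integer(0))
}

#' Buffer an FE-layer spike for the simple classifier
#'
#' @param clf a [SimpleClassifier-class].
#' @param feature 0-based FE neuron index(es) that spiked.
#' @return the updated classifier.
#' @export
bufferFeature <- function(clf, feature) {
  e <- c(clf@buffer, as.integer(feature))
  n <- length(e)
  if (n > clf@bufferSize) e <- e[(n - clf@bufferSize + 1L):n]
  clf@buffer <- e
  clf
}

## renormalize one integer column to the budget, largest-remainder rounding
.renormColumn <- function(col, budget) {
  s <- sum(col)
  if (s == 0) return(col)
  scaled <- col * budget / s
  base <- floor(scaled)
  rem <- budget - sum(base)
  if (rem > 0) {
    o <- order(scaled - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Teacher-driven STDP update of the simple classifier
#'
#' The post-synaptic spike is replaced by a teacher signal naming the
#' correct class: weights from the buffered FE neurons to that class grow
#' by \code{learnRate}, then the class column is renormalized so its sum
#' returns to the budget (integer largest-remainder scaling). The buffer is
#' flushed afterwards. An empty buffer is a no-op.
#'
#' @param clf a [SimpleClassifier-class].
#' @param teacherClass 1-based index of the correct class.
#' @return the updated [SimpleClassifier-class].
#' @export
simpleClassifierUpdate <- function(clf, teacherClass) {
  if (!length(clf@buffer)) return(clf)
  col <- clf@weights[, teacherClass]
  tab <- tabulate(clf@buffer + 1L, nbins = nrow(clf@weights))
  col <- col + clf@learnRate * tab
  clf@weights[, teacherClass] <- .renormColumn(col, clf@wSumTarget)
  clf@buffer <- integer(0)
  clf
}

#' Classify with the simple classifier
#'
#' Readout is the spike-count-weighted score: each class accumulates the
#' product of FE spike counts and its weights; the argmax wins, ties broken
#' by lowest index.
#'
#' @param clf a [SimpleClassifier-class].
#' @param featureCounts integer vector of FE spike counts (length
#'   nFeatures).
#' @return 1-based predicted class.
#' @export
simpleClassifierPredict <- function(clf, featureCounts) {
  scores <- as.numeric(crossprod(clf@weights, featureCounts))
  which.max(scores)
}

#' Normalized spike-count histogram of the FE layer
#'
#' Counts spikes per FE neuron over a sample and divides by the total
#' (per-sample L1 normalization): entries are non-negative and sum to 1
#' when any spike occurred, else the all-zero vector is returned.
#' Order-free: permuting events leaves the histogram unchanged.
#'
#' @param events an [EventStream-class] over FE addresses, or an integer
#'   vector of 0-based FE spike addresses.
#' @param nFeatures number of FE neurons.
#' @return numeric vector of length \code{nFeatures}.
#' @export
histogramFeatures <- function(events, nFeatures) {
  addr <- if (is(events, "EventStream")) events@addresses else
    as.integer(events)
  if (length(addr) && any(addr >= nFeatures))
    stop("event address exceeds the number of features")
  counts <- tabulate(addr + 1L, nbins = nFeatures)
  total <- sum(counts)
  if (total == 0) numeric(nFeatures) else counts / total
}

#' Train a softmax classifier by mini-batch SGD
#'
#' Multinomial logistic regression on histogram features, minimizing
#' cross-entropy by mini-batch stochastic gradient descent. No bias term:
#' histogram features are L1-normalized, so a bias is redundant with the
#' weight offset applied at spiking conversion. Reproducible per seed.
#'
#' @param features numeric matrix (samples x features).
#' @param labels integer class labels, 1-based.
#' @param nClasses number of classes (default \code{max(labels)}).
#' @param learnRate SGD step size.
#' @param epochs passes over the training set.
#' @param batchSize mini-batch size.
#' @param l2 ridge penalty.
#' @param seed RNG seed for shuffling and initialization.
#' @return list with \code{weights} (features x classes) and \code{loss}
#'   (per-epoch mean cross-entropy).
#' @export
trainSoftmaxSgd <- function(features, labels, nClasses = max(labels),
                            learnRate = 2, epochs = 60, batchSize = 16,
                            l2 = 1e-4, seed = 1) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("softmax training needs at least 2 classes present")
  n <- nrow(features); p <- ncol(features)
  set.seed(seed)
  W <- matrix(stats::rnorm(p * nClasses, sd = 0.01), p, nClasses)
  Y <- matrix(0, n, nClasses)
  Y[cbind(seq_len(n), labels)] <- 1
  loss <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (start in seq(1, n, by = batchSize)) {
      idx <- ord[start:min(start + batchSize - 1, n)]
      X <- features[idx, , drop = FALSE]
      S <- X %*% W
      S <- S - apply(S, 1, max)
      P <- exp(S); P <- P / rowSums(P)
      G <- crossprod(X, P - Y[idx, , drop = FALSE]) / length(idx) + l2 * W
      W <- W - learnRate * G
      tot <- tot - sum(log(pmax(P[cbind(seq_along(idx), labels[idx])],
                                1e-12)))
    }
    loss[ep] <- tot / n
  }
  list(weights = W, loss = loss)
}

#' Frame-domain softmax prediction
#'
#' @param weights features x classes weight matrix.
#' @param features numeric matrix (samples x features) or a single vector.
#' @return 1-based predicted class per sample.
#' @export
softmaxPredict <- function(weights, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  apply(features %*% weights, 1, which.max)
}

#' Convert a frame-trained classifier to spiking neurons
#'
#' Scales the weights by a constant \code{k} and sets the threshold of the
#' LIF output neurons to \code{k}. Spiking states are non-negative, so
#' negative weights are first removed: by default a single global offset
#' (\code{-min(W)}) is added to every weight — the per-class scores all
#' shift by the same amount per input event, leaving the argmax unchanged —
#' or negatives are clipped at zero (\code{negatives = "clip"}, an
#' approximation).
#'
#' @param weights real-valued features x classes matrix.
#' @param k positive scaling constant (and output threshold).
#' @param negatives "offset" (default) or "clip".
#' @param resetMode output-neuron reset: "subtract" (reset by threshold
#'   subtraction; preserves rates and is the faithful rate-code conversion)
#'   or "zero".
#' @return an [SnnClassifier-class].
#' @export
convertToSnn <- function(weights, k, negatives = c("offset", "clip"),
                         resetMode = c("subtract", "zero")) {
  negatives <- match.arg(negatives)
  resetMode <- match.arg(resetMode)
  if (k <= 0) stop("k must be positive")
  W <- weights
  if (negatives == "offset") {
    m <- min(W)
    if (m < 0) W <- W - m
  } else {
    W[W < 0] <- 0
  }
  Wi <- round(k * W)
  storage.mode(Wi) <- "integer"
  new("SnnClassifier", weights = Wi, threshold = k, resetMode = resetMode)
}

#' Classify an event stream with a converted spiking classifier
#'
#' Runs the events through the integrate-and-fire output layer and returns
#' the class with the maximum output spike count; ties break to the lowest
#' index. A sample that produces no output spikes yields the default class
#' with a warning.
#'
#' @param clf an [SnnClassifier-class].
#' @param events an [EventStream-class] over FE addresses, or an integer
#'   vector of 0-based addresses.
#' @param defaultClass class returned when no output spike occurs.
#' @return 1-based predicted class.
#' @export
snnClassify <- function(clf, events, defaultClass = 1L) {
  addr <- if (is(events, "EventStream")) events@addresses else
    as.integer(events)
  counts <- cpp_snn_counts(addr, clf@weights, clf@threshold,
                           clf@resetMode == "subtract")
  if (sum(counts) == 0L) {
    warning("no output spikes; returning default class")
    return(defaultClass)
  }
  which.max(counts)
}
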