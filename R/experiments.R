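#' @include AllClasses.R network.R stimuli.R classifiers.R
NULL

#' Default configuration of the orientation-selectivity experiment
#'
#' A 32 x 32 input layer fully connected to 4 neurons, trained on Poisson
#' encoded oriented bars: initial threshold 10, threshold ceiling 100,
#' pre-buffer of 250 events, LTP probability 80%, popcount budget
#' \eqn{W_{sum} = 180}, deterministic weight normalization, 400 training
#' epochs over the orientations 0, 45, 90 and 135 degrees. The encoding
#' defaults (200 spikes per sample at a 100 kev/s population rate, leak time
#' constant 12 ms, inter-symbol time = the full leak-to-rest time) are this
#' package's choices and are recorded here as data.
#'
#' @param epochs training epochs.
#' @param spikesPerSample Poisson events per bar presentation.
#' @param totalRate population event rate (events/second); fast enough
#'   that per-event integration dominates the leak between events.
#' @param tauUs leak time constant (microseconds).
#' @return a list with components \code{nInput}, \code{nFe},
#'   \code{orientations}, \code{epochs}, \code{neuron}
#'   ([NeuronConfig-class]), \code{stdp} ([StdpConfig-class]), \code{leak}
#'   ([LeakSchedule-class]), \code{encoding} ([EncodingConfig-class]),
#'   \code{wSum}.
#' @export
orientationConfig <- function(epochs = 400, spikesPerSample = 200,
                              totalRate = 1e5, tauUs = 12000) {
  leak <- fitLeakSchedule(tauUs)
  list(nInput = 1024L, nFe = 4L, orientations = c(0, 45, 90, 135),
       epochs = epochs, wSum = 180L,
       neuron = NeuronConfig(xThInit = 10, xThMax = 100, thIncrement = 1),
       stdp = StdpConfig(pLtp = 0.8, bufferSize = 250,
                         normalization = "deterministic", flush = TRUE),
       leak = leak,
       encoding = EncodingConfig(totalRate = totalRate,
                                 totalSpikes = spikesPerSample,
                                 istUs = leakRestTime(leak, 100)))
}

#' Train the orientation-selectivity network
#'
#' Runs the unsupervised experiment: for each epoch the four oriented bars
#' are presented once in random order as Poisson spike trains separated by
#' an inter-symbol time long enough for all neurons to leak to rest.
#' Plasticity, winner-take-all inhibition and homeostatic threshold
#' adaptation are all enabled. With deterministic normalization every
#' neuron's active-synapse count equals \eqn{W_{sum}} at all times.
#'
#' @param config as returned by [orientationConfig()].
#' @param seed RNG seed; the run is bitwise reproducible per seed.
#' @return a trained [FeNetwork-class].
#' @export
runOrientationTraining <- function(config = orientationConfig(), seed = 1) {
  set.seed(seed)
  w0 <- randomBinaryWeights(config$nInput, config$nFe, config$wSum)
  net <- FeNetwork(w0, neuronConfig = config$neuron,
                   stdpConfig = config$stdp, leak = config$leak)
  seq <- barSequence(config$orientations, epochs = config$epochs,
                     config = config$encoding,
                     size = as.integer(sqrt(config$nInput)))
  runNetwork(net, seq$stream, learn = TRUE, wta = TRUE,
             adaptThresholds = TRUE)$network
}

#' Measure orientation tuning curves
#'
#' Post-learning test protocol: plasticity, dynamic thresholds and the
#' internal (inhibition) reset are disabled and thresholds stay at their
#' final training values; a bar is presented at each angle and each
#' neuron's firing rate is recorded.
#'
#' @param network a trained [FeNetwork-class].
#' @param angles stimulus angles in degrees (default 0..180 step 10).
#' @param encoding an [EncodingConfig-class] for the probe stimuli
#'   (default 2000 spikes per angle at the training rate).
#' @return a [TuningCurve-class] (rates in events/second).
#' @export
measureTuning <- function(network, angles = seq(0, 180, by = 10),
                          encoding = EncodingConfig(totalRate = 1e5,
                                                    totalSpikes = 2000L)) {
  n <- ncol(network@weights@bits)
  size <- as.integer(sqrt(nrow(network@weights@bits)))
  rates <- matrix(0, n, length(angles))
  for (i in seq_along(angles)) {
    img <- orientedBarImage(angles[i], size = size)
    s <- poissonEncode(img, encoding)
    durS <- if (!is.na(encoding@totalSpikes))
      encoding@totalSpikes / encoding@totalRate else encoding@durationUs / 1e6
    res <- runNetwork(network, s, learn = FALSE, wta = FALSE,
                      adaptThresholds = FALSE)
    rates[, i] <- res$spikeCounts / durS
  }
  new("TuningCurve", angles = angles, rates = rates)
}

#' Preferred orientations of a tuning curve
#'
#' Maps each neuron to the trained orientation nearest (modulo 180
#' degrees) to its tuning-curve argmax.
#'
#' @param curve a [TuningCurve-class].
#' @param trained the trained orientations in degrees.
#' @return integer vector: index into \code{trained} per neuron.
#' @export
preferredOrientations <- function(curve, trained = c(0, 45, 90, 135)) {
  peaks <- curve@angles[apply(curve@rates, 1, which.max)]
  vapply(peaks, function(a) {
    d <- abs(a - trained) %% 180
    which.min(pmin(d, 180 - d))
  }, integer(1))
}

#' Confidence interval of a test error rate
#'
#' Binomial-approximation confidence interval
#' \eqn{\hat\mu \pm z^* \sqrt{\hat\mu(1-\hat\mu)/N_T}} for the mean test
#' error, assuming independent test samples. For the 0.99 confidence level
#' \eqn{z^* = 2.578}; other levels use the normal quantile.
#'
#' @param errorRate estimated test error in [0, 1].
#' @param nTest test-set size (>= 1).
#' @param confidence confidence level (default 0.99).
#' @return named numeric: \code{low}, \code{high}, \code{halfWidth}.
#' @examples
#' confidenceInterval(0.5, 100)   # half-width 2.578 * 0.05 = 0.1289
#' @export
confidenceInterval <- function(errorRate, nTest, confidence = 0.99) {
  if (errorRate < 0 || errorRate > 1) stop("errorRate must lie in [0, 1]")
  if (nTest < 1) stop("nTest must be >= 1")
  z <- if (identical(confidence, 0.99)) 2.578 else
    stats::qnorm(1 - (1 - confidence) / 2)
  hw <- z * sqrt(errorRate * (1 - errorRate) / nTest)
  c(low = max(0, errorRate - hw), high = min(1, errorRate + hw),
    halfWidth = hw)
}

## run a frozen network over one sample and return FE spike addresses
.feResponse <- function(network, stream, leakOn = TRUE) {
  res <- runNetwork(network, stream, learn = FALSE, wta = FALSE,
                    adaptThresholds = FALSE, leakOn = leakOn,
                    recordSpikes = TRUE)
  res
}

#' Run the two-layer feature-extraction + classifier pipeline
#'
#' Trains the 1-bit FE layer by stochastic STDP in a single pass over the
#' training samples (or draws fixed random weights with the same
#' \eqn{W_{sum}} for the baseline), freezes weights and thresholds,
#' disables the lateral inhibition, and trains the requested output
#' classifier on the frozen FE responses. Reports train/test accuracy with
#' binomial confidence intervals.
#'
#' @param trainStreams,trainLabels,testStreams,testLabels the dataset:
#'   lists of [EventStream-class] samples and 1-based class labels.
#' @param nFe number of FE neurons.
#' @param wSum FE popcount budget.
#' @param neuronConfig,stdpConfig,leak model parameters.
#' @param feMode "stdp" (train by STDP) or "random" (fixed random weights
#'   with enforced \eqn{W_{sum}}).
#' @param classifier "simple" (teacher-driven STDP classifier) or
#'   "softmax" (histogram/SGD classifier converted to spiking neurons).
#' @param k conversion constant for the softmax classifier.
#' @param seed RNG seed.
#' @return list with \code{trainAccuracy}, \code{testAccuracy},
#'   \code{ci} (0.99 CI of the test error), \code{network},
#'   \code{predictions}.
#' @export
runFePipeline <- function(trainStreams, trainLabels, testStreams,
                          testLabels, nFe = 32, wSum = 32,
                          neuronConfig = NeuronConfig(xThInit = 10,
                                                      xThMax = 60),
                          stdpConfig = StdpConfig(pLtp = 0.8,
                                                  bufferSize = 250),
                          leak = fitLeakSchedule(12000),
                          feMode = c("stdp", "random"),
                          classifier = c("simple", "softmax"),
                          k = 1000, seed = 1) {
  feMode <- match.arg(feMode)
  classifier <- match.arg(classifier)
  if (!length(trainStreams)) stop("empty training set")
  if (length(unique(trainLabels)) < 2L) stop("single-class dataset")
  set.seed(seed)
  nInput <- trainStreams[[1]]@addressSpace
  nClasses <- max(trainLabels)
  net <- FeNetwork(randomBinaryWeights(nInput, nFe, wSum),
                   neuronConfig = neuronConfig, stdpConfig = stdpConfig,
                   leak = leak)
  if (feMode == "stdp") {
    ## one pass of unsupervised learning; counters reset between samples
    for (s in trainStreams)
      net <- runNetwork(net, s, learn = TRUE, wta = TRUE,
                        adaptThresholds = TRUE)$network
  }
  ## frozen responses
  respond <- function(streams)
    lapply(streams, function(s) .feResponse(net, s))
  trainResp <- respond(trainStreams)
  testResp <- respond(testStreams)
  if (classifier == "simple") {
    clf <- SimpleClassifier(nFe, nClasses)
    for (i in seq_along(trainResp)) {
      spikes <- trainResp[[i]]$spikes$neuron - 1L
      if (length(spikes)) {
        clf <- bufferFeature(clf, spikes)
        clf <- simpleClassifierUpdate(clf, trainLabels[i])
      }
    }
    predictOne <- function(r) simpleClassifierPredict(clf, r$spikeCounts)
  } else {
    featMat <- function(resp) t(vapply(resp, function(r)
      histogramFeatures(r$spikes$neuron - 1L, nFe), numeric(nFe)))
    Xtr <- featMat(trainResp)
    fit <- trainSoftmaxSgd(Xtr, trainLabels, nClasses, seed = seed)
    snn <- convertToSnn(fit$weights, k)
    clf <- snn
    predictOne <- function(r) {
      addr <- r$spikes$neuron - 1L
      if (!length(addr)) return(1L)
      suppressWarnings(snnClassify(snn, addr))
    }
  }
  predTrain <- vapply(trainResp, predictOne, integer(1))
  predTest <- vapply(testResp, predictOne, integer(1))
  testAcc <- mean(predTest == testLabels)
  list(trainAccuracy = mean(predTrain == trainLabels),
       testAccuracy = testAcc,
       ci = confidenceInterval(1 - testAcc, length(testLabels)),
       network = net, classifier = clf, predictions = predTest)
}

#' Grid search of the STDP hyperparameters
#'
#' Evaluates every grid point on the validation split, retrains the winner
#' on the merged training + validation data and scores the test set
#' exactly once (the returned \code{testEvaluations} counter documents the
#' leakage guard).
#'
#' @param grid data.frame with columns among \code{wSum}, \code{xThMax},
#'   \code{bufferSize}, \code{pLtp}, \code{nFe}.
#' @param trainStreams,trainLabels,valStreams,valLabels,testStreams,testLabels
#'   the three splits.
#' @param ... further arguments passed to [runFePipeline()].
#' @param seed RNG seed.
#' @return list with \code{best} (winning row), \code{validationScores},
#'   \code{testAccuracy}, \code{testEvaluations} (always 1), \code{report}
#'   (the winner's full pipeline report).
#' @export
hyperparamSearch <- function(grid, trainStreams, trainLabels, valStreams,
                             valLabels, testStreams, testLabels, ...,
                             seed = 1) {
  if (!nrow(grid)) stop("empty hyperparameter grid")
  if (!length(valStreams)) stop("empty validation split")
  args <- list(...)
  runPoint <- function(row, trS, trL, teS, teL) {
    a <- c(list(trainStreams = trS, trainLabels = trL, testStreams = teS,
                testLabels = teL, seed = seed), args)
    for (nm in intersect(names(row), c("nFe", "wSum")))
      a[[nm]] <- row[[nm]]
    if ("xThMax" %in% names(row))
      a$neuronConfig <- NeuronConfig(xThInit = 10, xThMax = row$xThMax)
    if (any(c("bufferSize", "pLtp") %in% names(row)))
      a$stdpConfig <- StdpConfig(
        pLtp = if ("pLtp" %in% names(row)) row$pLtp else 0.8,
        bufferSize = if ("bufferSize" %in% names(row)) row$bufferSize
                     else 250)
    do.call(runFePipeline, a)
  }
  scores <- vapply(seq_len(nrow(grid)), function(i)
    runPoint(grid[i, , drop = FALSE], trainStreams, trainLabels,
             valStreams, valLabels)$testAccuracy, numeric(1))
  best <- which.max(scores)
  testEvaluations <- 0L
  report <- runPoint(grid[best, , drop = FALSE],
                     c(trainStreams, valStreams),
                     c(trainLabels, valLabels),
                     testStreams, testLabels)
  testEvaluations <- testEvaluations + 1L
  list(best = grid[best, , drop = FALSE], validationScores = scores,
       testAccuracy = report$testAccuracy,
       testEvaluations = testEvaluations, report = report)
}

#' Export a receptive field as a PGM image
#'
#' Renders one neuron's 1-bit weight column as a plain-text (P2) PGM for
#' visual inspection.
#'
#' @param weights a [BinaryWeights-class].
#' @param neuronIndex 1-based neuron index.
#' @param path output file.
#' @param size image side length (default \code{sqrt(nPre)}).
#' @return \code{path}, invisibly.
#' @export
writeReceptiveFieldPgm <- function(weights, neuronIndex, path,
                                   size = as.integer(sqrt(nrow(weights@bits)))) {
  bits <- matrix(weights@bits[, neuronIndex], size, size, byrow = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(size, size), "1"), con)
  writeLines(apply(bits, 1, paste, collapse = " "), con)
  invisible(path)
}
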