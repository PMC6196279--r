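test_that("simple classifier conserves column budgets and learns a feature", {
  clf <- SimpleClassifier(8, 3, wSumTarget = 32, learnRate = 4)
  expect_equal(simpleClassifierUpdate(clf, 2), clf)   # empty buffer: no-op

  set.seed(20)
  for (i in 1:20) {
    clf <- bufferFeature(clf, sample(0:7, 5, TRUE))
    clf <- simpleClassifierUpdate(clf, sample(3, 1))
    expect_equal(unname(colSums(clf@weights)), rep(32, 3))
  }

  ## a single feature repeatedly paired with one class dominates its column
  clf <- SimpleClassifier(8, 3, wSumTarget = 32, learnRate = 4)
  w_hist <- numeric(100)
  for (i in 1:100) {
    clf <- bufferFeature(clf, 5L)
    clf <- simpleClassifierUpdate(clf, 2)
    w_hist[i] <- clf@weights[6, 2]
  }
  expect_true(all(diff(w_hist) >= 0))        # monotone until budget-limited
  expect_gt(w_hist[100], 3 * w_hist[1])      # dominates its class column
  expect_lte(w_hist[100], 32)                # never exceeds the budget
  expect_equal(simpleClassifierPredict(clf, tabulate(6, 8)), 2)
})

test_that("histograms are L1-normalized, order-free and zero-safe", {
  h <- histogramFeatures(c(0L, 0L, 1L, 2L), 3)
  expect_equal(h, c(0.5, 0.25, 0.25))
  expect_equal(histogramFeatures(integer(0), 4), rep(0, 4))
  set.seed(21)
  a <- sample(0:9, 200, TRUE)
  expect_equal(histogramFeatures(a, 10), histogramFeatures(sample(a), 10))
  expect_error(histogramFeatures(5L, 4), "exceeds")
})

test_that("softmax SGD separates Gaussian clusters and is seed-deterministic", {
  set.seed(22)
  n <- 60
  X <- rbind(matrix(rnorm(n * 4, 2), n, 4), matrix(rnorm(n * 4, -2), n, 4))
  y <- rep(1:2, each = n)
  fit <- trainSoftmaxSgd(X, y, 2, seed = 7)
  expect_equal(mean(softmaxPredict(fit$weights, X) == y), 1)
  fit2 <- trainSoftmaxSgd(X, y, 2, seed = 7)
  expect_identical(fit$weights, fit2$weights)

  ## label permutation: accuracy near chance
  set.seed(23)
  yPerm <- sample(y)
  fitP <- trainSoftmaxSgd(X, yPerm, 2, seed = 7)
  accP <- mean(softmaxPredict(fitP$weights, X) == yPerm)
  sigma <- sqrt(0.5 * 0.5 / (2 * n))
  expect_lt(accP, 0.5 + 5 * sigma + 0.15)   # generous: training acc > chance

  expect_error(trainSoftmaxSgd(X, rep(1L, nrow(X)), 2), "2 classes")
})

test_that("softmax SGD agrees with an independent multinomial fit", {
  skip_if_not_installed("nnet")
  set.seed(24)
  n <- 50
  X <- rbind(matrix(rnorm(n * 3, 1.5), n, 3),
             matrix(rnorm(n * 3, -1.5), n, 3),
             cbind(rnorm(n, 3), rnorm(n, -3), rnorm(n)))
  y <- rep(1:3, each = n)
  fit <- trainSoftmaxSgd(X, y, 3, seed = 7)
  ours <- mean(softmaxPredict(fit$weights, X) == y)
  ref <- nnet::multinom(factor(y) ~ X, trace = FALSE)
  theirs <- mean(predict(ref) == factor(y))
  expect_gte(ours, theirs - 0.05)
})

test_that("conversion to spiking neurons preserves the frame-domain argmax", {
  set.seed(25)
  W <- matrix(rnorm(12), 4, 3)
  snn <- convertToSnn(W, 1000)
  expect_equal(snn@threshold, 1000)
  expect_true(all(snn@weights >= 0))
  expect_error(convertToSnn(W, 0), "positive")

  ## doubling k leaves the frame-domain argmax unchanged
  h <- abs(rnorm(4)); h <- h / sum(h)
  off <- W - min(W)
  expect_equal(which.max(h %*% off), which.max(h %*% (2 * off)))

  ## spike-count argmax agrees with frame-domain argmax at high rate
  agree <- 0
  for (i in 1:50) {
    h <- runif(4)^2; h <- h / sum(h)
    addr <- sample.int(4, 4000, TRUE, prob = h) - 1L
    frame <- which.max(histogramFeatures(addr, 4) %*% (W - min(W)))
    expect_warning(regexp = NA,
                   spike <- snnClassify(snn, addr))
    agree <- agree + (frame == spike)
  }
  expect_gte(agree / 50, 0.9)
})

test_that("snnClassify handles degenerate input with a warning", {
  snn <- convertToSnn(matrix(c(0, 1, 1, 0), 2, 2), 10)
  expect_warning(cl <- snnClassify(snn, integer(0), defaultClass = 2L),
                 "default")
  expect_equal(cl, 2L)
  ## features driving only class-2 weights select class 2
  W <- matrix(0, 3, 3); W[2, 2] <- 1
  snn2 <- convertToSnn(W, 5)
  expect_equal(snnClassify(snn2, rep(1L, 50)), 2L)
})
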