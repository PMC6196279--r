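test_that("confidence intervals follow the binomial expression", {
  ci <- confidenceInterval(0, 50)
  expect_equal(unname(ci["halfWidth"]), 0)
  ci <- confidenceInterval(0.5, 100, 0.99)
  expect_equal(unname(ci["halfWidth"]), 0.1289, tolerance = 1e-6)
  ## width strictly decreases with n
  w <- vapply(c(10, 50, 100, 1000), function(n)
    unname(confidenceInterval(0.3, n)["halfWidth"]), numeric(1))
  expect_true(all(diff(w) < 0))
  expect_error(confidenceInterval(1.2, 10), "\\[0, 1\\]")
  expect_error(confidenceInterval(0.2, 0), "nTest")
})

test_that("a short orientation run keeps the budget and is reproducible", {
  cfg <- orientationConfig(epochs = 40)
  net1 <- runOrientationTraining(cfg, seed = 5)
  expect_equal(unname(popcounts(net1@weights)), rep(180, 4))
  expect_true(all(net1@firingThresholds <= 100))
  expect_true(all(net1@firingThresholds >= 10))
  net2 <- runOrientationTraining(cfg, seed = 5)
  expect_identical(weightBits(net1@weights), weightBits(net2@weights))
  expect_identical(net1@firingThresholds, net2@firingThresholds)
})

test_that("trained neurons peak at or adjacent to their orientation", {
  cfg <- orientationConfig(epochs = 150)
  net <- runOrientationTraining(cfg, seed = 2)
  tc <- measureTuning(net)
  expect_true(all(tc@rates >= 0))
  pref <- preferredOrientations(tc, cfg$orientations)
  ## each neuron maps to a distinct trained orientation...
  expect_equal(sort(pref), 1:4)
  ## ...and its peak lies within one 10-degree step of it (the diagonal
  ## orientations sit off the probe grid, so "adjacent" means <= 15 deg)
  peaks <- tc@angles[apply(tc@rates, 1, which.max)]
  for (j in 1:4) {
    d <- abs(peaks[j] - cfg$orientations[pref[j]]) %% 180
    expect_lte(min(d, 180 - d), 15)
  }
})

test_that("untrained random networks lack consistent 4-way coverage", {
  cfg <- orientationConfig()
  covered <- vapply(1:4, function(seed) {
    set.seed(seed)
    net <- FeNetwork(randomBinaryWeights(1024, 4, 180),
                     neuronConfig = cfg$neuron, stdpConfig = cfg$stdp,
                     leak = cfg$leak,
                     firingThresholds = rep(100, 4))
    tc <- measureTuning(net)
    length(unique(preferredOrientations(tc, cfg$orientations)))
  }, integer(1))
  expect_lt(mean(covered), 4)
})

test_that("the pipeline trains, evaluates and reports confidence intervals", {
  d <- tinySymbolSplit(nPerClass = 6)
  rep <- runFePipeline(d$trS, d$trL, d$teS, d$teL, nFe = 8, wSum = 24,
                       classifier = "simple", seed = 3)
  expect_true(rep$testAccuracy >= 0 && rep$testAccuracy <= 1)
  expect_true(rep$trainAccuracy >= 0 && rep$trainAccuracy <= 1)
  expect_equal(unname(popcounts(rep$network@weights)), rep(24, 8))
  expect_named(rep$ci, c("low", "high", "halfWidth"))
  expect_error(runFePipeline(list(), integer(0), d$teS, d$teL),
               "empty training set")
  expect_error(runFePipeline(d$trS, rep(1L, length(d$trS)), d$teS, d$teL),
               "single-class")
})

test_that("hyperparameter search honors the argmax contract and test-once rule", {
  d <- tinySymbolSplit(nPerClass = 6)
  nVal <- 8
  res <- hyperparamSearch(
    data.frame(wSum = c(16, 32)),
    d$trS[-(1:nVal)], d$trL[-(1:nVal)],
    d$trS[1:nVal], d$trL[1:nVal],
    d$teS, d$teL, nFe = 8, classifier = "simple", seed = 4)
  expect_equal(res$testEvaluations, 1L)
  expect_gte(max(res$validationScores),
             res$validationScores[which.max(res$validationScores)])
  expect_equal(res$best$wSum,
               c(16, 32)[which.max(res$validationScores)])
  expect_error(hyperparamSearch(data.frame(), d$trS, d$trL, d$trS, d$trL,
                                d$teS, d$teL), "empty hyperparameter grid")
})

test_that("receptive fields export as valid plain PGM", {
  set.seed(35)
  w <- randomBinaryWeights(16, 2, 5)
  f <- withr::local_tempfile(fileext = ".pgm")
  writeReceptiveFieldPgm(w, 1, f, size = 4L)
  lines <- readLines(f)
  expect_equal(lines[1], "P2")
  expect_equal(lines[2], "4 4")
  vals <- as.integer(unlist(strsplit(paste(lines[-(1:3)], collapse = " "),
                                     " +")))
  expect_equal(sum(vals), 5L)
})
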