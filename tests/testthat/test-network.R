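test_that("compiled event loop matches the single-neuron R path", {
  set.seed(16)
  sch <- fitLeakSchedule(8000)
  cfg <- NeuronConfig(xThInit = 5, xThMax = 12, thIncrement = 1)
  bits <- as.integer(runif(32) < 0.4)
  s <- randomStream(400, 32, maxGapUs = 800)

  ## R reference: one neuron driven event by event
  st <- NeuronState(cfg)
  fires <- 0
  for (i in seq_len(nEvents(s))) {
    r <- processInputEvent(st, bits[eventAddresses(s)[i] + 1L],
                           eventTimes(s)[i], cfg, sch)
    st <- r$state
    fires <- fires + r$fired
  }

  net <- FeNetwork(BinaryWeights(matrix(bits, ncol = 1), sum(bits)),
                   neuronConfig = cfg, leak = sch)
  res <- runNetwork(net, s, learn = FALSE, wta = FALSE,
                    adaptThresholds = TRUE)
  expect_equal(res$spikeCounts, fires)
  expect_equal(res$network@firingThresholds, st@firingThreshold)
})

test_that("winner-take-all emits at most one spike per input event", {
  set.seed(17)
  net <- FeNetwork(randomBinaryWeights(64, 6, 20),
                   neuronConfig = NeuronConfig(xThInit = 3, xThMax = 30),
                   stdpConfig = StdpConfig(pLtp = 0.8, bufferSize = 50))
  s <- EventStream(timestamps = seq_len(500),     # distinct timestamps
                   addresses = sample(0:63, 500, TRUE),
                   addressSpace = 64L)
  res <- runNetwork(net, s, learn = TRUE, wta = TRUE,
                    adaptThresholds = TRUE, recordSpikes = TRUE)
  expect_lte(max(table(res$spikes$time)), 1L)
  ## bit-domain invariants after a learning run
  W <- weightBits(res$network@weights)
  expect_true(all(W %in% c(0L, 1L)))
  expect_equal(unname(popcounts(res$network@weights)), rep(20, 6))
  expect_true(all(res$network@firingThresholds <= 30))
})

test_that("training runs are bitwise reproducible per seed", {
  run <- function() {
    set.seed(18)
    net <- FeNetwork(randomBinaryWeights(64, 4, 16),
                     stdpConfig = StdpConfig(pLtp = 0.6, bufferSize = 40))
    s <- randomStream(800, 64, maxGapUs = 20)
    runNetwork(net, s, learn = TRUE, wta = TRUE, adaptThresholds = TRUE)
  }
  a <- run(); b <- run()
  expect_identical(weightBits(a$network@weights),
                   weightBits(b$network@weights))
  expect_identical(a$network@firingThresholds, b$network@firingThresholds)
  expect_identical(a$spikeCounts, b$spikeCounts)
})

test_that("evaluation leaves weights and thresholds untouched", {
  set.seed(19)
  net <- FeNetwork(randomBinaryWeights(64, 4, 16))
  s <- randomStream(500, 64, maxGapUs = 20)
  res <- runNetwork(net, s, learn = FALSE, wta = FALSE,
                    adaptThresholds = FALSE)
  expect_identical(weightBits(res$network@weights),
                   weightBits(net@weights))
  expect_identical(res$network@firingThresholds, net@firingThresholds)
  expect_identical(res$network@stdpThresholds, net@stdpThresholds)
})

test_that("address-space mismatch is rejected", {
  net <- FeNetwork(randomBinaryWeights(16, 2, 4))
  s <- randomStream(10, 32)
  expect_error(runNetwork(net, s), "address space")
})
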