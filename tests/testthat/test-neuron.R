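test_that("leak schedule tracks the target exponential within its recorded error", {
  sch <- fitLeakSchedule(12000)   # tau = 12 ms
  tt <- seq(0, 60000, by = 500)   # every 0.5 ms over 60 ms
  exact <- 100 * exp(-tt / 12000)
  approxed <- pmax(0, 100 - leakAmount(sch, tt))
  dev <- max(abs(approxed - exact))
  expect_lte(dev, sch@fitError + 1e-8)
  expect_lt(sch@fitError, 10)     # within 10% of the reference state
})

test_that("applyLeak is lazy, clamps at zero and enforces time order", {
  sch <- fitLeakSchedule(12000)
  st <- NeuronState(NeuronConfig())
  st@firingCounter <- 42; st@learningCounter <- 17; st@lastUpdate <- 1000
  expect_equal(applyLeak(st, 1000, sch), st)          # elapsed 0: identity
  far <- applyLeak(st, 1000 + 5 * 12000, sch)         # >> all breakpoints
  expect_equal(far@firingCounter, 0)
  expect_equal(far@learningCounter, 0)
  expect_error(applyLeak(st, 999, sch), "temporal ordering")
})

test_that("input events increment, fire at threshold, reset and adapt", {
  cfg <- NeuronConfig(xThInit = 3, xThMax = 5, thIncrement = 1)
  st <- NeuronState(cfg)

  r <- processInputEvent(st, 0, 10, cfg)
  expect_false(r$fired)
  expect_equal(r$state@firingCounter, 0)              # weight 0: unchanged

  st@firingCounter <- 2; st@learningCounter <- 2      # threshold - 1
  r <- processInputEvent(st, 1, 10, cfg)
  expect_true(r$fired)
  expect_true(r$stdpTriggered)                        # single-threshold mode
  expect_equal(r$state@firingCounter, 0)              # reset on fire
  expect_equal(r$state@firingThreshold, 4)            # grew by 1

  ## threshold saturates at the ceiling
  for (i in 1:20) {
    st2 <- r$state; st2@firingCounter <- st2@firingThreshold - 1
    r <- processInputEvent(st2, 1, 10 + i, cfg)
  }
  expect_equal(r$state@firingThreshold, 5)
})

test_that("dual-threshold mode decouples firing and STDP triggers", {
  cfg <- NeuronConfig(xThInit = 5, xThMax = 10, dualThreshold = TRUE,
                      stdpThInit = 3)
  st <- NeuronState(cfg)
  st@firingCounter <- 1; st@learningCounter <- 2
  r <- processInputEvent(st, 1, 0, cfg)
  expect_false(r$fired)                # 2 < 5
  expect_true(r$stdpTriggered)         # 3 >= 3
  expect_equal(r$state@stdpThreshold, 4)
  expect_equal(r$state@learningCounter, 0)
})

test_that("inhibit zeroes counters only and is idempotent", {
  st <- NeuronState(NeuronConfig(xThInit = 7))
  st@firingCounter <- 5; st@learningCounter <- 3
  r <- inhibit(st)
  expect_equal(r@firingCounter, 0)
  expect_equal(r@learningCounter, 0)
  expect_equal(r@firingThreshold, st@firingThreshold)
  expect_equal(r@stdpThreshold, st@stdpThreshold)
  expect_equal(inhibit(r), r)
})

test_that("counters stay non-negative under random operation sequences", {
  set.seed(8)
  sch <- fitLeakSchedule(5000)
  cfg <- NeuronConfig(xThInit = 4, xThMax = 9)
  st <- NeuronState(cfg)
  now <- 0
  for (i in 1:300) {
    op <- sample(3, 1)
    now <- now + sample(0:3000, 1)
    if (op == 1) st <- processInputEvent(st, sample(0:1, 1), now, cfg,
                                         sch)$state
    else if (op == 2) st <- applyLeak(st, now, sch)
    else st <- inhibit(st)
    expect_gte(st@firingCounter, 0)
    expect_gte(st@learningCounter, 0)
    expect_lte(st@firingThreshold, cfg@xThMax)
  }
})

test_that("with leak off and all weights 1 a neuron fires floor(N/T) times", {
  for (T in c(3, 7, 10)) {
    N <- 50
    cfg <- NeuronConfig(xThInit = T, xThMax = 1000, thIncrement = 0)
    ## single-neuron R path
    st <- NeuronState(cfg)
    fires <- 0
    for (i in seq_len(N)) {
      r <- processInputEvent(st, 1, i, cfg)
      st <- r$state
      fires <- fires + r$fired
    }
    expect_equal(fires, floor(N / T))
    ## network (compiled) path agrees
    net <- FeNetwork(BinaryWeights(matrix(1L, 1, 1), 1L),
                     neuronConfig = cfg)
    s <- EventStream(seq_len(N), rep(0L, N), addressSpace = 1L)
    res <- runNetwork(net, s, learn = FALSE, wta = FALSE,
                      adaptThresholds = FALSE, leakOn = FALSE)
    expect_equal(res$spikeCounts, floor(N / T))
  }
})
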