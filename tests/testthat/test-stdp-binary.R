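test_that("stochasticBitUpdate follows the signed-probability rule", {
  expect_equal(stochasticBitUpdate(0L, 0.8, 0.5), 1L)
  expect_equal(stochasticBitUpdate(1L, -0.25, 0.5), 1L)   # u > |p|
  expect_equal(stochasticBitUpdate(1L, -0.25, 0.1), 0L)
  expect_equal(stochasticBitUpdate(1L, 0.9, 0.1), 1L)     # idempotent set
  expect_error(stochasticBitUpdate(0L, 1.5, 0.5), "\\[-1, 1\\]")

  set.seed(9)
  u <- runif(1e5)
  frac <- mean(stochasticBitUpdate(rep(0L, 1e5), 0.3, u))
  sigma <- sqrt(0.3 * 0.7 / 1e5)
  expect_lt(abs(frac - 0.3), 3 * sigma)
})

test_that("ltdProbability1024 implements the 10-bit normalized formula", {
  expect_equal(ltdProbability1024(180, 180), 0L)
  expect_equal(ltdProbability1024(150, 180), 0L)   # below target: no LTD
  expect_equal(ltdProbability1024(37, 0), 1024L)
  expect_equal(ltdProbability1024(200, 180), 102L)
  expect_equal(ltdProbability1024(100, 50), 512L)
})

test_that("deterministic updates restore the popcount budget exactly", {
  set.seed(10)
  cfg <- StdpConfig(pLtp = 1, bufferSize = 16, normalization = "deterministic")
  ## 16-synapse toy, z zero-bits in the buffer
  bits <- rep(0L, 16); bits[1:6] <- 1L
  w <- BinaryWeights(matrix(bits, ncol = 1), 6L)
  buf <- PreBuffer(16, c(7L, 8L, 9L))         # 3 zero bits, pLtp = 1
  w2 <- suppressMessages(applyBinaryStdp(w, 1, buf, cfg))
  expect_equal(sum(weightBits(w2)), 6)        # budget restored
  expect_equal(weightBits(w2)[8:10], rep(1L, 3))  # buffered set, protected
  expect_equal(sum(weightBits(w2)[1:6]), 3)   # z = 3 depressions elsewhere

  ## no-op fixed point: buffer names already-active synapses at budget
  bufFix <- PreBuffer(16, c(0L, 1L))
  w3 <- applyBinaryStdp(w, 1, bufFix, cfg)
  expect_equal(weightBits(w3), weightBits(w))
})

test_that("popcount conservation holds for all seeds under deterministic mode", {
  cfg <- StdpConfig(pLtp = 0.7, bufferSize = 32)
  for (seed in 1:10) {
    set.seed(seed)
    w <- randomBinaryWeights(64, 3, 20)
    buf <- PreBuffer(32, sample(0:63, 25, TRUE))
    j <- sample(3, 1)
    w2 <- suppressMessages(applyBinaryStdp(w, j, buf, cfg))
    expect_true(all(weightBits(w2) %in% c(0L, 1L)))
    expect_equal(unname(popcounts(w2)), rep(20, 3))
  }
})

test_that("LTP never clears a bit and LTD never sets one", {
  cfg <- StdpConfig(pLtp = 0.5, bufferSize = 16,
                    normalization = "stochastic", protectBuffered = FALSE)
  for (seed in 1:10) {
    set.seed(seed)
    bits <- as.integer(runif(40) < 0.5)
    w <- BinaryWeights(matrix(bits, ncol = 1), 10L)
    buf <- PreBuffer(16, sample(0:39, 10, TRUE))
    w2 <- applyBinaryStdp(w, 1, buf, cfg)
    newBits <- weightBits(w2)[, 1]
    turnedOn <- which(newBits == 1L & bits == 0L)
    turnedOff <- which(newBits == 0L & bits == 1L)
    expect_true(all(turnedOn %in% (buf@entries + 1L)))   # only LTP sets
    expect_true(all(!(turnedOff %in% turnedOn)))
    expect_true(all(newBits %in% c(0L, 1L)))
  }
})

test_that("stochastic normalization drifts the popcount back to the budget", {
  set.seed(11)
  cfg <- StdpConfig(pLtp = 0, bufferSize = 4,
                    normalization = "stochastic")
  bits <- rep(0L, 256); bits[sample(256, 120)] <- 1L
  w <- BinaryWeights(matrix(bits, ncol = 1), 80L)
  emptyBuf <- PreBuffer(4)
  pops <- numeric(30)
  for (i in 1:30) {
    w <- applyBinaryStdp(w, 1, emptyBuf, cfg)
    pops[i] <- popcounts(w)[1]
  }
  expect_true(all(diff(pops) <= 0))       # supermartingale above the budget
  ## settles in a band around W_sum (one overshoot of the binomial LTD is
  ## possible, after which no further depression occurs)
  expect_lt(abs(pops[30] - 80), 12)
})

test_that("the pre-buffer is circular and flushable", {
  b <- PreBuffer(4)
  b <- pushPre(b, c(1L, 2L, 3L, 4L, 5L))
  expect_equal(b@entries, 2:5)            # oldest evicted
  b <- pushPre(b, 6L)
  expect_equal(b@entries, 3:6)
  expect_equal(flushBuffer(b)@entries, integer(0))
})

test_that("WTA resolution returns one winner with the configured policy", {
  expect_equal(wtaResolve(7), 7)
  expect_equal(wtaResolve(c(4, 2, 9)), 2)
  set.seed(12); a <- wtaResolve(c(4, 2, 9), "random")
  set.seed(12); b <- wtaResolve(c(4, 2, 9), "random")
  expect_equal(a, b)
  expect_error(wtaResolve(integer(0)), "empty")
})

test_that("deterministic LTD falls back to buffered synapses when starved", {
  set.seed(13)
  cfg <- StdpConfig(pLtp = 1, bufferSize = 32)
  bits <- rep(0L, 32)
  w <- BinaryWeights(matrix(bits, ncol = 1), 4L)
  buf <- PreBuffer(32, 0:19)              # LTP sets 20 bits, all protected
  expect_message(w2 <- applyBinaryStdp(w, 1, buf, cfg),
                 class = "bitsnnLtdFallback")
  expect_equal(unname(popcounts(w2)), 4)
})

test_that("LFSR-driven updates match float-path statistics on the 10-bit grid", {
  ## acceptance frequency of "sample < p1024" over the full period is
  ## p1024 / 1024 +- 1/65535 by construction; chi-square compares the two
  ## sources at several probability levels
  seqs <- lfsrSequence(Lfsr16(), 65535)
  set.seed(14)
  for (p1024 in c(102, 512, 819)) {
    hwFrac <- mean(seqs$sample < p1024)
    floatFrac <- mean(runif(65535) < p1024 / 1024)
    tab <- rbind(c(hwFrac, 1 - hwFrac), c(floatFrac, 1 - floatFrac)) * 65535
    pval <- suppressWarnings(chisq.test(round(tab))$p.value)
    expect_gt(pval, 0.01)
  }
})

test_that("hardware-emulation STDP obeys the budget with LFSR draws", {
  set.seed(15)
  w <- randomBinaryWeights(64, 2, 12)
  cfg <- StdpConfig(pLtp = 0.8, bufferSize = 16,
                    probabilityScale = "int1024")
  buf <- PreBuffer(16, sample(0:63, 10, TRUE))
  r <- applyBinaryStdpHw(w, 1, buf, cfg, Lfsr16(state = 321L))
  expect_s4_class(r$lfsr, "Lfsr16")
  expect_true(r$lfsr@state != 321L)
  expect_equal(unname(popcounts(r$weights)[1]), 12)
  expect_true(all(weightBits(r$weights) %in% c(0L, 1L)))
})
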