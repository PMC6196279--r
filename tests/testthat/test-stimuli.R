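test_that("axis-aligned bars have exact geometry and intensity range", {
  set.seed(26)
  img <- orientedBarImage(0)
  expect_equal(sum(img > 0), 8 * 24)
  expect_true(all(img[img > 0] >= 0.8 & img[img > 0] <= 1.0))
  ## 90 degrees is the transpose of the 0-degree image under the same draws
  set.seed(26); a <- orientedBarImage(0)
  set.seed(26); b <- orientedBarImage(90)
  expect_equal(b, t(a))
  ## diagonal bars keep roughly the same mass (nearest-neighbor raster)
  set.seed(26); d <- orientedBarImage(45)
  expect_gt(sum(d > 0), 0.8 * 192)
  expect_lt(sum(d > 0), 1.2 * 192)
  expect_error(orientedBarImage(0, size = 16, barLength = 24), "fit")
})

test_that("Poisson encoding keeps the population rate constant", {
  cfg <- EncodingConfig(totalRate = 10000, totalSpikes = 2000L)
  ## zero-intensity pixels never fire
  img <- matrix(0, 4, 4); img[1, 1] <- 1; img[4, 4] <- 0.5
  set.seed(27)
  s <- poissonEncode(img, cfg)
  expect_equal(nEvents(s), 2000L)
  expect_true(all(eventAddresses(s) %in% c(0L, 15L)))
  expect_error(poissonEncode(matrix(0, 2, 2), cfg), "all-zero")

  ## uniform image: per-pixel counts consistent with equal rates
  set.seed(28)
  counts <- numeric(16)
  for (i in 1:10) {
    s <- poissonEncode(matrix(1, 4, 4), cfg)
    counts <- counts + tabulate(eventAddresses(s) + 1L, 16)
  }
  pval <- chisq.test(counts)$p.value
  expect_gt(pval, 0.01)

  ## duration mode: total count within 3 sigma of rate * duration
  cfgD <- EncodingConfig(totalRate = 10000, totalSpikes = NA,
                         durationUs = 5e4)
  set.seed(29)
  tot <- replicate(100, nEvents(poissonEncode(matrix(1, 4, 4), cfgD)))
  lambda <- 10000 * 5e4 / 1e6
  expect_lt(abs(mean(tot) - lambda), 3 * sqrt(lambda / 100))
})

test_that("bar sequences count samples and space them by the IST", {
  set.seed(30)
  cfg <- EncodingConfig(totalRate = 1e5, totalSpikes = 50L, istUs = 7000)
  seqd <- barSequence(c(0, 45, 90, 135), epochs = 5, config = cfg)
  expect_length(seqd$labels, 20L)
  expect_equal(sort(unique(seqd$labels)), 1:4)
  expect_equal(as.vector(table(seqd$labels)), rep(5L, 4))
  ## consecutive sample windows are exactly IST apart
  gaps <- seqd$sampleStartUs[-1] - seqd$sampleEndUs[-20]
  expect_equal(gaps, rep(7000, 19))
  ## seeded reproducibility
  set.seed(30)
  seqd2 <- barSequence(c(0, 45, 90, 135), epochs = 5, config = cfg)
  expect_identical(seqd$stream@addresses, seqd2$stream@addresses)
  expect_identical(seqd$labels, seqd2$labels)
})

test_that("moving-symbol events are motion-driven and spatially confined", {
  ## stationary path: no motion, essentially no events
  still <- matrix(30, nrow = 100, ncol = 2)
  set.seed(31)
  s <- movingSymbolStream("diamond", eventRate = 50000, durationUs = 1e5,
                          fieldSize = 64, path = still)
  expect_equal(nEvents(s), 0L)

  ## events stay inside the trajectory envelope of the glyph
  set.seed(32)
  s <- movingSymbolStream("heart", eventRate = 50000, durationUs = 5e4,
                          fieldSize = 64, glyphScale = 2, wanderPx = 2)
  expect_gt(nEvents(s), 100)
  r <- eventAddresses(s) %/% 64; c <- eventAddresses(s) %% 64
  ctr <- (64 - 32) / 2
  expect_true(all(r >= ctr - 3 & r <= ctr + 32 + 3))
  expect_true(all(c >= ctr - 3 & c <= ctr + 32 + 3))

  ## reproducible per seed
  set.seed(33); a <- movingSymbolStream("club", 20000, 2e4, 64)
  set.seed(33); b <- movingSymbolStream("club", 20000, 2e4, 64)
  expect_identical(eventAddresses(a), eventAddresses(b))
  expect_error(movingSymbolStream("joker", 1000, 1e4), "unknown symbol")
})

test_that("IDX files round-trip and mismatched pairs are rejected", {
  set.seed(34)
  imgs <- lapply(1:3, function(i) matrix(runif(28 * 28), 28, 28))
  fImg <- withr::local_tempfile(fileext = ".idx3-ubyte")
  fLab <- withr::local_tempfile(fileext = ".idx1-ubyte")
  writeIdx(imgs, fImg)
  writeIdx(c(3L, 1L, 4L), fLab)
  d <- readIdxDataset(fImg, fLab)
  expect_length(d$images, 3L)
  expect_equal(d$labels, c(3L, 1L, 4L))
  expect_lte(max(vapply(d$images, max, numeric(1))), 1)
  expect_equal(d$images[[2]], imgs[[2]], tolerance = 1 / 255)

  writeIdx(c(1L, 2L), fLab)
  expect_error(readIdxDataset(fImg, fLab), "3 samples.*2")

  bad <- withr::local_tempfile()
  writeBin(as.raw(c(1, 2, 3, 4, 5)), bad)
  expect_error(readIdx(bad), "magic")
})
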