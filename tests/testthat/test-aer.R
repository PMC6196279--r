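test_that("AER-CSV parsing handles plain, empty and malformed files", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,5", "10,7"), f)
  s <- readAerCsv(f, addressSpace = 16)
  expect_equal(nEvents(s), 2L)
  expect_equal(eventAddresses(s), c(5L, 7L))
  expect_equal(eventTimes(s), c(0, 10))

  writeLines(character(0), f)
  expect_equal(nEvents(readAerCsv(f, 16)), 0L)

  writeLines(c("# comment", "timestamp_us,address", "0,5", "oops"), f)
  expect_error(readAerCsv(f, 16), "line 4")

  writeLines(c("0,5", "1,99"), f)
  expect_error(readAerCsv(f, 16), "address out of range at line 2")
})

test_that("out-of-order input errors under strictOrder and re-sorts otherwise", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("10,5", "0,7", "10,3"), f)
  expect_error(readAerCsv(f, 16), "non-decreasing")
  s <- readAerCsv(f, 16, strictOrder = FALSE)
  ## reference stable sort by timestamp
  ts <- c(10, 0, 10); ad <- c(5L, 7L, 3L); o <- order(ts)
  expect_equal(eventTimes(s), ts[o])
  expect_equal(eventAddresses(s), ad[o])
})

test_that("AER-CSV round-trips arbitrary valid streams", {
  set.seed(5)
  for (pol in c(FALSE, TRUE)) {
    s <- randomStream(1000, 64, polarity = pol)
    f <- withr::local_tempfile(fileext = ".csv")
    writeAerCsv(s, f)
    r <- readAerCsv(f, 64)
    expect_equal(eventTimes(r), eventTimes(s))
    expect_equal(eventAddresses(r), eventAddresses(s))
    expect_equal(eventPolarity(r), eventPolarity(s))
  }
  ## empty stream still produces a parseable file with a header
  f <- withr::local_tempfile(fileext = ".csv")
  writeAerCsv(EventStream(addressSpace = 8), f)
  expect_match(readLines(f)[1], "timestamp_us,address")
  expect_equal(nEvents(readAerCsv(f, 8)), 0L)
})

test_that("event-count slicing yields exact kesl-sized slices, remainder dropped", {
  set.seed(6)
  s <- randomStream(35000, 32)
  slices <- sliceByEventCount(s, 10000)
  expect_length(slices, 3L)
  expect_true(all(vapply(slices, nEvents, integer(1)) == 10000L))

  expect_length(sliceByEventCount(randomStream(9999, 8), 10000), 0L)
  expect_error(sliceByEventCount(s, 0), "positive")

  ## conservation: kesl * n + remainder == total, order preserved
  for (i in 1:5) {
    n <- sample(50:500, 1); k <- sample(7:60, 1)
    s <- randomStream(n, 16)
    sl <- sliceByEventCount(s, k)
    expect_equal(k * length(sl) + n %% k, n)
    if (length(sl))
      expect_equal(unlist(lapply(sl, eventAddresses)),
                   eventAddresses(s)[seq_len(k * length(sl))])
  }
})

test_that("address subsampling maps pixels by integer division", {
  set.seed(7)
  s <- EventStream(timestamps = c(0, 5, 9),
                   addresses = c(7L * 128L + 9L, 0L, 127L * 128L + 127L),
                   addressSpace = 128L * 128L, geometry = c(128L, 128L))
  r <- subsampleAddresses(s, 4)
  expect_equal(addressSpace(r), 32L * 32L)
  expect_equal(geometry(r), c(32L, 32L))
  expect_equal(eventAddresses(r)[1], 1L * 32L + 2L)  # (7,9) -> (1,2)
  expect_equal(eventTimes(r), eventTimes(s))
  expect_equal(nEvents(r), nEvents(s))

  expect_identical(subsampleAddresses(s, 1), s)
  expect_error(subsampleAddresses(s, 5), "does not divide")
  bare <- EventStream(0, 1L, addressSpace = 16L)
  expect_error(subsampleAddresses(bare, 2), "geometry")
})

test_that("EventStream validity rejects bad objects", {
  expect_error(EventStream(c(1, 0), c(0L, 1L), addressSpace = 4),
               "non-decreasing")
  expect_error(EventStream(0, 4L, addressSpace = 4), "addressSpace")
  expect_error(EventStream(-1, 0L, addressSpace = 4), "non-negative")
})
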