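## shared test utilities

randomStream <- function(n, addressSpace, maxGapUs = 100,
                         polarity = FALSE) {
  EventStream(timestamps = cumsum(sample(0:maxGapUs, n, TRUE)),
              addresses = sample.int(addressSpace, n, TRUE) - 1L,
              addressSpace = addressSpace,
              polarity = if (polarity) sample(0:1, n, TRUE) else integer(0))
}

## Brute-force reference for one 1-bit STDP update, written directly from
## the rule (scalar loops, no shared code with the implementation). Fully
## determined by the injected draws.
refBinaryStdp <- function(bits, buffered, pLtp, target,
                          normalization = "deterministic",
                          protect = TRUE, scale = "float",
                          uLtp = numeric(0), ltdOrder = NULL,
                          uLtd = NULL) {
  p <- if (scale == "int1024") floor(pLtp * 1024) / 1024 else pLtp
  for (k in seq_along(buffered))
    if (uLtp[k] <= p) bits[buffered[k] + 1L] <- 1L
  prot <- if (protect) unique(buffered + 1L) else integer(0)
  excess <- sum(bits) - target
  if (excess > 0) {
    if (normalization == "deterministic") {
      victims <- integer(0)
      for (v in ltdOrder)
        if (bits[v] == 1L && !(v %in% prot)) victims <- c(victims, v)
      if (length(victims) < excess)
        for (v in ltdOrder)
          if (bits[v] == 1L && (v %in% prot)) victims <- c(victims, v)
      for (v in victims[seq_len(min(excess, length(victims)))])
        bits[v] <- 0L
    } else {
      p1024 <- floor(1024 * excess / sum(bits))
      i <- 0
      for (idx in seq_along(bits)) {
        if (bits[idx] == 1L && !(idx %in% prot)) {
          i <- i + 1
          if (uLtd[i] <= p1024 / 1024) bits[idx] <- 0L
        }
      }
    }
  }
  bits
}

## tiny pipeline dataset for the slower experiment tests
tinySymbolSplit <- function(nPerClass = 6, seed = 99) {
  set.seed(seed)
  d <- movingSymbolDataset(nPerClass = nPerClass, eventsPerSample = 600)
  idx <- sample(length(d$streams))
  nTr <- floor(0.7 * length(idx))
  list(trS = d$streams[idx[1:nTr]], trL = d$labels[idx[1:nTr]],
       teS = d$streams[idx[(nTr + 1):length(idx)]],
       teL = d$labels[idx[(nTr + 1):length(idx)]])
}
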