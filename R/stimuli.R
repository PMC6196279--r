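#' @include AllClasses.R aer.R
NULL

#' Oriented-bar test image
#'
#' A centered bar of the given thickness and length on a black background;
#' bar pixels have independent random intensities drawn from U[0.8, 1.0].
#' The base bar is horizontal (0 degrees); 90 degrees is the exact
#' transpose of the base image, other angles are produced by
#' nearest-neighbor rotation of the base about the image center (pixel
#' count may then deviate slightly from thickness x length).
#'
#' @param orientationDeg bar orientation in degrees (mod 180).
#' @param size image side length (pixels).
#' @param thickness,barLength bar dimensions in pixels.
#' @param low,high intensity range of the bar pixels.
#' @return numeric size x size matrix with values in [0, 1].
#' @examples
#' img <- orientedBarImage(0)
#' sum(img > 0)   # 8 * 24 = 192 bar pixels
#' @export
orientedBarImage <- function(orientationDeg, size = 32, thickness = 8,
                             barLength = 24, low = 0.8, high = 1.0) {
  if (thickness > size || barLength > size)
    stop("bar does not fit in a ", size, "x", size, " frame")
  ang <- orientationDeg %% 180
  base <- matrix(0, size, size)
  r0 <- (size - thickness) %/% 2
  c0 <- (size - barLength) %/% 2
  rows <- (r0 + 1):(r0 + thickness)
  cols <- (c0 + 1):(c0 + barLength)
  base[rows, cols] <- stats::runif(thickness * barLength, low, high)
  if (ang == 0) return(base)
  if (ang == 90) return(t(base))
  ## nearest-neighbor inverse rotation about the image center
  ctr <- (size + 1) / 2
  th <- ang * pi / 180
  out <- matrix(0, size, size)
  idx <- expand.grid(r = seq_len(size), c = seq_len(size))
  dr <- idx$r - ctr; dc <- idx$c - ctr
  sr <- round(cos(th) * dr - sin(th) * dc + ctr)
  sc <- round(sin(th) * dr + cos(th) * dc + ctr)
  ok <- sr >= 1 & sr <= size & sc >= 1 & sc <= size
  out[cbind(idx$r[ok], idx$c[ok])] <- base[cbind(sr[ok], sc[ok])]
  out
}

#' Poisson rate coding with constant population rate
#'
#' Converts a gray-scale image to a spike train: pixel i fires as a Poisson
#' process with rate \code{totalRate * I_i / sum(I)}, so the total firing
#' rate of the population is constant regardless of image brightness. With
#' \code{totalSpikes} set, exactly that many events are generated (the
#' population process conditioned on its total count: iid addresses with
#' probability proportional to intensity, order statistics of uniform
#' times); with \code{durationUs} set, the total count is Poisson.
#'
#' @param image numeric matrix with intensities in [0, 1]; at least one
#'   pixel must be nonzero.
#' @param config an [EncodingConfig-class].
#' @return an [EventStream-class] with row-major pixel addresses and the
#'   image geometry.
#' @export
poissonEncode <- function(image, config) {
  stopifnot(is(config, "EncodingConfig"))
  intens <- as.vector(t(image))       # row-major: address = r*cols + c
  if (all(intens == 0)) stop("all-zero image cannot be rate-coded")
  if (any(intens < 0)) stop("intensities must be non-negative")
  if (!is.na(config@totalSpikes)) {
    n <- config@totalSpikes
    durUs <- n / config@totalRate * 1e6
  } else {
    durUs <- config@durationUs
    n <- stats::rpois(1, config@totalRate * durUs / 1e6)
  }
  if (n == 0)
    return(EventStream(addressSpace = length(intens),
                       geometry = dim(image)))
  times <- floor(sort(stats::runif(n)) * durUs)
  addr <- sample.int(length(intens), n, replace = TRUE,
                     prob = intens) - 1L
  EventStream(timestamps = times, addresses = addr,
              addressSpace = length(intens), geometry = dim(image))
}

#' Training sequence of Poisson-encoded oriented bars
#'
#' Per epoch, the orientations are presented once each in random order;
#' every presentation uses a freshly drawn bar image. Successive samples
#' are separated by the inter-symbol time \code{istUs}, chosen so that all
#' neurons leak back to rest between samples.
#'
#' @param orientations bar angles in degrees.
#' @param epochs number of passes; each epoch presents every orientation
#'   once.
#' @param config an [EncodingConfig-class] (per-sample spike count or
#'   duration, total rate, IST).
#' @param size image side length.
#' @return list with \code{stream} (one concatenated
#'   [EventStream-class]), \code{labels} (orientation index per sample),
#'   \code{angles} (degrees per sample), \code{sampleStartUs} and
#'   \code{sampleEndUs} (sample time windows; consecutive windows are
#'   exactly \code{istUs} apart).
#' @export
barSequence <- function(orientations = c(0, 45, 90, 135), epochs = 1,
                        config = EncodingConfig(totalRate = 20000,
                                                totalSpikes = 200L),
                        size = 32) {
  nSamples <- epochs * length(orientations)
  streams <- vector("list", nSamples)
  labels <- integer(nSamples)
  starts <- ends <- numeric(nSamples)
  clock <- 0
  k <- 0
  for (ep in seq_len(epochs)) {
    for (o in sample(seq_along(orientations))) {
      k <- k + 1
      img <- orientedBarImage(orientations[o], size = size)
      s <- poissonEncode(img, config)
      dur <- if (!is.na(config@totalSpikes))
        config@totalSpikes / config@totalRate * 1e6 else config@durationUs
      streams[[k]] <- EventStream(timestamps = s@timestamps + clock,
                                  addresses = s@addresses,
                                  addressSpace = s@addressSpace,
                                  geometry = s@geometry)
      labels[k] <- o
      starts[k] <- clock
      ends[k] <- clock + dur
      clock <- clock + dur + config@istUs
    }
  }
  list(stream = concatStreams(streams), labels = labels,
       angles = orientations[labels], sampleStartUs = starts,
       sampleEndUs = ends)
}

## ---------------------------------------------------------------------------
## DVS-like moving-symbol surrogate
## ---------------------------------------------------------------------------

## 16x16 glyph masks built from coordinate predicates (centered grid)
.glyphMask <- function(symbol) {
  g <- expand.grid(r = 1:16, c = 1:16)
  dr <- g$r - 8.5; dc <- g$c - 8.5
  inside <- switch(symbol,
    diamond = abs(dr) + abs(dc) <= 7,
    heart = {
      lobes <- (dr + 3)^2 + (dc - 3)^2 <= 13 |
               (dr + 3)^2 + (dc + 3)^2 <= 13
      tri <- dr > -2 & dr <= 7 & abs(dc) <= (7 - dr) * 0.75
      lobes | tri
    },
    spade = {
      lobes <- (dr - 1)^2 + (dc - 3)^2 <= 10 |
               (dr - 1)^2 + (dc + 3)^2 <= 10
      tri <- dr <= 1 & dr >= -7 & abs(dc) <= (dr + 7) * 0.6
      stem <- dr > 1 & dr <= 7 & abs(dc) <= 1
      lobes | tri | stem
    },
    club = {
      circ <- (dr + 3)^2 + dc^2 <= 9 |
              (dr - 0.5)^2 + (dc - 3.5)^2 <= 9 |
              (dr - 0.5)^2 + (dc + 3.5)^2 <= 9
      stem <- dr > 2 & dr <= 7 & abs(dc) <= 1
      circ | stem
    },
    stop("unknown symbol '", symbol, "'"))
  matrix(inside, 16, 16)
}

## edge pixels: mask cells with at least one off-mask 4-neighbor
.edgePixels <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  pad <- matrix(FALSE, n + 2, m + 2)
  pad[2:(n + 1), 2:(m + 1)] <- mask
  core <- pad[2:(n + 1), 2:(m + 1)] &
    pad[1:n, 2:(m + 1)] & pad[3:(n + 2), 2:(m + 1)] &
    pad[2:(n + 1), 1:m] & pad[2:(n + 1), 3:(m + 2)]
  which(mask & !core, arr.ind = TRUE)
}

#' Synthetic DVS-like moving-symbol event stream
#'
#' A statistical stand-in for event-camera recordings of slowly moved
#' printed symbols: events are emitted from the edge pixels of a glyph
#' gliding along a smooth random path, with an emission probability
#' proportional to the instantaneous speed (an event camera responds to
#' contrast change, so a stationary symbol emits essentially nothing).
#' It reproduces the edge-driven, motion-dependent density of DVS data for
#' pipeline tests; it does not model sensor noise or latency.
#'
#' @param symbol one of \code{"heart"}, \code{"diamond"}, \code{"club"},
#'   \code{"spade"}.
#' @param eventRate candidate event rate (events/second) at reference
#'   speed.
#' @param durationUs recording length in microseconds.
#' @param fieldSize visual-field side length (default 128, as for a
#'   128 x 128 event camera).
#' @param path optional 2-column matrix of (row, col) glyph-center
#'   positions sampled every \code{stepUs}; NULL draws a smooth random
#'   walk confined near the field center.
#' @param stepUs path sampling period in microseconds.
#' @param refSpeed reference speed (pixels per ms) at which the full
#'   \code{eventRate} is emitted.
#' @param glyphScale integer pixel-replication factor of the 16 x 16
#'   glyph masks.
#' @param wanderPx half-width of the box around the field center within
#'   which the glyph center wanders (small values keep samples of a class
#'   spatially aligned).
#' @return an [EventStream-class] with geometry
#'   \code{c(fieldSize, fieldSize)}.
#' @export
movingSymbolStream <- function(symbol, eventRate = 20000,
                               durationUs = 1e5, fieldSize = 128,
                               path = NULL, stepUs = 1000,
                               refSpeed = 0.2, glyphScale = 1,
                               wanderPx = 2) {
  mask <- .glyphMask(symbol)
  if (glyphScale > 1)
    mask <- kronecker(mask, matrix(TRUE, glyphScale, glyphScale), "&")
  gs <- nrow(mask)
  edges <- .edgePixels(mask)
  nSteps <- max(2, ceiling(durationUs / stepUs))
  if (is.null(path)) {
    ctr <- (fieldSize - gs) / 2
    lo <- max(0, ctr - wanderPx); hi <- min(fieldSize - gs, ctr + wanderPx)
    if (hi < lo) stop("glyph does not fit the field")
    pos <- matrix(0, nSteps, 2)
    pos[1, ] <- stats::runif(2, lo, hi)
    vel <- stats::rnorm(2, 0, refSpeed * stepUs / 1000)
    for (i in 2:nSteps) {
      vel <- 0.9 * vel + stats::rnorm(2, 0, 0.5 * refSpeed * stepUs / 1000)
      p <- pos[i - 1, ] + vel
      ## reflect at the walls
      for (d in 1:2) {
        if (p[d] < lo) { p[d] <- 2 * lo - p[d]; vel[d] <- -vel[d] }
        if (p[d] > hi) { p[d] <- 2 * hi - p[d]; vel[d] <- -vel[d] }
      }
      pos[i, ] <- p
    }
    path <- pos
  } else {
    nSteps <- nrow(path)
  }
  speed <- sqrt(rowSums(rbind(c(0, 0), diff(path))^2)) / (stepUs / 1000)
  nCand <- stats::rpois(1, eventRate * durationUs / 1e6)
  if (nCand == 0)
    return(EventStream(addressSpace = fieldSize^2,
                       geometry = c(fieldSize, fieldSize)))
  times <- sort(stats::runif(nCand)) * durationUs
  stepIdx <- pmin(nSteps, floor(times / stepUs) + 1)
  keep <- stats::runif(nCand) <= pmin(1, speed[stepIdx] / refSpeed)
  times <- floor(times[keep]); stepIdx <- stepIdx[keep]
  n <- length(times)
  if (n == 0)
    return(EventStream(addressSpace = fieldSize^2,
                       geometry = c(fieldSize, fieldSize)))
  pick <- sample.int(nrow(edges), n, replace = TRUE)
  r <- pmin(fieldSize - 1, pmax(0, round(path[stepIdx, 1]) +
                                   edges[pick, 1] - 1))
  c <- pmin(fieldSize - 1, pmax(0, round(path[stepIdx, 2]) +
                                   edges[pick, 2] - 1))
  EventStream(timestamps = times, addresses = r * fieldSize + c,
              addressSpace = fieldSize^2,
              geometry = c(fieldSize, fieldSize))
}

#' Generate a labeled moving-symbol dataset
#'
#' One [movingSymbolStream()] recording per sample, cycling through the
#' four glyph classes. The default geometry keeps the task learnable at
#' small scale: a 32 x 32-pixel glyph wandering near the center of a
#' 64 x 64 field, subsampled to a 32 x 32 input grid, so that samples of
#' one class share most of their active contour pixels while the classes
#' differ in contour shape.
#'
#' @param nPerClass samples per glyph class.
#' @param eventsPerSample approximate events per sample (candidate rate is
#'   inflated so that after motion thinning roughly this many survive).
#' @param durationUs recording length per sample.
#' @param fieldSize,glyphScale field and glyph geometry, see
#'   [movingSymbolStream()].
#' @param subsampleFactor per-axis divisor applied via
#'   [subsampleAddresses()] (default 2: 64 -> 32).
#' @return list with \code{streams} (list of [EventStream-class]) and
#'   \code{labels} (1-based class per sample).
#' @export
movingSymbolDataset <- function(nPerClass = 50, eventsPerSample = 1500,
                                durationUs = 2e4, fieldSize = 64,
                                glyphScale = 2, subsampleFactor = 2) {
  symbols <- c("heart", "diamond", "club", "spade")
  n <- nPerClass * length(symbols)
  streams <- vector("list", n)
  labels <- integer(n)
  k <- 0
  for (cl in seq_along(symbols)) {
    for (i in seq_len(nPerClass)) {
      k <- k + 1
      ## thinning keeps roughly half the candidates at cruising speed
      s <- movingSymbolStream(symbols[cl],
                              eventRate = 2 * eventsPerSample * 1e6 /
                                durationUs,
                              durationUs = durationUs,
                              fieldSize = fieldSize,
                              glyphScale = glyphScale)
      if (subsampleFactor > 1) s <- subsampleAddresses(s, subsampleFactor)
      streams[[k]] <- s
      labels[k] <- cl
    }
  }
  list(streams = streams, labels = labels)
}
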