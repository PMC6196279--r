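#' @include AllClasses.R AllGenerics.R
NULL

#' Read an AER-CSV event stream
#'
#' The AER-CSV dialect is UTF-8 text with one event per line,
#' \code{timestamp_us,address[,polarity]}; an optional header line naming the
#' columns and \code{#}-prefixed comment lines are skipped. Addresses are
#' 0-based and must be smaller than the declared address space.
#'
#' @param path file to read.
#' @param addressSpace declared address-space size; addresses \code{>=}
#'   this value are rejected.
#' @param strictOrder if TRUE (default), out-of-order timestamps are an
#'   error; if FALSE the stream is stably re-sorted by timestamp.
#' @param geometry optional \code{c(rows, cols)} for pixel sources.
#' @return an [EventStream-class].
#' @seealso [writeAerCsv()]
#' @export
readAerCsv <- function(path, addressSpace, strictOrder = TRUE,
                       geometry = integer(0)) {
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (length(lines) && grepl("^\\s*timestamp", lines[1], ignore.case = TRUE)) {
    lines <- lines[-1]
    lineno <- lineno[-1]
  }
  if (!length(lines))
    return(EventStream(addressSpace = addressSpace, geometry = geometry))
  parts <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad))
    stop("malformed AER-CSV line ", lineno[bad[1]], ": '", lines[bad[1]], "'")
  ts <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  ad <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  bad <- which(is.na(ts) | is.na(ad))
  if (length(bad))
    stop("malformed AER-CSV line ", lineno[bad[1]], ": '", lines[bad[1]], "'")
  pol <- integer(0)
  if (all(nf == 3L)) {
    pol <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3L)))
    if (anyNA(pol))
      stop("malformed polarity field at line ",
           lineno[which(is.na(pol))[1]])
  } else if (any(nf == 3L)) {
    stop("mixed 2- and 3-column lines; first at line ",
         lineno[which(nf == 3L)[1]])
  }
  if (any(ad >= addressSpace | ad < 0L))
    stop("address out of range at line ",
         lineno[which(ad >= addressSpace | ad < 0L)[1]],
         " (address space ", addressSpace, ")")
  if (is.unsorted(ts)) {
    if (strictOrder)
      stop("timestamps are not non-decreasing (set strictOrder = FALSE ",
           "to re-sort)")
    o <- order(ts)            # stable: ties keep file order
    ts <- ts[o]; ad <- ad[o]
    if (length(pol)) pol <- pol[o]
  }
  EventStream(timestamps = ts, addresses = ad, addressSpace = addressSpace,
              polarity = pol, geometry = geometry)
}

#' Write an AER-CSV event stream
#'
#' Inverse of [readAerCsv()]: \code{readAerCsv(writeAerCsv(s), ...)}
#' round-trips the stream. A header line is always written; a third column
#' is present only when the stream carries polarity.
#'
#' @param stream an [EventStream-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeAerCsv <- function(stream, path) {
  stopifnot(is(stream, "EventStream"))
  hasPol <- length(stream@polarity) > 0L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(if (hasPol) "timestamp_us,address,polarity"
             else "timestamp_us,address", con)
  if (length(stream@timestamps)) {
    body <- if (hasPol)
      paste(format(stream@timestamps, scientific = FALSE, trim = TRUE),
            stream@addresses, stream@polarity, sep = ",")
    else
      paste(format(stream@timestamps, scientific = FALSE, trim = TRUE),
            stream@addresses, sep = ",")
    writeLines(body, con)
  }
  invisible(path)
}

#' Slice a stream into fixed-event-count samples
#'
#' Cuts the stream into consecutive slices of exactly \code{kesl} events
#' each (order preserved); a trailing remainder shorter than \code{kesl} is
#' dropped so that every slice has identical statistics.
#'
#' @param stream an [EventStream-class].
#' @param kesl events per slice (>= 1).
#' @return a list of [EventStream-class] slices.
#' @export
sliceByEventCount <- function(stream, kesl) {
  stopifnot(is(stream, "EventStream"))
  kesl <- as.integer(kesl)
  if (length(kesl) != 1L || is.na(kesl) || kesl < 1L)
    stop("kesl must be a positive integer")
  n <- length(stream@timestamps)
  nSlices <- n %/% kesl
  if (nSlices == 0L) return(list())
  hasPol <- length(stream@polarity) > 0L
  lapply(seq_len(nSlices), function(i) {
    idx <- ((i - 1L) * kesl + 1L):(i * kesl)
    EventStream(timestamps = stream@timestamps[idx],
                addresses = stream@addresses[idx],
                addressSpace = stream@addressSpace,
                polarity = if (hasPol) stream@polarity[idx] else integer(0),
                geometry = stream@geometry)
  })
}

#' Spatially subsample a pixel-addressed stream
#'
#' Maps pixel (r, c) to (r %/% factor, c %/% factor), shrinking the address
#' space from rows x cols to (rows/factor) x (cols/factor). Timestamps,
#' ordering and event count are unchanged.
#'
#' @param stream an [EventStream-class] with geometry.
#' @param factor per-axis integer divisor; must divide both axes.
#' @return the subsampled [EventStream-class].
#' @export
subsampleAddresses <- function(stream, factor) {
  stopifnot(is(stream, "EventStream"))
  factor <- as.integer(factor)
  if (length(stream@geometry) != 2L)
    stop("stream has no geometry; cannot subsample addresses")
  rows <- stream@geometry[1]; cols <- stream@geometry[2]
  if (rows %% factor != 0L || cols %% factor != 0L)
    stop("factor ", factor, " does not divide geometry ", rows, "x", cols)
  if (factor == 1L) return(stream)
  r <- stream@addresses %/% cols
  c <- stream@addresses %% cols
  nr <- rows %/% factor; nc <- cols %/% factor
  newAddr <- (r %/% factor) * nc + (c %/% factor)
  EventStream(timestamps = stream@timestamps, addresses = newAddr,
              addressSpace = nr * nc, polarity = stream@polarity,
              geometry = c(nr, nc))
}

#' Concatenate event streams end to end
#'
#' Utility used by the stimulus generators: streams must share an address
#' space; timestamps are taken as already absolute (caller shifts them).
#'
#' @param streams list of [EventStream-class] objects.
#' @return a single [EventStream-class].
#' @keywords internal
#' @export
concatStreams <- function(streams) {
  stopifnot(length(streams) > 0L)
  space <- streams[[1]]@addressSpace
  geom <- streams[[1]]@geometry
  EventStream(timestamps = unlist(lapply(streams, slot, "timestamps")),
              addresses = unlist(lapply(streams, slot, "addresses")),
              addressSpace = space, geometry = geom)
}
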