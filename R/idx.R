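#' @include AllClasses.R
NULL

#' Read an IDX file (MNIST format)
#'
#' Standard IDX layout: two zero bytes, a type byte (0x08 = unsigned
#' byte), a dimension-count byte, big-endian 32-bit dimension sizes, then
#' the data. Image files (3 dimensions) are returned as a list of numeric
#' matrices with intensities divided by 255; label files (1 dimension) as
#' an integer vector.
#'
#' @param path file to read.
#' @return list of matrices (images) or integer vector (labels).
#' @seealso [readIdxDataset()]
#' @export
readIdx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 4, size = 1, signed = FALSE)
  if (magic[1] != 0 || magic[2] != 0 || magic[3] != 0x08)
    stop("bad IDX magic number in '", path, "'")
  ndim <- magic[4]
  dims <- readBin(con, "integer", n = ndim, size = 4, endian = "big")
  data <- readBin(con, "integer", n = prod(dims), size = 1,
                  signed = FALSE)
  if (length(data) != prod(dims))
    stop("truncated IDX file '", path, "'")
  if (ndim == 1) return(as.integer(data))
  if (ndim == 3) {
    per <- dims[2] * dims[3]
    return(lapply(seq_len(dims[1]), function(i) {
      matrix(data[((i - 1) * per + 1):(i * per)] / 255,
             dims[2], dims[3], byrow = TRUE)
    }))
  }
  stop("unsupported IDX dimensionality: ", ndim)
}

#' Read a paired IDX image/label dataset
#'
#' @param imagesPath,labelsPath the two IDX files.
#' @return list with \code{images} (list of matrices, intensities in
#'   [0, 1]) and \code{labels} (integer vector); lengths must match.
#' @export
readIdxDataset <- function(imagesPath, labelsPath) {
  images <- readIdx(imagesPath)
  labels <- readIdx(labelsPath)
  if (length(images) != length(labels))
    stop("image file has ", length(images), " samples but label file has ",
         length(labels))
  list(images = images, labels = labels)
}

#' Write images or labels to an IDX file
#'
#' Inverse of [readIdx()]; intensities in [0, 1] are scaled back to
#' unsigned bytes. Useful for building small synthetic fixtures.
#'
#' @param x list of numeric matrices (images) or integer vector (labels).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeIdx <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (is.list(x)) {
    d <- dim(x[[1]])
    writeBin(as.raw(c(0, 0, 0x08, 3)), con)
    writeBin(as.integer(c(length(x), d[1], d[2])), con, size = 4,
             endian = "big")
    for (img in x)
      writeBin(as.raw(round(pmin(1, pmax(0, t(img))) * 255)), con)
  } else {
    writeBin(as.raw(c(0, 0, 0x08, 1)), con)
    writeBin(length(x), con, size = 4, endian = "big")
    writeBin(as.raw(as.integer(x)), con)
  }
  invisible(path)
}
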