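# Bytecoding with exception + exception-guide (EG) arrays.

.checkU32 <- function(values) {
  if (length(values) == 0L) return(invisible(NULL))
  if (any(!is.finite(values)) || any(values != floor(values)))
    stop("values must be non-negative integers", call. = FALSE)
  if (any(values < 0))
    stop("negative values cannot be bytecoded", call. = FALSE)
  if (any(values >= 2^32))
    stop("values must be below 2^32", call. = FALSE)
  invisible(NULL)
}

#' Bytecode an integer vector with an exception guide array
#'
#' Stores each value in a single byte when it is below 255; the byte 255
#' flags an exception whose true value is appended, with its key, to a
#' key-sorted exception array. When `guideInterval` is a number `G`, an
#' exception guide (EG) array is also built: entry `g` holds the position in
#' the exception array of the first exception with key `>= g * G` (plus a
#' final sentinel equal to the exception count), so a flagged key `k` is
#' resolved by a binary search restricted to the window
#' `guide[k div G] .. guide[k div G + 1]`.
#'
#' @param values numeric vector of non-negative integers below 2^32.
#' @param guideInterval the guide interval `G`, a power of two (default
#'   1024), or `NULL` to keep no guide array.
#' @return a [ByteGuideVector].
#' @examples
#' v <- byteGuideEncode(c(3, 1, 300, 255))
#' byteGuideGet(v, 0:3)
#' @export
byteGuideEncode <- function(values, guideInterval = 1024L) {
  values <- as.numeric(values)
  .checkU32(values)
  N <- length(values)
  exc <- which(values >= 255) # 1-based
  bytes <- as.raw(pmin(values, 255))
  keys <- as.numeric(exc - 1L)
  if (is.null(guideInterval) || is.na(guideInterval)) {
    G <- NA_integer_
    guide <- numeric(0L)
  } else {
    G <- as.integer(guideInterval)
    if (G < 1L || bitwAnd(G, G - 1L) != 0L)
      stop("guideInterval must be a power of two", call. = FALSE)
    nb <- if (N > 0L) (N - 1L) %/% G + 1L else 0L
    # guide[g + 1] = number of exception keys < g * G
    guide <- c(findInterval((0:max(nb - 1L, 0L)) * G - 0.5, keys),
               length(keys))
    if (nb == 0L) guide <- numeric(0L)
  }
  new("ByteGuideVector", bytes = bytes, excKeys = keys,
      excValues = values[exc], guideInterval = G, guide = guide)
}

# Binary search for `key` among excKeys[lo..hi] (1-based, inclusive).
.excBinarySearch <- function(keys, values, key, lo, hi) {
  while (lo <= hi) {
    mid <- (lo + hi) %/% 2L
    km <- keys[mid]
    if (km == key) return(values[mid])
    if (km < key) lo <- mid + 1L else hi <- mid - 1L
  }
  stop("internal error: flagged key ", key, " missing from exception array",
       call. = FALSE)
}

# Scalar lookup used by the search hot path.
.bgvGet1 <- function(vec, k) {
  b <- as.integer(vec@bytes[k + 1])
  if (b < 255L) return(b)
  if (is.na(vec@guideInterval)) {
    .excBinarySearch(vec@excKeys, vec@excValues, k, 1L, length(vec@excKeys))
  } else {
    g <- k %/% vec@guideInterval
    .excBinarySearch(vec@excKeys, vec@excValues, k,
                     vec@guide[g + 1L] + 1L, vec@guide[g + 2L])
  }
}

#' Random access into a ByteGuideVector
#'
#' Returns the original value at each 0-based key `k`. Non-flagged keys are
#' read directly from the byte vector; flagged keys are resolved by binary
#' search through the exception array, restricted to the guide window when a
#' guide array is present.
#'
#' @param vec a [ByteGuideVector].
#' @param k 0-based key(s), each in `0..N-1`.
#' @return numeric vector of decoded values.
#' @export
byteGuideGet <- function(vec, k) {
  stopifnot(is(vec, "ByteGuideVector"))
  if (any(k < 0L | k >= length(vec@bytes)))
    stop("key out of range", call. = FALSE)
  out <- as.numeric(as.integer(vec@bytes[k + 1]))
  flagged <- which(out == 255)
  for (f in flagged) out[f] <- .bgvGet1(vec, k[f])
  out
}

#' @describeIn byteGuideGet number of encoded values.
#' @export
bgvLength <- function(vec) length(vec@bytes)

#' Compressed size accounting for a ByteGuideVector
#'
#' Payload bytes under the documented layout: one byte per value, 8 bytes per
#' exception (32-bit key + 32-bit value) and 4 bytes per guide entry.
#'
#' @param vec a [ByteGuideVector].
#' @return named numeric vector with components `bytes`, `exceptions`,
#'   `guide` and `total`.
#' @export
bgvSizeBytes <- function(vec) {
  b <- length(vec@bytes)
  e <- 8 * length(vec@excKeys)
  g <- 4 * length(vec@guide)
  c(bytes = b, exceptions = e, guide = g, total = b + e + g)
}

setMethod("show", "ByteGuideVector", function(object) {
  cat("ByteGuideVector of ", length(object@bytes), " values, ",
      length(object@excKeys), " exception(s)", sep = "")
  if (is.na(object@guideInterval)) cat(", no guide\n")
  else cat(", guide interval ", object@guideInterval, "\n", sep = "")
})
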