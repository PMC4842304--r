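# Direct bitpacking in blocks of 64 values with even bit widths, laid out
# vertically over 32-bit words as four interleaved lanes of 16 values.
# All word arithmetic is done in doubles (exact for integers < 2^53).

.bitLength <- function(v) {
  if (v <= 0) return(0L)
  sum(v >= 2^(0:31))
}

#' Bitpack an integer vector in blocks of 64
#'
#' Values are grouped in blocks of 64; each block is stored with a uniform
#' bit width, the smallest even width (minimum 2, maximum 32) that represents
#' the block maximum. Within a block, value index `i` (0-based) is assigned
#' to lane `i mod 4` at lane slot `floor(i / 4)`; each lane packs its 16
#' values little-endian into a series of 32-bit words starting at block word
#' `i mod 4` with stride 4, so random access selects one of 16 procedures by
#' `floor(i / 4)` applied to the word series starting at word `i mod 4`.
#' The final block is zero-padded.
#'
#' @param values numeric vector of non-negative integers below 2^32.
#' @return a [BP64Vector].
#' @examples
#' v <- bp64Encode(c(0:63, rep(1000, 10)))
#' bp64Get(v, c(0, 63, 70))
#' @export
bp64Encode <- function(values) {
  values <- as.numeric(values)
  .checkU32(values)
  N <- length(values)
  nblocks <- as.integer(ceiling(N / 64))
  widths <- integer(nblocks)
  payload <- numeric(0L)
  offsets <- numeric(nblocks + 1L)
  for (b in seq_len(nblocks)) {
    vals <- values[((b - 1L) * 64L + 1L):min(b * 64L, N)]
    if (length(vals) < 64L) vals <- c(vals, numeric(64L - length(vals)))
    w <- max(2L, as.integer(ceiling(.bitLength(max(vals)) / 2) * 2))
    widths[b] <- w
    words <- numeric(2L * w)
    for (i in 0:63) {
      v <- vals[i + 1L]
      if (v == 0) next
      lane <- i %% 4L
      bitpos <- (i %/% 4L) * w
      wi <- bitpos %/% 32L
      off <- bitpos %% 32L
      first <- min(w, 32L - off)
      idx <- lane + 4L * wi + 1L
      words[idx] <- words[idx] + (v %% 2^first) * 2^off
      if (w > first) {
        idx2 <- lane + 4L * (wi + 1L) + 1L
        words[idx2] <- words[idx2] + v %/% 2^first
      }
    }
    payload <- c(payload, words)
    offsets[b + 1L] <- offsets[b] + 2 * w
  }
  new("BP64Vector", widths = widths, payload = payload,
      blockOffsets = offsets, N = N)
}

#' Random access into a BP64Vector
#'
#' @param vec a [BP64Vector].
#' @param k 0-based index(es), each in `0..N-1`.
#' @return numeric vector of decoded values.
#' @export
bp64Get <- function(vec, k) {
  stopifnot(is(vec, "BP64Vector"))
  if (any(k < 0L | k >= vec@N))
    stop("index out of range", call. = FALSE)
  out <- numeric(length(k))
  for (q in seq_along(k)) {
    kk <- k[q]
    b <- kk %/% 64L
    i <- kk %% 64L
    w <- vec@widths[b + 1L]
    base <- vec@blockOffsets[b + 1L]
    lane <- i %% 4L
    bitpos <- (i %/% 4L) * w
    wi <- bitpos %/% 32L
    off <- bitpos %% 32L
    first <- min(w, 32L - off)
    v <- (vec@payload[base + lane + 4L * wi + 1L] %/% 2^off) %% 2^first
    if (w > first)
      v <- v + (vec@payload[base + lane + 4L * (wi + 1L) + 1L] %%
                  2^(w - first)) * 2^first
    out[q] <- v
  }
  out
}

#' @describeIn bp64Get number of encoded values.
#' @export
bp64Length <- function(vec) vec@N

#' @describeIn bp64Get payload size in bytes (4 bytes per 32-bit word plus
#'   one width byte per block).
#' @export
bp64SizeBytes <- function(vec) {
  4 * length(vec@payload) + length(vec@widths)
}

setMethod("show", "BP64Vector", function(object) {
  cat("BP64Vector of ", object@N, " values in ", length(object@widths),
      " block(s); widths: ",
      paste(unique(object@widths), collapse = ","), "\n", sep = "")
})
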