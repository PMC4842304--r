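# Binary (de)serialization of the compressed vectors. Everything is
# little-endian; each format starts with a 4-byte magic and a 32-bit version.

.u32ToRaw <- function(x) {
  x <- as.numeric(x)
  as.raw(rbind(x %% 256, (x %/% 256) %% 256,
               (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

.rawToU32 <- function(r) {
  m <- matrix(as.integer(r), nrow = 4L)
  m[1L, ] + 256 * m[2L, ] + 65536 * m[3L, ] + 16777216 * m[4L, ]
}

# Sequential reader over a raw vector with truncation checks.
.rawReader <- function(r) {
  pos <- 0L
  list(
    bytes = function(nb) {
      if (nb == 0L) return(raw(0L))
      if (pos + nb > length(r))
        stop("truncated payload", call. = FALSE)
      out <- r[(pos + 1L):(pos + nb)]
      pos <<- pos + as.integer(nb)
      out
    },
    u32 = function(nv = 1L) {
      if (nv == 0L) return(numeric(0L))
      if (pos + 4L * nv > length(r))
        stop("truncated payload", call. = FALSE)
      out <- .rawToU32(r[(pos + 1L):(pos + 4L * nv)])
      pos <<- pos + 4L * as.integer(nv)
      out
    },
    pos = function() pos,
    atEnd = function() pos >= length(r)
  )
}

.MAGIC_BGV <- charToRaw("BGV1")
.MAGIC_BP64 <- charToRaw("BP64")
.CODEC_VERSION <- 1

#' Serialize a compressed vector to raw bytes
#'
#' Writes a [ByteGuideVector] or [BP64Vector] to a versioned little-endian
#' byte layout that round-trips bit-exactly through [deserializeVector()].
#'
#' @param vec a [ByteGuideVector] or [BP64Vector].
#' @return a raw vector.
#' @examples
#' v <- byteGuideEncode(c(1, 300))
#' identical(byteGuideGet(deserializeVector(serializeVector(v)), 0:1),
#'           byteGuideGet(v, 0:1))
#' @export
setGeneric("serializeVector", function(vec) standardGeneric("serializeVector"))

#' @rdname serializeVector
#' @export
setMethod("serializeVector", "ByteGuideVector", function(vec) {
  hasGuide <- !is.na(vec@guideInterval)
  c(.MAGIC_BGV, .u32ToRaw(.CODEC_VERSION),
    .u32ToRaw(length(vec@bytes)),
    as.raw(as.integer(hasGuide)),
    .u32ToRaw(if (hasGuide) vec@guideInterval else 0),
    .u32ToRaw(length(vec@excKeys)),
    vec@bytes,
    .u32ToRaw(vec@excKeys),
    .u32ToRaw(vec@excValues),
    if (hasGuide) c(.u32ToRaw(length(vec@guide)), .u32ToRaw(vec@guide))
    else raw(0))
})

#' @rdname serializeVector
#' @export
setMethod("serializeVector", "BP64Vector", function(vec) {
  c(.MAGIC_BP64, .u32ToRaw(.CODEC_VERSION),
    .u32ToRaw(vec@N),
    .u32ToRaw(length(vec@widths)),
    as.raw(vec@widths),
    .u32ToRaw(length(vec@payload)),
    .u32ToRaw(vec@payload))
})

#' Deserialize a compressed vector from raw bytes
#'
#' @param r a raw vector produced by [serializeVector()].
#' @return the reconstructed [ByteGuideVector] or [BP64Vector].
#' @export
deserializeVector <- function(r) {
  stopifnot(is.raw(r))
  if (length(r) < 8L) stop("truncated payload", call. = FALSE)
  magic <- r[1:4]
  rd <- .rawReader(r[-(1:4)])
  version <- rd$u32()
  if (version != .CODEC_VERSION)
    stop("unsupported codec version ", version, call. = FALSE)
  if (identical(magic, .MAGIC_BGV)) {
    N <- rd$u32()
    hasGuide <- as.integer(rd$bytes(1L)) == 1L
    G <- rd$u32()
    E <- rd$u32()
    bytes <- rd$bytes(N)
    keys <- rd$u32(E)
    vals <- rd$u32(E)
    if (hasGuide) {
      ng <- rd$u32()
      guide <- rd$u32(ng)
    } else {
      G <- NA_integer_
      guide <- numeric(0L)
    }
    new("ByteGuideVector", bytes = bytes, excKeys = as.numeric(keys),
        excValues = as.numeric(vals), guideInterval = as.integer(G),
        guide = as.numeric(guide))
  } else if (identical(magic, .MAGIC_BP64)) {
    N <- rd$u32()
    nb <- rd$u32()
    widths <- as.integer(rd$bytes(nb))
    nw <- rd$u32()
    payload <- as.numeric(rd$u32(nw))
    offsets <- cumsum(c(0, 2 * widths))
    new("BP64Vector", widths = widths, payload = payload,
        blockOffsets = offsets, N = as.integer(N))
  } else {
    stop("unrecognized magic bytes: not a serialized vector", call. = FALSE)
  }
}
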