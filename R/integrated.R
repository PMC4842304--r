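# The ESA-gdi integrated layout: 5-byte blocks interleaving two bytecoded
# LCP values, two bytecoded child values and one DC byte, with shared
# guided exception arrays, plus whole-index serialization.

.mkGuide <- function(keys, N, G) {
  nb <- if (N > 0L) (N - 1L) %/% G + 1L else 0L
  if (nb == 0L) return(numeric(0L))
  c(findInterval((0:(nb - 1L)) * G - 0.5, keys), length(keys))
}

#' Build the integrated 5-byte-block index
#'
#' Interleaves the bytecoded LCP and child arrays and the nibble-packed DC
#' array into blocks of 5 bytes covering two adjacent indices each, so that
#' `LCP[k]`, `Child[k]` and `DC[k]` are retrieved together. Values of 255 or
#' more are flagged and kept in exception arrays with exception guide
#' arrays (one shared guide interval for both); the suffix array itself
#' stays uncompressed.
#'
#' @param esa an [EnhancedSuffixArray].
#' @param guideInterval guide interval for both exception guides
#'   (default 1024).
#' @return an [IntegratedESA].
#' @examples
#' idx <- buildIntegrated(buildEsa(encodeGenome("acaaacatat")))
#' integratedGet(idx, 8)
#' @export
buildIntegrated <- function(esa, guideInterval = 1024L) {
  stopifnot(is(esa, "EnhancedSuffixArray"))
  G <- as.integer(guideInterval)
  if (G < 1L || bitwAnd(G, G - 1L) != 0L)
    stop("guideInterval must be a power of two", call. = FALSE)
  N <- esa@genome@n + 1L
  lcp <- as.numeric(esa@lcp)
  rel <- as.numeric(esa@child@rel)
  dc <- esa@dc
  nblk <- ceiling(N / 2)
  # pad the odd tail with zeros
  pad <- 2L * nblk - N
  lcpB <- c(pmin(lcp, 255), numeric(pad))
  relB <- c(pmin(rel, 255), numeric(pad))
  dcP <- c(dc, integer(pad))
  even <- seq(1L, 2L * nblk, by = 2L)
  blocks <- as.raw(rbind(lcpB[even], lcpB[even + 1L],
                         relB[even], relB[even + 1L],
                         dcP[even] + 16L * dcP[even + 1L]))
  lk <- which(lcp >= 255) - 1L
  ck <- which(rel >= 255) - 1L
  new("IntegratedESA", genome = esa@genome, sa = esa@sa, blocks = blocks,
      lcpExcKeys = as.numeric(lk), lcpExcValues = lcp[lk + 1L],
      lcpGuide = .mkGuide(as.numeric(lk), N, G),
      childExcKeys = as.numeric(ck), childExcValues = rel[ck + 1L],
      childGuide = .mkGuide(as.numeric(ck), N, G),
      guideInterval = G, bucket = esa@bucket)
}

.intExcLookup <- function(keys, values, guide, G, k) {
  g <- k %/% G
  .excBinarySearch(keys, values, k, guide[g + 1L] + 1L, guide[g + 2L])
}

#' Read one index entry from the integrated blocks
#'
#' A single 5-byte block read yields the LCP value, the relative child value
#' and the DC code for index `k`; 255-flagged LCP/child bytes are resolved
#' through their guided exception arrays.
#'
#' @param idx an [IntegratedESA].
#' @param k index in `0..n`.
#' @return list with components `lcp`, `child` (relative stored value) and
#'   `dc` (nibble code; 15 at index 0, decode with [dcPairDecode()]).
#' @export
integratedGet <- function(idx, k) {
  stopifnot(is(idx, "IntegratedESA"))
  n <- idx@genome@n
  if (k < 0L || k > n) stop("index out of range 0..n", call. = FALSE)
  b <- k %/% 2L
  o <- k %% 2L
  base <- 5L * b
  lcpv <- as.integer(idx@blocks[base + 1L + o])
  childv <- as.integer(idx@blocks[base + 3L + o])
  dcByte <- as.integer(idx@blocks[base + 5L])
  dcv <- if (o == 0L) dcByte %% 16L else dcByte %/% 16L
  if (lcpv == 255L)
    lcpv <- .intExcLookup(idx@lcpExcKeys, idx@lcpExcValues, idx@lcpGuide,
                          idx@guideInterval, k)
  if (childv == 255L)
    childv <- .intExcLookup(idx@childExcKeys, idx@childExcValues,
                            idx@childGuide, idx@guideInterval, k)
  list(lcp = lcpv, child = childv, dc = dcv)
}

# Search accessors over the integrated blocks (DC mode by default).
.accessorsIntegrated <- function(idx, mode = "dc") {
  blocks <- idx@blocks
  G <- idx@guideInterval
  lk <- idx@lcpExcKeys; lv <- idx@lcpExcValues; lg <- idx@lcpGuide
  ck <- idx@childExcKeys; cv <- idx@childExcValues; cg <- idx@childGuide
  list(n = idx@genome@n, txt = idx@genome@text, sa = idx@sa,
       lcpAt = function(k) {
         v <- as.integer(blocks[5L * (k %/% 2L) + 1L + k %% 2L])
         if (v < 255L) v else .intExcLookup(lk, lv, lg, G, k)
       },
       childAt = function(k) {
         v <- as.integer(blocks[5L * (k %/% 2L) + 3L + k %% 2L])
         if (v < 255L) v else .intExcLookup(ck, cv, cg, G, k)
       },
       dcAt = function(k) {
         byte <- as.integer(blocks[5L * (k %/% 2L) + 5L])
         if (k %% 2L == 0L) byte %% 16L else byte %/% 16L
       },
       mode = mode, bucket = idx@bucket)
}

#' Space accounting for the integrated layout
#'
#' @param idx an [IntegratedESA].
#' @return named numeric vector: `blocks` (5 bytes per pair of indices),
#'   `exceptions` (8 bytes per exception), `guides` (4 bytes per entry) and
#'   `total`.
#' @export
integratedSizeBytes <- function(idx) {
  b <- length(idx@blocks)
  e <- 8 * (length(idx@lcpExcKeys) + length(idx@childExcKeys))
  g <- 4 * (length(idx@lcpGuide) + length(idx@childGuide))
  c(blocks = b, exceptions = e, guides = g, total = b + e + g)
}

setMethod("show", "IntegratedESA", function(object) {
  cat("IntegratedESA over a genome of length ", object@genome@n, "\n  ",
      length(object@blocks) %/% 5L, " five-byte blocks; exceptions: lcp ",
      length(object@lcpExcKeys), ", child ", length(object@childExcKeys),
      "; guide interval ", object@guideInterval, "\n", sep = "")
})

# ---- whole-index container -----------------------------------------------
# Container layout (little-endian): magic "ESAG", u32 format version,
# u8 layout (1 = separate arrays, 2 = integrated blocks), u32 section
# count, then sections of (4-byte tag, u32 payload length, payload), and a
# trailing u32 checksum (sum of all section payload bytes mod 2^32).
# Section tags: GNOM genome text + sequence table; SUFA suffix array;
# LCPB/CHLD serialized ByteGuideVectors of the LCP and child arrays;
# DCAR packed DC nibbles; INTG integrated blocks + exceptions + guides;
# BUKT bucket array.

.INDEX_MAGIC <- charToRaw("ESAG")
.INDEX_VERSION <- 1

.genomeToRaw <- function(genome) {
  st <- genome@seqTable
  nameRaw <- lapply(st$name, charToRaw)
  c(.u32ToRaw(genome@n),
    as.raw(genome@text),
    .u32ToRaw(nrow(st)),
    do.call(c, c(lapply(seq_len(nrow(st)), function(s) {
      c(.u32ToRaw(length(nameRaw[[s]])), nameRaw[[s]],
        .u32ToRaw(st$start[s]), .u32ToRaw(st$length[s]))
    }), list(raw(0)))))
}

.genomeFromRaw <- function(r) {
  rd <- .rawReader(r)
  n <- rd$u32()
  txt <- as.integer(rd$bytes(n + 1))
  ns <- rd$u32()
  rows <- lapply(seq_len(ns), function(s) {
    nl <- rd$u32()
    nm <- rawToChar(rd$bytes(nl))
    data.frame(name = nm, start = rd$u32(), length = rd$u32(),
               stringsAsFactors = FALSE)
  })
  new("EncodedGenome", text = txt, n = as.integer(n),
      seqTable = do.call(rbind, rows))
}

.bucketToRaw <- function(bucket) {
  c(.u32ToRaw(bucket@q), .u32ToRaw(bucket@start), .u32ToRaw(bucket@end))
}

.bucketFromRaw <- function(r) {
  rd <- .rawReader(r)
  q <- rd$u32()
  new("BucketArray", q = as.integer(q), start = rd$u32(4^q),
      end = rd$u32(4^q))
}

#' Save and load an ESA index file
#'
#' Writes an [EnhancedSuffixArray] (separate-array layout) or an
#' [IntegratedESA] (5-byte-block layout) to a versioned little-endian
#' container with a section table and a trailing checksum; see the package
#' vignette for the byte-level format. The round trip is bit-exact:
#' re-serializing a loaded index reproduces the file, and searches against
#' a loaded index return identical results.
#'
#' @param x an [EnhancedSuffixArray] or [IntegratedESA].
#' @param path file path (conventionally `.esa`).
#' @return `saveIndex`: `path`, invisibly. `loadIndex`: the reconstructed
#'   index object.
#' @examples
#' esa <- buildEsa(encodeGenome("acaaacatat"))
#' f <- tempfile(fileext = ".esa")
#' saveIndex(esa, f)
#' esaCount(loadIndex(f), "aca")
#' @export
saveIndex <- function(x, path) {
  sections <- list()
  if (is(x, "EnhancedSuffixArray")) {
    layout <- 1L
    sections$GNOM <- .genomeToRaw(x@genome)
    sections$SUFA <- .u32ToRaw(x@sa)
    sections$LCPB <- serializeVector(byteGuideEncode(x@lcp, 1024L))
    sections$CHLD <- serializeVector(byteGuideEncode(x@child@rel, 1024L))
    dc <- x@dc
    if (length(dc) %% 2L == 1L) dc <- c(dc, 0L)
    even <- seq(1L, length(dc), by = 2L)
    sections$DCAR <- c(.u32ToRaw(length(x@dc)),
                       as.raw(dc[even] + 16L * dc[even + 1L]))
  } else if (is(x, "IntegratedESA")) {
    layout <- 2L
    sections$GNOM <- .genomeToRaw(x@genome)
    sections$SUFA <- .u32ToRaw(x@sa)
    sections$INTG <- c(.u32ToRaw(x@guideInterval), x@blocks)
    sections$LEXC <- c(.u32ToRaw(length(x@lcpExcKeys)),
                       .u32ToRaw(x@lcpExcKeys), .u32ToRaw(x@lcpExcValues))
    sections$CEXC <- c(.u32ToRaw(length(x@childExcKeys)),
                       .u32ToRaw(x@childExcKeys),
                       .u32ToRaw(x@childExcValues))
    sections$LGDE <- c(.u32ToRaw(length(x@lcpGuide)), .u32ToRaw(x@lcpGuide))
    sections$CGDE <- c(.u32ToRaw(length(x@childGuide)),
                       .u32ToRaw(x@childGuide))
  } else {
    stop("cannot save an object of class ", class(x), call. = FALSE)
  }
  if (!is.null(x@bucket)) sections$BUKT <- .bucketToRaw(x@bucket)
  body <- do.call(c, c(lapply(names(sections), function(tag) {
    c(charToRaw(tag), .u32ToRaw(length(sections[[tag]])), sections[[tag]])
  }), list(raw(0))))
  checksum <- sum(as.numeric(unlist(lapply(sections, as.integer)))) %% 2^32
  out <- c(.INDEX_MAGIC, .u32ToRaw(.INDEX_VERSION), as.raw(layout),
           .u32ToRaw(length(sections)), body, .u32ToRaw(checksum))
  writeBin(out, path)
  invisible(path)
}

#' @rdname saveIndex
#' @export
loadIndex <- function(path) {
  r <- readBin(path, what = "raw", n = file.size(path))
  if (length(r) < 13L || !identical(r[1:4], .INDEX_MAGIC))
    stop("not an ESA index file (bad magic)", call. = FALSE)
  rd <- .rawReader(r[-(1:4)])
  version <- rd$u32()
  if (version != .INDEX_VERSION)
    stop("unsupported index format version ", version, call. = FALSE)
  layout <- as.integer(rd$bytes(1L))
  nsect <- rd$u32()
  sections <- list()
  for (s in seq_len(nsect)) {
    tag <- rawToChar(rd$bytes(4L))
    len <- rd$u32()
    sections[[tag]] <- rd$bytes(len)
  }
  stored <- rd$u32()
  checksum <- sum(as.numeric(unlist(lapply(sections, as.integer)))) %% 2^32
  if (length(checksum) == 0L) checksum <- 0
  if (stored != checksum)
    stop("index file checksum mismatch (corrupted or truncated file)",
         call. = FALSE)
  genome <- .genomeFromRaw(sections$GNOM)
  sa <- as.integer(.rawReader(sections$SUFA)$u32(genome@n + 1L))
  bucket <- if (!is.null(sections$BUKT)) .bucketFromRaw(sections$BUKT)
            else NULL
  if (layout == 1L) {
    lcp <- as.integer(byteGuideGet(deserializeVector(sections$LCPB),
                                   0:genome@n))
    child <- buildChildArray(lcp)
    rel <- as.integer(byteGuideGet(deserializeVector(sections$CHLD),
                                   0:genome@n))
    if (!identical(rel, child@rel))
      stop("stored child array disagrees with the LCP array", call. = FALSE)
    rdDc <- .rawReader(sections$DCAR)
    nd <- rdDc$u32()
    bytes <- as.integer(rdDc$bytes(ceiling(nd / 2)))
    dc <- as.integer(rbind(bytes %% 16L, bytes %/% 16L))[seq_len(nd)]
    esa <- new("EnhancedSuffixArray", genome = genome, sa = sa, lcp = lcp,
               child = child, dc = dc, bucket = bucket)
    esa
  } else if (layout == 2L) {
    rdI <- .rawReader(sections$INTG)
    G <- as.integer(rdI$u32())
    blocks <- rdI$bytes(5L * ceiling((genome@n + 1L) / 2))
    rdL <- .rawReader(sections$LEXC)
    nl <- rdL$u32()
    lk <- rdL$u32(nl); lv <- rdL$u32(nl)
    rdC <- .rawReader(sections$CEXC)
    nc <- rdC$u32()
    ck <- rdC$u32(nc); cv <- rdC$u32(nc)
    rdLg <- .rawReader(sections$LGDE)
    lg <- rdLg$u32(rdLg$u32())
    rdCg <- .rawReader(sections$CGDE)
    cg <- rdCg$u32(rdCg$u32())
    new("IntegratedESA", genome = genome, sa = sa, blocks = blocks,
        lcpExcKeys = lk, lcpExcValues = lv, lcpGuide = lg,
        childExcKeys = ck, childExcValues = cv, childGuide = cg,
        guideInterval = G, bucket = bucket)
  } else {
    stop("unknown index layout ", layout, call. = FALSE)
  }
}
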