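# S4 classes for the ESA-gdi index.
#
# Symbol codes used throughout: $=0, a=1, c=2, g=3, t=4, x=5.
# All comparisons between symbols use this numeric order, so the terminator
# sorts lowest and the ambiguity character x sorts highest.
# Genome positions and suffix-array indices are 0-based (position n holds the
# terminator); R vectors are accessed at position + 1.

.SYMBOLS <- c("$", "a", "c", "g", "t", "x")

#' EncodedGenome: a DNA text over {$, a, c, g, t, x}
#'
#' Holds a genome (or concatenated set of sequences) as integer symbol codes
#' with a single terminator `$` at position `n` (0-based). The ambiguity
#' character `x` stands for any IUPAC code other than a/c/g/t and never
#' matches a query symbol.
#'
#' @slot text integer vector of length `n + 1` with symbol codes
#'   ($=0, a=1, c=2, g=3, t=4, x=5); the last element is the terminator.
#' @slot n integer, genome length excluding the terminator.
#' @slot seqTable data.frame with columns `name`, `start` (0-based offset of
#'   the sequence in the concatenated text) and `length`, recording
#'   multi-FASTA provenance.
#'
#' @seealso [loadFasta()], [synthGenome()], [charAt()]
#' @export
setClass("EncodedGenome",
  representation(text = "integer", n = "integer", seqTable = "data.frame"))

setValidity("EncodedGenome", function(object) {
  txt <- object@text
  n <- object@n
  if (length(n) != 1L || is.na(n) || n < 0L)
    return("'n' must be a single non-negative integer")
  if (length(txt) != n + 1L)
    return("'text' must have length n + 1 (terminator included)")
  if (txt[n + 1L] != 0L)
    return("the terminator $ must be at position n")
  if (n > 0L && any(txt[seq_len(n)] == 0L))
    return("the terminator $ may only occur at position n")
  if (any(txt < 0L | txt > 5L))
    return("symbol codes must lie in 0..5 ($, a, c, g, t, x)")
  st <- object@seqTable
  if (nrow(st) > 0L) {
    if (!all(c("name", "start", "length") %in% names(st)))
      return("seqTable needs columns name, start, length")
    o <- order(st$start)
    if (any(diff(st$start[o]) < st$length[o][-nrow(st)]))
      return("seqTable entries must be non-overlapping and ascending")
    if (any(st$start < 0) || any(st$start + st$length > n))
      return("seqTable entries must lie within the text")
  }
  TRUE
})

#' ByteGuideVector: bytecoded integer vector with exception guide array
#'
#' Random-access compressed integer vector. Values below 255 are stored in a
#' single byte; the byte 255 flags an exception whose true value lives in a
#' key-sorted exception array. An optional exception guide (EG) array stores,
#' for every fixed key interval `G`, the position in the exception array of
#' the first exception with key >= g*G, which bounds the binary search window
#' for a flagged key.
#'
#' @slot bytes raw vector of length `N`.
#' @slot excKeys numeric vector of 0-based keys, strictly ascending.
#' @slot excValues numeric vector of exception values (< 2^32).
#' @slot guideInterval integer, the guide interval G (a power of two), or
#'   `NA` when no guide array is kept.
#' @slot guide numeric vector of 0-based positions into the exception array,
#'   one per guide bucket plus a final sentinel equal to the exception count;
#'   length 0 when no guide is kept.
#'
#' @seealso [byteGuideEncode()], [byteGuideGet()]
#' @export
setClass("ByteGuideVector",
  representation(bytes = "raw", excKeys = "numeric", excValues = "numeric",
                 guideInterval = "integer", guide = "numeric"))

setValidity("ByteGuideVector", function(object) {
  E <- length(object@excKeys)
  if (length(object@excValues) != E)
    return("exception keys and values must have equal length")
  if (E > 0L) {
    if (any(diff(object@excKeys) <= 0))
      return("exception keys must be strictly increasing")
    if (any(object@bytes[object@excKeys + 1L] != as.raw(255L)))
      return("every exception key must be flagged with byte 255")
    if (any(object@excValues < 255))
      return("exception values must be >= 255")
  }
  G <- object@guideInterval
  if (!is.na(G)) {
    if (G < 1L || bitwAnd(G, G - 1L) != 0L)
      return("guideInterval must be a power of two")
    g <- object@guide
    if (length(g) > 0L) {
      if (any(diff(g) < 0)) return("guide must be non-decreasing")
      if (g[length(g)] != E)
        return("final guide entry must equal the exception count")
    }
  } else if (length(object@guide) != 0L) {
    return("guide must be empty when guideInterval is NA")
  }
  TRUE
})

#' BP64Vector: blockwise fixed-width bitpacked integer vector
#'
#' Integers are packed in blocks of 64 values, each block with a uniform even
#' bit width (2, 4, ..., 32) chosen as the smallest even width that holds the
#' block maximum. Within a block the values are laid out vertically in four
#' interleaved lanes over 32-bit words: value index `i` lives in lane
#' `i mod 4` at lane slot `floor(i / 4)`, so scalar access needs only 16
#' distinct per-width procedures.
#'
#' @slot widths integer vector, one even bit width per block.
#' @slot payload numeric vector of 32-bit words (stored as doubles in
#'   0..2^32-1), little-endian bit order within each word.
#' @slot blockOffsets numeric vector of running word offsets, one per block
#'   plus a final total.
#' @slot N integer, number of encoded values.
#'
#' @seealso [bp64Encode()], [bp64Get()]
#' @export
setClass("BP64Vector",
  representation(widths = "integer", payload = "numeric",
                 blockOffsets = "numeric", N = "integer"))

setValidity("BP64Vector", function(object) {
  w <- object@widths
  if (length(w) != max(0L, ceiling(object@N / 64)))
    return("one width per block of 64 values is required")
  if (length(w) > 0L && any(w < 2L | w > 32L | w %% 2L != 0L))
    return("block widths must be even and in 2..32")
  if (length(object@blockOffsets) != length(w) + 1L)
    return("blockOffsets must have one entry per block plus a total")
  if (length(w) > 0L && any(diff(object@blockOffsets) != 2 * w))
    return("each block must occupy exactly 2 * width words")
  TRUE
})

#' ChildArray: combined Next/Down/Up table of the lcp-interval tree
#'
#' One slot per suffix-array index. Slot `k` holds the Next sibling l-index
#' of `k` when one exists (Next takes precedence over Down), otherwise the
#' Down value of `k`, otherwise the Up value of `k + 1` (stored at the
#' preceding slot). Values are stored relative: `|absolute - k| - 1`. The
#' `role` slot keeps construction-time bookkeeping of which relationship
#' occupies each slot; compressed representations drop it and recover the
#' direction from context at query time.
#'
#' @slot rel integer vector of relative stored values, slots 0..n.
#' @slot role integer vector: 0 = unused, 1 = Next, 2 = Down,
#'   3 = Up-of-next-slot.
#'
#' @seealso [buildChildArray()], [childAbsolute()]
#' @export
setClass("ChildArray", representation(rel = "integer", role = "integer"))

setValidity("ChildArray", function(object) {
  if (length(object@rel) != length(object@role))
    return("rel and role must have equal length")
  if (any(object@role < 0L | object@role > 3L))
    return("roles must be in 0..3")
  if (any(object@rel < 0L))
    return("relative child values must be non-negative")
  TRUE
})

#' BucketArray: precomputed suffix-array intervals for all q-mers
#'
#' For every q-mer over {a, c, g, t} (the ambiguity character x is never part
#' of a q-mer) the arrays hold the start and end suffix-array indices of the
#' interval of suffixes prefixed by that q-mer; an empty interval is encoded
#' as start > end. A bucket lookup replaces the first q steps of descent for
#' patterns of length >= q.
#'
#' @slot q integer q-mer length.
#' @slot start,end numeric vectors of length `4^q` with SA interval bounds.
#'
#' @seealso [buildBucketArray()], [bucketStorageBytes()]
#' @export
setClass("BucketArray",
  representation(q = "integer", start = "numeric", end = "numeric"))

setValidity("BucketArray", function(object) {
  if (length(object@start) != 4^object@q ||
      length(object@end) != 4^object@q)
    return("start/end must have 4^q entries")
  TRUE
})

#' EnhancedSuffixArray: suffix array with LCP, child and DC arrays
#'
#' The full in-memory enhanced suffix array over one [EncodedGenome]: the
#' suffix array, the longest-common-prefix (LCP) array, the combined child
#' array (Next/Down/Up with role tags), the discriminating-character (DC)
#' array, and an optional q-mer bucket array.
#'
#' @slot genome an [EncodedGenome].
#' @slot sa integer vector of length `n + 1`: 0-based suffix start positions
#'   in lexicographic order (`sa[1] == n`, the terminator suffix).
#' @slot lcp integer vector of length `n + 1`; entry `k + 1` is the length of
#'   the common prefix of the suffixes ranked `k - 1` and `k` (slot 0 unused,
#'   stored as 0).
#' @slot child a [ChildArray].
#' @slot dc integer vector of length `n + 1` of DC nibble codes (0..14;
#'   15 is the reserved code used at index 0, which has no predecessor).
#' @slot bucket a [BucketArray] or `NULL`.
#'
#' @seealso [buildEsa()], [esaSearch()], [buildIntegrated()]
#' @export
setClass("EnhancedSuffixArray",
  representation(genome = "EncodedGenome", sa = "integer", lcp = "integer",
                 child = "ChildArray", dc = "integer", bucket = "ANY"))

setValidity("EnhancedSuffixArray", function(object) {
  N <- object@genome@n + 1L
  if (length(object@sa) != N) return("sa must have n + 1 entries")
  if (length(object@lcp) != N) return("lcp must have n + 1 entries")
  if (length(object@child@rel) != N) return("child must have n + 1 slots")
  if (length(object@dc) != N) return("dc must have n + 1 entries")
  if (object@sa[1L] != object@genome@n)
    return("the terminator suffix must rank first")
  if (!is.null(object@bucket) && !is(object@bucket, "BucketArray"))
    return("bucket must be NULL or a BucketArray")
  TRUE
})

#' IntegratedESA: interleaved 5-byte-block layout of LCP, child and DC
#'
#' The ESA-gdi layout: for every pair of adjacent indices 2b and 2b+1 one
#' 5-byte block holds the two bytecoded LCP values, the two bytecoded child
#' values and one byte with the two DC nibbles (low nibble = even index), so
#' one block read yields LCP[k], Child[k] and DC[k] together. Values of 255
#' or more are flagged with 255 and resolved through guided exception arrays
#' kept beside the blocks. The suffix array itself stays uncompressed.
#'
#' @slot genome an [EncodedGenome].
#' @slot sa integer suffix array (uncompressed), length `n + 1`.
#' @slot blocks raw vector of `5 * ceiling((n + 1) / 2)` bytes; padding bytes
#'   of an odd tail are zero.
#' @slot lcpExcKeys,lcpExcValues,childExcKeys,childExcValues numeric
#'   exception arrays (0-based keys, ascending).
#' @slot lcpGuide,childGuide numeric exception-guide arrays (0-based
#'   positions plus a final sentinel).
#' @slot guideInterval integer guide interval shared by both guides.
#' @slot bucket a [BucketArray] or `NULL`.
#'
#' @seealso [buildIntegrated()], [integratedGet()], [saveIndex()]
#' @export
setClass("IntegratedESA",
  representation(genome = "EncodedGenome", sa = "integer", blocks = "raw",
                 lcpExcKeys = "numeric", lcpExcValues = "numeric",
                 lcpGuide = "numeric",
                 childExcKeys = "numeric", childExcValues = "numeric",
                 childGuide = "numeric",
                 guideInterval = "integer", bucket = "ANY"))

setValidity("IntegratedESA", function(object) {
  N <- object@genome@n + 1L
  if (length(object@sa) != N) return("sa must have n + 1 entries")
  if (length(object@blocks) != 5L * ceiling(N / 2))
    return("blocks must hold 5 bytes per pair of indices")
  if (length(object@lcpExcKeys) != length(object@lcpExcValues) ||
      length(object@childExcKeys) != length(object@childExcValues))
    return("exception keys and values must have equal length")
  if (!is.null(object@bucket) && !is(object@bucket, "BucketArray"))
    return("bucket must be NULL or a BucketArray")
  TRUE
})

#' SearchResult: outcome of an ESA pattern search
#'
#' @slot pattern the query string.
#' @slot m integer query length.
#' @slot c integer length of the longest prefix of the pattern that occurs in
#'   the genome (0..m).
#' @slot i,j integer bounds of the suffix-array interval whose suffixes share
#'   the matched prefix `P[0..c)`; `i > j` encodes an empty interval
#'   (only possible for an empty genome).
#' @slot positions integer vector of 0-based genome positions, filled by the
#'   locating task for full matches and empty otherwise.
#'
#' @seealso [esaSearch()], [esaLocate()], [esaCount()]
#' @export
setClass("SearchResult",
  representation(pattern = "character", m = "integer", c = "integer",
                 i = "integer", j = "integer", positions = "integer"))

#' EsaVariant: a named search representation over one ESA
#'
#' Bundles an [EnhancedSuffixArray] with one of the five benchmark
#' representations: `"esa"` (raw integer arrays, genome-based branch lookup),
#' `"byte"` (bytecoded LCP/child without guide), `"guide"` (bytecoded with
#' exception guide arrays), `"dc"` (bytecoded with guides plus DC-based
#' branch lookup) and `"gdi"` (integrated 5-byte-block layout with DC-based
#' branch lookup).
#'
#' @slot name variant name.
#' @slot esa the underlying [EnhancedSuffixArray].
#' @slot lcpStore,childStore `NULL` (raw), or [ByteGuideVector]s.
#' @slot integrated an [IntegratedESA] or `NULL`.
#' @slot branchMode `"genome"` or `"dc"`.
#'
#' @seealso [esaVariant()], [benchSearch()]
#' @export
setClass("EsaVariant",
  representation(name = "character", esa = "EnhancedSuffixArray",
                 lcpStore = "ANY", childStore = "ANY", integrated = "ANY",
                 branchMode = "character"))
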