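# Construction of the enhanced suffix array: suffix array, LCP array,
# combined child array (Next/Down/Up), DC array and the optional q-mer
# bucket array.

#' Build the suffix array of a genome
#'
#' Sorts all `n + 1` suffixes (the terminator suffix included)
#' lexicographically under the symbol order $ < a < c < g < t < x and returns
#' their 0-based start positions. Uses prefix doubling with radix ordering;
#' construction speed is not a contract of this package, correctness is
#' (validated against a naive sort oracle in the test suite).
#'
#' @param genome an [EncodedGenome].
#' @return integer vector of length `n + 1`; the first entry is always `n`.
#' @examples
#' buildSuffixArray(encodeGenome("acaaacatat"))
#' @export
buildSuffixArray <- function(genome) {
  stopifnot(is(genome, "EncodedGenome"))
  txt <- genome@text
  N <- length(txt)
  if (N == 1L) return(0L)
  rk <- txt
  k <- 1L
  repeat {
    r2 <- c(rk[-seq_len(k)], rep.int(-1L, min(k, N)))
    o <- order(rk, r2, method = "radix")
    newr <- integer(N)
    rka <- rk[o]
    r2a <- r2[o]
    newr[o] <- cumsum(c(1L, as.integer(rka[-1L] != rka[-N] |
                                         r2a[-1L] != r2a[-N])))
    rk <- newr
    if (rk[o[N]] == N) break
    k <- 2L * k
  }
  as.integer(o - 1L)
}

#' Build the LCP array from a suffix array
#'
#' Entry `k` (1-based rank, stored at R index `k + 1`) holds the length of
#' the longest common prefix of the suffixes ranked `k - 1` and `k`. Slot 0
#' is unused and stored as 0; entry 1 is always 0, since no suffix shares a
#' prefix with the terminator suffix. Kasai's linear-time text-order scan.
#'
#' @param genome an [EncodedGenome].
#' @param sa its suffix array from [buildSuffixArray()].
#' @return integer vector of length `n + 1`.
#' @examples
#' g <- encodeGenome("acaaacatat")
#' buildLcpArray(g, buildSuffixArray(g))[-1]
#' @export
buildLcpArray <- function(genome, sa) {
  txt <- genome@text
  N <- length(txt)
  stopifnot(length(sa) == N)
  lcp <- integer(N)
  if (N == 1L) return(lcp)
  rank <- integer(N)
  rank[sa + 1L] <- 0:(N - 1L)
  h <- 0L
  for (a in 0:(N - 2L)) {
    k <- rank[a + 1L]
    if (k > 0L) {
      b <- sa[k] # predecessor in rank order (0-based position)
      while (a + h < N - 1L && b + h < N - 1L &&
             txt[a + h + 1L] == txt[b + h + 1L])
        h <- h + 1L
      lcp[k + 1L] <- h
      if (h > 0L) h <- h - 1L
    } else {
      h <- 0L
    }
  }
  lcp
}

#' Build the combined child array from an LCP array
#'
#' Computes the Next, Down and Up relationships among l-indices of the
#' lcp-interval tree by the standard stack scans (a virtual boundary value of
#' -Inf at index `n + 1` closes all open intervals, and the l-index `n + 1`
#' is taken to have an Up relationship to l-index 1, so the root interval
#' `[1..n]` needs no special case). The three relations are merged into one
#' slot per index — Next takes precedence over Down, and the Up value of
#' `k` is stored at slot `k - 1` — and stored relative as
#' `|absolute - k| - 1`. Slot roles are tagged for in-memory traversal;
#' compressed layouts drop the tags and recover direction from context.
#'
#' @param lcp an LCP array from [buildLcpArray()].
#' @return a [ChildArray].
#' @export
buildChildArray <- function(lcp) {
  N <- length(lcp) # slots 0..n
  n <- N - 1L
  rel <- integer(N)
  role <- integer(N) # 0 none, 1 next, 2 down, 3 up(slot k holds Up[k+1])
  if (n < 1L) return(new("ChildArray", rel = rel, role = role))
  lcpOf <- function(k) if (k == 0L) -1L else if (k <= n) lcp[k + 1L] else -1L

  assign_slot <- function(slot, value, r) {
    # Next (1) may supersede a Down (2) at the same slot; any other
    # collision indicates a construction bug.
    if (role[slot + 1L] != 0L && !(r == 1L && role[slot + 1L] == 2L))
      stop("internal error: child slot ", slot, " written twice",
           call. = FALSE)
    rel[slot + 1L] <<- as.integer(value)
    role[slot + 1L] <<- r
  }

  # Up/Down pass (boundary k = n + 1 closes everything and yields Up[n+1]).
  stack <- integer(N + 1L)
  top <- 1L
  stack[1L] <- 0L
  lastIndex <- -1L
  for (k in seq_len(n + 1L)) {
    lk <- lcpOf(k)
    while (lk < lcpOf(stack[top])) {
      lastIndex <- stack[top]
      top <- top - 1L
      if (lk <= lcpOf(stack[top]) &&
          lcpOf(stack[top]) != lcpOf(lastIndex) && stack[top] > 0L) {
        # Down[stack[top]] = lastIndex, stored only when no Next will claim
        # the slot (Next precedence handled in assign_slot).
        assign_slot(stack[top], lastIndex - stack[top] - 1L, 2L)
      }
    }
    if (lastIndex != -1L) {
      # Up[k] = lastIndex, stored at slot k - 1.
      assign_slot(k - 1L, k - lastIndex - 1L, 3L)
      lastIndex <- -1L
    }
    top <- top + 1L
    stack[top] <- k
  }

  # Next pass (run over real indices only; n + 1 is never a sibling).
  top <- 1L
  stack[1L] <- 0L
  for (k in seq_len(n)) {
    lk <- lcpOf(k)
    while (lk < lcpOf(stack[top])) top <- top - 1L
    if (lk == lcpOf(stack[top]) && stack[top] > 0L) {
      lastIndex <- stack[top]
      top <- top - 1L
      assign_slot(lastIndex, k - lastIndex - 1L, 1L)
    }
    top <- top + 1L
    stack[top] <- k
  }

  new("ChildArray", rel = rel, role = role)
}

#' Decode a child array slot to its absolute value
#'
#' Returns the absolute l-index stored at a slot together with its role.
#' Next and Down slots decode as `slot + stored + 1`; an Up slot `k` holds
#' `Up[k + 1]` and decodes as `slot - stored` (the stored value is
#' `|absolute - index| - 1` with index `k + 1`).
#'
#' @param x an [EnhancedSuffixArray] or [ChildArray].
#' @param k slot index (0..n).
#' @return a list with components `role` (`"none"`, `"next"`, `"down"` or
#'   `"up"`), `value` (the absolute l-index, `NA` for unused slots) and
#'   `stored` (the relative stored value).
#' @examples
#' esa <- buildEsa(encodeGenome("acaaacatat"))
#' childAbsolute(esa, 1)  # Next[1] = 7
#' @export
childAbsolute <- function(x, k) {
  child <- if (is(x, "EnhancedSuffixArray")) x@child else x
  stopifnot(is(child, "ChildArray"), k >= 0L, k < length(child@rel))
  r <- child@role[k + 1L]
  s <- child@rel[k + 1L]
  value <- switch(r + 1L, NA_integer_, k + s + 1L, k + s + 1L, k - s)
  list(role = c("none", "next", "down", "up")[r + 1L],
       value = value, stored = s)
}

# DC pair tables: printed order $a,$c,$g,$t,$x,ac,ag,at,ax,cg,ct,cx,gt,gx,tx
# gives codes 0..14; code 15 is reserved (used at index 0).
.DC_BASE <- c(0L, 5L, 9L, 12L, 14L) # base code by s1 = $,a,c,g
.DC_S1 <- c(0L, 0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 4L)
.DC_S2 <- c(1L, 2L, 3L, 4L, 5L, 2L, 3L, 4L, 5L, 3L, 4L, 5L, 4L, 5L, 5L)

.dcCodeNum <- function(s1, s2) .DC_BASE[s1 + 1L] + (s2 - s1 - 1L)

#' Nibble codec for discriminating-character pairs
#'
#' A discriminating-character pair is always in strict lexicographic order
#' under $ < a < c < g < t < x, and the right character is never the
#' terminator, leaving exactly 15 valid pairs: $a, $c, $g, $t, $x, ac, ag,
#' at, ax, cg, ct, cx, gt, gx, tx, coded 0..14 in that order. Code 15 is
#' reserved/invalid.
#'
#' @param s1,s2 single characters from `$, a, c, g, t, x` with `s1 < s2`.
#' @param code a nibble code in 0..14.
#' @return `dcPairCode`: the integer code; `dcPairDecode`: a character
#'   vector `c(s1, s2)`; `dcPairTable`: data.frame of all 15 pairs.
#' @examples
#' dcPairCode("a", "t")
#' dcPairDecode(7)
#' @export
dcPairCode <- function(s1, s2) {
  u <- match(s1, .SYMBOLS) - 1L
  v <- match(s2, .SYMBOLS) - 1L
  if (is.na(u) || is.na(v))
    stop("symbols must be one of $, a, c, g, t, x", call. = FALSE)
  if (u >= v)
    stop("DC pairs must be in strict lexicographic order (got '",
         s1, "' >= '", s2, "')", call. = FALSE)
  .dcCodeNum(u, v)
}

#' @rdname dcPairCode
#' @export
dcPairDecode <- function(code) {
  if (any(code < 0L | code > 14L))
    stop("valid DC codes are 0..14", call. = FALSE)
  c(.SYMBOLS[.DC_S1[code + 1L] + 1L], .SYMBOLS[.DC_S2[code + 1L] + 1L])
}

#' @rdname dcPairCode
#' @export
dcPairTable <- function() {
  data.frame(code = 0:14,
             s1 = .SYMBOLS[.DC_S1 + 1L],
             s2 = .SYMBOLS[.DC_S2 + 1L],
             stringsAsFactors = FALSE)
}

#' Build the discriminating-character (DC) array
#'
#' For every l-index `k` in `1..n` the discriminating characters are the
#' first characters that differ between the two adjacent suffixes, located
#' in the genome at `S[SA[k-1] + LCP[k]]` and `S[SA[k] + LCP[k]]`. They are
#' returned as nibble codes (two of which pack into one byte, so the DC
#' array occupies `ceiling((n+1)/2)` bytes); index 0 has no predecessor and
#' carries the reserved code 15.
#'
#' @param genome an [EncodedGenome].
#' @param sa,lcp suffix array and LCP array of the genome.
#' @return integer vector of length `n + 1` of codes.
#' @export
buildDcArray <- function(genome, sa, lcp) {
  txt <- genome@text
  N <- length(txt)
  stopifnot(length(sa) == N, length(lcp) == N)
  if (N == 1L) return(15L)
  ks <- 2:N # R indices of k = 1..n
  s1 <- txt[sa[ks - 1L] + lcp[ks] + 1L]
  s2 <- txt[sa[ks] + lcp[ks] + 1L]
  if (any(s1 >= s2) || any(s2 == 0L))
    stop("internal error: invalid discriminating-character pair",
         call. = FALSE)
  c(15L, .dcCodeNum(s1, s2))
}

#' Build the q-mer bucket array
#'
#' For every q-mer over {a, c, g, t} the bucket array stores the start and
#' end suffix-array indices of the interval of suffixes prefixed by that
#' q-mer (suffixes containing `x` or shorter than `q` belong to no bucket;
#' empty buckets have start > end). A lookup replaces the first `q` descent
#' steps for patterns with `m >= q`.
#'
#' @param esa an [EnhancedSuffixArray] (or an [EncodedGenome] together with
#'   `sa`).
#' @param q q-mer length, `1 <= q <= 16`; limited in practice by the memory
#'   budget `4^q * 16` bytes (see `memoryLimit`).
#' @param sa suffix array, only when `esa` is an [EncodedGenome].
#' @param memoryLimit maximum allowed in-memory size in bytes of the two
#'   bucket arrays (default 2^29).
#' @return a [BucketArray].
#' @export
buildBucketArray <- function(esa, q, sa = NULL, memoryLimit = 2^29) {
  stopifnot(q >= 1L, q <= 16L)
  if (4^q * 16 > memoryLimit)
    stop("bucket array for q = ", q, " exceeds the memory budget of ",
         memoryLimit, " bytes", call. = FALSE)
  if (is(esa, "EnhancedSuffixArray")) {
    genome <- esa@genome
    sa <- esa@sa
  } else {
    genome <- esa
    stopifnot(is(genome, "EncodedGenome"), !is.null(sa))
  }
  txt <- genome@text
  n <- genome@n
  M <- 4^q
  start <- rep.int(1, M)
  end <- numeric(M) # start > end everywhere: all buckets empty
  if (n >= q) {
    ks <- 1:n # SA indices (rank); rank 0 is the terminator suffix
    pos <- sa[ks + 1L]
    valid <- pos + q <= n + 1L # suffix has at least q symbols before $
    w <- numeric(length(ks))
    for (d in 0:(q - 1L)) {
      cd <- txt[pos + d + 1L]
      valid <- valid & cd >= 1L & cd <= 4L
      w <- w * 4 + (cd - 1L)
    }
    ks <- ks[valid]
    w <- w[valid] + 1
    if (length(ks) > 0L) {
      # suffixes sharing a q-mer prefix are contiguous in SA order
      first <- !duplicated(w)
      start[w[first]] <- ks[first]
      last <- rev(!duplicated(rev(w)))
      end[w[last]] <- ks[last]
    }
  }
  new("BucketArray", q = as.integer(q), start = start, end = end)
}

#' Storage arithmetic for bucket arrays
#'
#' Each bucket array of suffix-array indices for q-mers occupies
#' `4^q * 4` bytes; both the start and the end array must be stored
#' explicitly (the ambiguity character is not part of any q-mer, so the
#' interval cannot be recovered from a single array of boundaries).
#'
#' @param q q-mer length.
#' @return named numeric vector with `perArray` and `pair` byte counts.
#' @examples
#' bucketStorageBytes(12) # 67 MB per array, 134 MB for the pair
#' @export
bucketStorageBytes <- function(q) {
  per <- 4^q * 4
  c(perArray = per, pair = 2 * per)
}

#' Look up the suffix-array interval of a q-mer
#'
#' @param bucket a [BucketArray].
#' @param qmer a character string of length `q` over a/c/g/t.
#' @return integer vector `c(i, j)`; `i > j` means the q-mer is absent.
#' @export
bucketInterval <- function(bucket, qmer) {
  stopifnot(is(bucket, "BucketArray"))
  p <- .encodePattern(qmer)
  if (length(p) != bucket@q)
    stop("q-mer length must equal ", bucket@q, call. = FALSE)
  w <- sum((p - 1L) * 4^((bucket@q - 1L):0)) + 1
  as.integer(c(bucket@start[w], bucket@end[w]))
}

#' Build the complete enhanced suffix array
#'
#' Convenience constructor running [buildSuffixArray()], [buildLcpArray()],
#' [buildChildArray()] and [buildDcArray()], optionally adding a q-mer
#' bucket array.
#'
#' @param genome an [EncodedGenome].
#' @param bucketQ q-mer length for an optional bucket array, or `NULL`.
#' @return an [EnhancedSuffixArray].
#' @examples
#' esa <- buildEsa(encodeGenome("acaaacatat"))
#' esaCount(esa, "aca")
#' @export
buildEsa <- function(genome, bucketQ = NULL) {
  stopifnot(is(genome, "EncodedGenome"))
  sa <- buildSuffixArray(genome)
  lcp <- buildLcpArray(genome, sa)
  child <- buildChildArray(lcp)
  dc <- buildDcArray(genome, sa, lcp)
  esa <- new("EnhancedSuffixArray", genome = genome, sa = sa, lcp = lcp,
             child = child, dc = dc, bucket = NULL)
  if (!is.null(bucketQ))
    esa@bucket <- buildBucketArray(esa, bucketQ)
  esa
}

#' @describeIn buildEsa accessor for the suffix array.
#' @param esa an [EnhancedSuffixArray].
#' @export
suffixArray <- function(esa) esa@sa

#' @describeIn buildEsa accessor for the LCP array.
#' @export
lcpArray <- function(esa) esa@lcp

#' @describeIn buildEsa accessor for the DC codes.
#' @export
dcArray <- function(esa) esa@dc

#' @describeIn buildEsa accessor for the genome.
#' @export
esaGenome <- function(esa) esa@genome

setMethod("show", "EnhancedSuffixArray", function(object) {
  cat("EnhancedSuffixArray over a genome of length ", object@genome@n,
      "\n  exceptions >= 255: lcp ", sum(object@lcp >= 255L),
      ", child ", sum(object@child@rel >= 255L), "\n", sep = "")
  if (!is.null(object@bucket))
    cat("  bucket array: q = ", object@bucket@q, "\n", sep = "")
})

setMethod("show", "ChildArray", function(object) {
  cat("ChildArray with ", length(object@rel), " slots (",
      sum(object@role == 1L), " Next, ", sum(object@role == 2L), " Down, ",
      sum(object@role == 3L), " Up)\n", sep = "")
})

setMethod("show", "BucketArray", function(object) {
  cat("BucketArray for q = ", object@q, " (",
      sum(object@start <= object@end), " of ", 4^object@q,
      " q-mers present)\n", sep = "")
})
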