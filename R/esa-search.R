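# Pattern search over the ESA: blind descent through the lcp-interval tree
# with genome-based or DC-based child selection, plus counting and locating.
#
# Interval conventions: [i..j] are suffix-array indices with 1 <= i <= j <= n
# (index 0, the terminator suffix, is excluded from search; the initial
# interval is [1..n]). The first l-index of the root comes from the Up value
# of the virtual l-index n + 1 stored at slot n, which yields l-index 1 and
# an empty leading child [1..0] that traversal skips.

#' Count character matches between a pattern suffix and a genome suffix
#'
#' Returns the largest `t >= c` such that `P[c..t)` equals `S[pos+c..pos+t)`
#' symbol by symbol. The terminator and the ambiguity character `x` never
#' equal a query symbol, so comparison always stops at or before them.
#'
#' @param genome an [EncodedGenome].
#' @param pattern query string over a/c/g/t.
#' @param c number of already-matched characters (`0 <= c <= m`).
#' @param pos 0-based genome position (`0 <= pos <= n`).
#' @return integer match length `t`.
#' @examples
#' countMatches(encodeGenome("acaaacatat"), "aca", 0, 0)
#' @export
countMatches <- function(genome, pattern, c = 0L, pos = 0L) {
  stopifnot(is(genome, "EncodedGenome"))
  p <- .encodePattern(pattern)
  m <- length(p)
  stopifnot(c >= 0L, c <= m, pos >= 0L, pos <= genome@n)
  .countFrom(genome@text, p, as.integer(c), as.integer(pos))
}

.countFrom <- function(txt, p, c, pos) {
  m <- length(p)
  N <- length(txt)
  len <- min(m - c, N - (pos + c))
  if (len <= 0L) return(c)
  a <- p[(c + 1L):(c + len)]
  b <- txt[(pos + c + 1L):(pos + c + len)]
  mism <- which(a != b)
  if (length(mism) == 0L) c + len else c + mism[1L] - 1L
}

# ---- accessor bundles -----------------------------------------------------
# A bundle is a plain list: n, txt, sa (R vector, sa[k+1] = SA[k]),
# lcpAt(k), childAt(k) (relative stored value), dcAt(k) (code), mode
# ("genome" or "dc"), bucket (BucketArray or NULL).

.accessorsRaw <- function(esa, mode = "genome") {
  lcp <- esa@lcp
  rel <- esa@child@rel
  dc <- esa@dc
  list(n = esa@genome@n, txt = esa@genome@text, sa = esa@sa,
       lcpAt = function(k) lcp[k + 1L],
       childAt = function(k) rel[k + 1L],
       dcAt = function(k) dc[k + 1L],
       mode = mode, bucket = esa@bucket)
}

.accessorsBgv <- function(esa, lcpStore, childStore, mode = "genome") {
  list(n = esa@genome@n, txt = esa@genome@text, sa = esa@sa,
       lcpAt = function(k) .bgvGet1(lcpStore, k),
       childAt = function(k) .bgvGet1(childStore, k),
       dcAt = local({dc <- esa@dc; function(k) dc[k + 1L]}),
       mode = mode, bucket = esa@bucket)
}

# ---- child-interval traversal --------------------------------------------

# First l-index of the non-singleton interval [i..j]. Direction is recovered
# from context: the up-decode of slot j (j - stored) is the answer exactly
# when it falls in (i..j] -- for a genuine lcp-interval, slot j can only
# hold an Up value, and an Up value of a strictly larger interval ending at
# j decodes to a position <= i. Otherwise the forward decode of slot i
# (i + stored + 1) gives the Down value. On first entry (`isRoot`) the Up
# value of the virtual l-index n + 1, stored at slot n, yields l-index 1
# directly; the root rule must not be reapplied to a child that happens to
# share the root's bounds (all suffixes sharing a common first character),
# where the general rule takes over at greater depth.
.firstLIndex <- function(acc, i, j, isRoot = FALSE) {
  if (isRoot)
    return(acc$n - acc$childAt(acc$n))
  up <- j - acc$childAt(j)
  if (up > i && up <= j) up else i + acc$childAt(i) + 1L
}

# Next sibling l-index after k within parent [i..j] at depth d, or NA.
# A forward decode is a Next value exactly when it stays inside the parent
# and sits at the parent's depth.
.nextLIndex <- function(acc, k, j, d) {
  cand <- k + acc$childAt(k) + 1L
  if (cand <= j && acc$lcpAt(cand) == d) cand else NA_integer_
}

# Genome-based child selection: read each candidate child's branch
# character from the genome at S[SA[left] + d] and compare with p; children
# come in ascending character order, so stop early once the branch
# character exceeds p.
.selectChildGenome <- function(acc, i, j, k1, d, p) {
  if (k1 > i) {
    branch <- acc$txt[acc$sa[i + 1L] + d + 1L]
    if (branch == p) return(c(i, k1 - 1L))
    if (branch > p) return(NULL)
  }
  k <- k1
  repeat {
    nk <- .nextLIndex(acc, k, j, d)
    branch <- acc$txt[acc$sa[k + 1L] + d + 1L]
    if (branch == p) return(c(k, if (is.na(nk)) j else nk - 1L))
    if (branch > p || is.na(nk)) return(NULL)
    k <- nk
  }
}

# DC-based child selection: no suffix-array or genome access. At the first
# l-index the full pair (s1, s2) decides the left child or an early exit;
# along the Next chain only s2 is consulted.
.selectChildDc <- function(acc, i, j, k1, d, p) {
  code <- acc$dcAt(k1)
  s1 <- .DC_S1[code + 1L]
  s2 <- .DC_S2[code + 1L]
  if (p == s1) return(if (k1 - 1L >= i) c(i, k1 - 1L) else NULL)
  if (p < s1) return(NULL)
  if (p < s2) return(NULL) # s1 < p < s2: p was skipped
  k <- k1
  repeat {
    if (p == s2) {
      nk <- .nextLIndex(acc, k, j, d)
      return(c(k, if (is.na(nk)) j else nk - 1L))
    }
    nk <- .nextLIndex(acc, k, j, d)
    if (is.na(nk)) return(NULL)
    k <- nk
    s2 <- .DC_S2[acc$dcAt(k) + 1L]
    if (p < s2) return(NULL)
  }
}

.selectChild <- function(acc, i, j, k1, d, p) {
  if (acc$mode == "dc") .selectChildDc(acc, i, j, k1, d, p)
  else .selectChildGenome(acc, i, j, k1, d, p)
}

# ---- search core ----------------------------------------------------------

# Blind descent: children are selected by the single character P[d] at each
# parent depth d without verifying edge labels; one countMatches against a
# suffix of the final interval fixes the true match length c, and the
# answer interval is the shallowest interval on the descent path whose
# depth reaches c.
.searchCore <- function(acc, p, useBucket = FALSE) {
  m <- length(p)
  n <- acc$n
  if (n == 0L)
    return(list(c = 0L, i = 1L, j = 0L))
  pathI <- integer(0L); pathJ <- integer(0L); pathD <- integer(0L)
  i <- 1L; j <- n
  if (useBucket && !is.null(acc$bucket) && m >= acc$bucket@q) {
    q <- acc$bucket@q
    w <- sum((p[seq_len(q)] - 1) * 4^((q - 1L):0)) + 1
    bi <- acc$bucket@start[w]; bj <- acc$bucket@end[w]
    if (bi <= bj) {
      # the bucket interval is the maximal range sharing P[0..q)
      pathI <- c(pathI, 1L); pathJ <- c(pathJ, n); pathD <- c(pathD, 0L)
      i <- as.integer(bi); j <- as.integer(bj)
      pathI <- c(pathI, i); pathJ <- c(pathJ, j); pathD <- c(pathD, q)
      if (i < j) {
        res <- .descend(acc, p, i, j, pathI, pathJ, pathD, isRoot = FALSE)
        return(.finish(acc, p, res))
      }
      return(.finish(acc, p, list(pathI = c(pathI, i), pathJ = c(pathJ, j),
                                  pathD = c(pathD, m), i = i, j = j)))
    }
    # empty bucket: the q-mer is absent; fall through to a full descent to
    # recover the partial match length
  }
  res <- .descend(acc, p, i, j, pathI, pathJ, pathD, isRoot = TRUE)
  .finish(acc, p, res)
}

.descend <- function(acc, p, i, j, pathI, pathJ, pathD, isRoot) {
  m <- length(p)
  repeat {
    if (i == j) {
      pathI <- c(pathI, i); pathJ <- c(pathJ, j); pathD <- c(pathD, m)
      break
    }
    k1 <- .firstLIndex(acc, i, j, isRoot)
    d <- acc$lcpAt(k1)
    if (d >= m) {
      pathI <- c(pathI, i); pathJ <- c(pathJ, j); pathD <- c(pathD, m)
      break
    }
    pathI <- c(pathI, i); pathJ <- c(pathJ, j); pathD <- c(pathD, d)
    child <- .selectChild(acc, i, j, k1, d, p[d + 1L])
    if (is.null(child)) break
    isRoot <- FALSE
    i <- child[1L]; j <- child[2L]
  }
  list(pathI = pathI, pathJ = pathJ, pathD = pathD, i = i, j = j)
}

.finish <- function(acc, p, res) {
  c <- .countFrom(acc$txt, p, 0L, acc$sa[res$i + 1L])
  sel <- which(res$pathD >= c)[1L]
  if (is.na(sel)) sel <- length(res$pathD)
  list(c = as.integer(c), i = as.integer(res$pathI[sel]),
       j = as.integer(res$pathJ[sel]))
}

# ---- public search API ----------------------------------------------------

.accessorsFor <- function(x, variant) {
  if (is(x, "EnhancedSuffixArray")) {
    .accessorsRaw(x, mode = variant)
  } else if (is(x, "IntegratedESA")) {
    .accessorsIntegrated(x, mode = variant)
  } else if (is(x, "EsaVariant")) {
    .accessorsVariant(x)
  } else {
    stop("no search accessors for class ", class(x), call. = FALSE)
  }
}

#' Search a pattern in an ESA index
#'
#' Performs blind descent through the lcp-interval hierarchy, selecting the
#' child interval by the single pattern character at each parent's depth,
#' and fixes the true match length with one final character-count against a
#' suffix of the final interval. Returns the length `c` of the longest
#' prefix of the pattern occurring in the genome, and the maximal
#' suffix-array interval `[i..j]` whose suffixes share `P[0..c)` (the root
#' `[1..n]` when `c = 0`). The whole pattern occurs iff `c == m`.
#'
#' @param x an [EnhancedSuffixArray], [IntegratedESA] or [EsaVariant].
#' @param pattern query string over a/c/g/t.
#' @param variant branch lookup: `"genome"` reads branch characters from the
#'   suffix array and genome text; `"dc"` reads them from the
#'   discriminating-character array only. Ignored for an [EsaVariant],
#'   which fixes its own mode.
#' @param useBucket seed the descent with the q-mer bucket array when the
#'   index has one and `m >= q`.
#' @return a [SearchResult] (without positions; see [esaLocate()]).
#' @examples
#' esa <- buildEsa(encodeGenome("acaaacatat"))
#' esaSearch(esa, "aca")
#' esaSearch(esa, "at", variant = "dc")
#' @export
esaSearch <- function(x, pattern, variant = c("genome", "dc"),
                      useBucket = FALSE) {
  variant <- match.arg(variant)
  p <- .encodePattern(pattern)
  acc <- .accessorsFor(x, variant)
  res <- .searchCore(acc, p, useBucket = useBucket)
  new("SearchResult", pattern = pattern, m = length(p), c = res$c,
      i = res$i, j = res$j, positions = integer(0L))
}

#' Locate and count full pattern matches
#'
#' Full-match semantics: when the matched prefix length `c` is shorter than
#' the pattern, `esaLocate` returns no positions and `esaCount` returns 0;
#' otherwise the positions are `SA[i..j]` sorted ascending and the count is
#' `j - i + 1`.
#'
#' @inheritParams esaSearch
#' @return `esaLocate`: sorted integer vector of 0-based genome positions;
#'   `esaCount`: the number of occurrences.
#' @examples
#' esa <- buildEsa(encodeGenome("acaaacatat"))
#' esaLocate(esa, "at")
#' esaCount(esa, "a")
#' @export
esaLocate <- function(x, pattern, variant = c("genome", "dc"),
                      useBucket = FALSE) {
  variant <- match.arg(variant)
  p <- .encodePattern(pattern)
  acc <- .accessorsFor(x, variant)
  res <- .searchCore(acc, p, useBucket = useBucket)
  if (res$c < length(p)) return(integer(0L))
  sort(acc$sa[(res$i:res$j) + 1L])
}

#' @rdname esaLocate
#' @export
esaCount <- function(x, pattern, variant = c("genome", "dc"),
                     useBucket = FALSE) {
  variant <- match.arg(variant)
  p <- .encodePattern(pattern)
  acc <- .accessorsFor(x, variant)
  res <- .searchCore(acc, p, useBucket = useBucket)
  if (res$c < length(p)) 0L else res$j - res$i + 1L
}

#' Select the child lcp-interval matching a character
#'
#' Exposes one step of the descent: given a non-singleton lcp-interval
#' `[i..j]` of the index, returns the child interval whose branch character
#' equals `p`, or `NULL` when no child matches. `getIntervalGenome`
#' implements the genome-based branch lookup (it reads one character per
#' candidate child from the genome at the position given by the suffix
#' array); `getIntervalDc` reads only the discriminating-character array.
#'
#' @param x an [EnhancedSuffixArray] or [IntegratedESA].
#' @param i,j interval bounds, `1 <= i < j <= n` (or `i == j == 1` is
#'   rejected: singletons have no children).
#' @param p a single character from a/c/g/t.
#' @return integer vector `c(i, j)` of the child interval, or `NULL`.
#' @examples
#' esa <- buildEsa(encodeGenome("acaaacatat"))
#' getIntervalGenome(esa, 1, 10, "c")  # [7..8]
#' getIntervalDc(esa, 7, 8, "t")       # [8..8]
#' @export
getIntervalGenome <- function(x, i, j, p) {
  .getIntervalPublic(x, i, j, p, "genome")
}

#' @rdname getIntervalGenome
#' @export
getIntervalDc <- function(x, i, j, p) {
  .getIntervalPublic(x, i, j, p, "dc")
}

.getIntervalPublic <- function(x, i, j, p, mode) {
  acc <- .accessorsFor(x, mode)
  i <- as.integer(i); j <- as.integer(j)
  if (i < 1L || j > acc$n || i >= j)
    stop("[i..j] must be a non-singleton interval within [1..n]",
         call. = FALSE)
  pc <- .encodePattern(p)
  if (length(pc) != 1L)
    stop("p must be a single character", call. = FALSE)
  k1 <- .firstLIndex(acc, i, j, isRoot = (i == 1L && j == acc$n))
  d <- acc$lcpAt(k1)
  child <- .selectChild(acc, i, j, k1, d, pc)
  if (is.null(child)) NULL else as.integer(child)
}

#' Enumerate all lcp-intervals via the child array
#'
#' Walks the combined child array from the root, listing every non-singleton
#' lcp-interval with its depth. Used by the benchmark harness to sample
#' parent intervals and by the test suite to compare against a brute-force
#' partition of the LCP array.
#'
#' @param x an [EnhancedSuffixArray] or [IntegratedESA].
#' @return data.frame with columns `i`, `j`, `depth`.
#' @export
lcpIntervals <- function(x) {
  acc <- .accessorsFor(x, "genome")
  n <- acc$n
  if (n < 1L) return(data.frame(i = integer(0), j = integer(0),
                                depth = integer(0)))
  out <- list()
  queue <- list(c(1L, n, 1L)) # (i, j, isRoot flag)
  while (length(queue) > 0L) {
    iv <- queue[[1L]]
    queue <- queue[-1L]
    i <- iv[1L]; j <- iv[2L]
    if (i >= j) next
    k1 <- .firstLIndex(acc, i, j, isRoot = iv[3L] == 1L)
    d <- acc$lcpAt(k1)
    out[[length(out) + 1L]] <- c(i, j, d)
    # children: [i..k1-1] (empty at the root), then between l-indices; a
    # child sharing the parent's bounds (only possible from the root rule)
    # is re-entered under the general rule at greater depth
    ch <- list()
    if (k1 - 1L >= i) ch[[1L]] <- c(i, k1 - 1L)
    k <- k1
    repeat {
      nk <- .nextLIndex(acc, k, j, d)
      ch[[length(ch) + 1L]] <- c(k, if (is.na(nk)) j else nk - 1L)
      if (is.na(nk)) break
      k <- nk
    }
    for (cc in ch)
      if (cc[1L] < cc[2L])
        queue[[length(queue) + 1L]] <- c(cc, 0L)
  }
  df <- do.call(rbind, out)
  data.frame(i = df[, 1L], j = df[, 2L], depth = df[, 3L])
}

setMethod("show", "SearchResult", function(object) {
  cat("SearchResult for '", object@pattern, "' (m = ", object@m, ")\n",
      "  matched prefix c = ", object@c,
      if (object@c == object@m) " (full match)" else " (partial)",
      "\n  interval [", object@i, "..", object@j, "]",
      if (object@i <= object@j)
        paste0(" (", object@j - object@i + 1L, " suffixes)") else " (empty)",
      "\n", sep = "")
  if (length(object@positions) > 0L)
    cat("  positions: ", paste(object@positions, collapse = ", "), "\n",
        sep = "")
})
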