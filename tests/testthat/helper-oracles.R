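# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: suffix order comes from radix-sorting substrings, LCP from
# pairwise character comparison, matches from a sliding scan, and the
# lcp-interval tree from a recursive partition of the LCP array.

oracleSuffixArray <- function(genome) {
  s <- genomeString(genome) # "$" sorts below letters in the C locale
  N <- nchar(s)
  sufs <- substring(s, 1:N, N)
  order(sufs, method = "radix") - 1L
}

oracleLcp <- function(genome, sa) {
  s <- genomeString(genome)
  N <- nchar(s)
  lcp <- integer(N)
  for (k in seq_len(N - 1L)) {
    a <- substring(s, sa[k] + 1L, N)
    b <- substring(s, sa[k + 1L] + 1L, N)
    h <- 0L
    while (h < min(nchar(a), nchar(b)) &&
           substr(a, h + 1L, h + 1L) == substr(b, h + 1L, h + 1L))
      h <- h + 1L
    lcp[k + 1L] <- h
  }
  lcp
}

# All 0-based genome positions where the pattern occurs exactly.
oracleLocate <- function(genome, pattern) {
  txt <- genome@text
  p <- esagdi:::.encodePattern(pattern)
  m <- length(p)
  n <- genomeLength(genome)
  if (m > n) return(integer(0L))
  hits <- rep(TRUE, n - m + 1L)
  for (d in seq_len(m))
    hits <- hits & txt[d:(n - m + d)] == p[d]
  which(hits) - 1L
}

# max over genome positions a of lcp(P, S[a..]).
oracleMaxMatch <- function(genome, pattern) {
  txt <- genome@text
  p <- esagdi:::.encodePattern(pattern)
  n <- genomeLength(genome)
  best <- 0L
  for (a in 0:n) {
    h <- 0L
    while (h < length(p) && a + h < n + 1L && txt[a + h + 1L] == p[h + 1L])
      h <- h + 1L
    best <- max(best, h)
  }
  best
}

# Recursive partition of the LCP array into the lcp-interval tree:
# the l-indices of [i..j] are the positions of the minimum of lcp[(i+1)..j],
# and that minimum is the interval's depth. Returns all non-singleton
# intervals.
oracleIntervalTree <- function(lcp, n) {
  rows <- list()
  recurse <- function(i, j) {
    if (i >= j) return(invisible(NULL))
    vals <- lcp[(i + 1L):j + 1L]
    d <- min(vals)
    ls <- (i + 1L):j
    ls <- ls[vals == d]
    rows[[length(rows) + 1L]] <<- c(i, j, d)
    bounds <- c(i, ls, j + 1L)
    for (b in seq_len(length(bounds) - 1L))
      recurse(bounds[b], bounds[b + 1L] - 1L)
  }
  recurse(1L, n)
  if (length(rows) == 0L)
    return(data.frame(i = integer(0), j = integer(0), depth = integer(0)))
  df <- do.call(rbind, rows)
  data.frame(i = df[, 1L], j = df[, 2L], depth = df[, 3L])
}

# Branch characters of the children of [i..j] at depth d, from the genome.
oracleBranchChars <- function(genome, sa, lcp, i, j) {
  vals <- lcp[(i + 1L):j + 1L]
  d <- min(vals)
  ls <- ((i + 1L):j)[vals == d]
  lefts <- c(i, ls)
  genome@text[sa[lefts + 1L] + d + 1L]
}

# A small battery of genomes exercising plain, duplicated and x-masked text.
testGenomes <- function(count, maxN = 2000L, seed = 42L) {
  gs <- vector("list", count)
  set.seed(seed)
  specs <- data.frame(
    n = sample(50:maxN, count, replace = TRUE),
    dup = sample(0:2, count, replace = TRUE),
    xrun = sample(c(0L, 0L, 0L, 5L), count, replace = TRUE),
    seed = sample.int(1e6, count))
  for (g in seq_len(count)) {
    dup <- if (specs$n[g] >= 400L) specs$dup[g] else 0L
    dupLen <- if (dup > 0L) min(30L, specs$n[g] %/% 10L) else 0L
    gs[[g]] <- synthGenome(specs$n[g], dup, dupLen,
                           specs$xrun[g], seed = specs$seed[g])
  }
  gs
}

sortedIntervals <- function(df) {
  df <- df[order(df$i, df$j, df$depth), , drop = FALSE]
  rownames(df) <- NULL
  df
}
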