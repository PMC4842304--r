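# Benchmark harness for the count/locate measurement protocol: random
# indices / parent intervals / query sequences, repeated trials with
# randomized method order, median times with the iteration overhead
# subtracted, and cross-representation checksums that must agree.
#
# Timing numbers are reported, never asserted; the asserted artifacts are
# checksums, counts and byte-accounting columns.

.median_ <- function(x) stats::median(x)

.checksumAdd <- function(acc, v) (acc * 31 + v) %% 2147483647

.timeOnce <- function(fn) {
  t0 <- proc.time()[[3L]]
  res <- fn()
  list(elapsed = proc.time()[[3L]] - t0, result = res)
}

#' Benchmark LCP value retrieval across representations
#'
#' Retrieves the LCP value for `nQueries` random indices drawn uniformly in
#' `1..n`, for each representation of the LCP array: the raw integer vector
#' (`"raw"`), bytecoding without a guide (`"byte"`), bytecoding with an
#' exception guide array (`"guide"`), and blockwise bitpacking (`"bp64"`).
#' Every trial uses the representations in random order; the median time
#' over trials, minus the median time of an identical loop over the raw
#' vector (the iteration + checksum overhead), is reported per query. A
#' checksum over the retrieved values must be identical across
#' representations, and the function stops if it is not.
#'
#' @param genome an [EncodedGenome] (an ESA is built internally).
#' @param nQueries number of random indices (default 1e4).
#' @param trials odd number of repetitions (default 9).
#' @param seed integer seed.
#' @param guideInterval guide interval for the `"guide"` representation.
#' @return data.frame with one row per representation: median time per
#'   query (microseconds, overhead-subtracted), payload bytes, bytes per
#'   genome length, exception rate, and the common checksum.
#' @export
benchLcpRetrieval <- function(genome, nQueries = 1e4L, trials = 9L,
                              seed = 1L, guideInterval = 1024L) {
  stopifnot(trials %% 2L == 1L)
  esa <- buildEsa(genome)
  n <- genome@n
  lcp <- as.numeric(esa@lcp)
  reps <- list(
    raw = list(get = function(ks) lcp[ks + 1L], bytes = 4 * (n + 1)),
    byte = local({
      v <- byteGuideEncode(lcp, NULL)
      list(get = function(ks) byteGuideGet(v, ks),
           bytes = unname(bgvSizeBytes(v)["total"]))
    }),
    guide = local({
      v <- byteGuideEncode(lcp, guideInterval)
      list(get = function(ks) byteGuideGet(v, ks),
           bytes = unname(bgvSizeBytes(v)["total"]))
    }),
    bp64 = local({
      v <- bp64Encode(lcp)
      list(get = function(ks) bp64Get(v, ks), bytes = bp64SizeBytes(v))
    }))
  .withSeed(seed, {
    times <- matrix(NA_real_, nrow = trials, ncol = length(reps),
                    dimnames = list(NULL, names(reps)))
    sums <- matrix(NA_real_, nrow = trials, ncol = length(reps))
    overhead <- numeric(trials)
    for (t in seq_len(trials)) {
      # each trial draws fresh random indices and runs the
      # representations in a fresh random order
      ks <- sample.int(n, nQueries, replace = TRUE) # indices 1..n
      overhead[t] <- .timeOnce(function() sum(ks))$elapsed
      for (r in sample(seq_along(reps))) {
        run <- .timeOnce(function() sum(reps[[r]]$get(ks)))
        times[t, r] <- run$elapsed
        sums[t, r] <- run$result
      }
      if (length(unique(sums[t, ])) != 1L)
        stop("checksum mismatch across LCP representations", call. = FALSE)
    }
    med <- apply(times, 2L, .median_) - .median_(overhead)
    data.frame(
      representation = names(reps),
      usPerQuery = pmax(med, 0) / nQueries * 1e6,
      bytes = vapply(reps, function(r) r$bytes, numeric(1L)),
      bytesPerGenome = vapply(reps, function(r) r$bytes, numeric(1L)) / n,
      exceptionRate = sum(lcp[-1L] >= 255) / n,
      checksum = sums[1L, ],
      nQueries = nQueries, trials = trials,
      row.names = NULL, stringsAsFactors = FALSE)
  })
}

# Sample non-singleton parent intervals by descending on random genomic
# q-mers, pooling every non-singleton interval on each descent path.
.sampleIntervals <- function(esa, count, qmerLen = 12L) {
  n <- esa@genome@n
  qmerLen <- min(qmerLen, max(1L, n %/% 2L))
  qmers <- sampleQueries(esa@genome, qmerLen, max(count, 64L),
                         seed = sample.int(2^30, 1L))
  acc <- .accessorsRaw(esa)
  pool <- list()
  for (qm in qmers) {
    p <- .encodePattern(qm)
    res <- .descend(acc, p, 1L, n, integer(0), integer(0), integer(0),
                    isRoot = TRUE)
    keep <- res$pathI < res$pathJ
    if (any(keep))
      pool[[length(pool) + 1L]] <- cbind(res$pathI[keep], res$pathJ[keep])
  }
  if (length(pool) == 0L)
    stop("genome too small to sample parent intervals", call. = FALSE)
  pool <- unique(do.call(rbind, pool))
  pool[sample.int(nrow(pool), count, replace = TRUE), , drop = FALSE]
}

#' Benchmark child-interval selection
#'
#' Samples `nIntervals` non-singleton parent lcp-intervals (reached by
#' descending on random genomic q-mers) plus one random query character
#' each, and measures the time to return the matching child lcp-interval or
#' the absence of a match, for genome-based branch lookup
#' (suffix array + genome text accesses) versus DC-based lookup. The
#' returned intervals must be identical across methods; singleton intervals
#' are never sampled.
#'
#' @param genome an [EncodedGenome].
#' @param nIntervals number of sampled parent intervals (default 1e4).
#' @param trials odd number of repetitions.
#' @param seed integer seed.
#' @param qmerLen length of the genomic q-mers used to reach parent
#'   intervals (default 12, shortened on tiny genomes).
#' @return data.frame with one row per method: median time per selection
#'   (microseconds, overhead-subtracted) and the common result checksum.
#' @export
benchChildSelection <- function(genome, nIntervals = 1e4L, trials = 9L,
                                seed = 1L, qmerLen = 12L) {
  stopifnot(trials %% 2L == 1L)
  esa <- buildEsa(genome)
  accG <- .accessorsRaw(esa, "genome")
  accD <- .accessorsRaw(esa, "dc")
  n <- genome@n
  .withSeed(seed, {
    iv <- .sampleIntervals(esa, nIntervals, qmerLen)
    pc <- sample.int(4L, nrow(iv), replace = TRUE)
    selector <- function(acc) function() {
      s <- 0
      for (r in seq_len(nrow(iv))) {
        i <- iv[r, 1L]; j <- iv[r, 2L]
        k1 <- .firstLIndex(acc, i, j, isRoot = (i == 1L && j == n))
        ch <- .selectChild(acc, i, j, k1, acc$lcpAt(k1), pc[r])
        s <- .checksumAdd(s, if (is.null(ch)) -1 else ch[1L] * (n + 1) + ch[2L])
      }
      s
    }
    methods <- list(genome = selector(accG), dc = selector(accD))
    times <- matrix(NA_real_, trials, length(methods),
                    dimnames = list(NULL, names(methods)))
    overhead <- numeric(trials)
    sums <- rep(NA_real_, length(methods))
    for (t in seq_len(trials)) {
      overhead[t] <- .timeOnce(function() {
        s <- 0
        for (r in seq_len(nrow(iv))) s <- .checksumAdd(s, r)
        s
      })$elapsed
      for (r in sample(seq_along(methods))) {
        run <- .timeOnce(methods[[r]])
        times[t, r] <- run$elapsed
        sums[r] <- run$result
      }
    }
    if (length(unique(sums)) != 1L)
      stop("child selection results differ between genome-based and ",
           "DC-based branch lookup", call. = FALSE)
    med <- apply(times, 2L, .median_) - .median_(overhead)
    data.frame(method = names(methods),
               usPerSelection = pmax(med, 0) / nrow(iv) * 1e6,
               checksum = sums, nIntervals = nrow(iv), trials = trials,
               row.names = NULL, stringsAsFactors = FALSE)
  })
}

#' Benchmark full search across the five ESA representations
#'
#' Generates random query sequences from the genome at the given lengths,
#' runs the counting and locating tasks under each representation
#' ([esaVariant()]: `esa`, `byte`, `guide`, `dc`, `gdi`) in random order per
#' trial, and reports median times per query, locating time per match
#' result (the per-query time normalized by the mean number of matches) and
#' the mean match count per query length. A checksum over the
#' `(c, i, j)` result triples must agree across all representations.
#'
#' @param genome an [EncodedGenome].
#' @param nQueriesPerLength queries per length (default 1e4).
#' @param queryLengths query lengths (default 12, 24, 36).
#' @param trials odd number of repetitions.
#' @param seed integer seed.
#' @param variants subset of the five representation names.
#' @param guideInterval guide interval for the guided representations.
#' @return data.frame with one row per (variant, length): times, mean
#'   matches per query, and the common checksum.
#' @export
benchSearch <- function(genome, nQueriesPerLength = 1e4L,
                        queryLengths = c(12L, 24L, 36L), trials = 9L,
                        seed = 1L, variants = .VARIANT_NAMES,
                        guideInterval = 1024L) {
  stopifnot(trials %% 2L == 1L)
  variants <- match.arg(variants, .VARIANT_NAMES, several.ok = TRUE)
  esa <- buildEsa(genome)
  vs <- lapply(variants, function(nm) esaVariant(esa, nm, guideInterval))
  names(vs) <- variants
  accs <- lapply(vs, .accessorsVariant)
  .withSeed(seed, {
    rows <- list()
    for (L in queryLengths) {
      queries <- sampleQueries(genome, L, nQueriesPerLength,
                               seed = sample.int(2^30, 1L))
      plist <- lapply(queries, .encodePattern)
      runner <- function(acc) function() {
        s <- 0
        matches <- 0
        for (p in plist) {
          res <- .searchCore(acc, p)
          s <- .checksumAdd(s, (res$c * (acc$n + 2) + res$i) * (acc$n + 2) +
                              res$j)
          if (res$c == length(p)) matches <- matches + res$j - res$i + 1
        }
        c(s, matches)
      }
      runners <- lapply(accs, runner)
      times <- matrix(NA_real_, trials, length(runners),
                      dimnames = list(NULL, names(runners)))
      overhead <- numeric(trials)
      sums <- matches <- rep(NA_real_, length(runners))
      for (t in seq_len(trials)) {
        overhead[t] <- .timeOnce(function() {
          s <- 0
          for (p in plist) s <- .checksumAdd(s, p[1L])
          s
        })$elapsed
        for (r in sample(seq_along(runners))) {
          run <- .timeOnce(runners[[r]])
          times[t, r] <- run$elapsed
          sums[r] <- run$result[1L]
          matches[r] <- run$result[2L]
        }
      }
      if (length(unique(sums)) != 1L)
        stop("search results differ across representations at length ", L,
             call. = FALSE)
      med <- pmax(apply(times, 2L, .median_) - .median_(overhead), 0)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = names(runners), queryLength = L,
        usPerQuery = med / length(plist) * 1e6,
        nsPerMatch = ifelse(matches > 0, med / matches * 1e9, NA_real_),
        meanMatches = matches / length(plist),
        sizeBytes = vapply(vs, variantSizeBytes, numeric(1L)),
        checksum = sums, nQueries = length(plist), trials = trials,
        row.names = NULL, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}
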