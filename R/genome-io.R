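# Genome text model: FASTA ingestion, character access, synthetic genomes
# and query sampling.

# IUPAC DNA codes; everything that is not a/c/g/t collapses to the single
# ambiguity symbol x.
.CHAR2CODE <- local({
  m <- c("a" = 1L, "c" = 2L, "g" = 3L, "t" = 4L,
         "u" = 4L,
         "r" = 5L, "y" = 5L, "s" = 5L, "w" = 5L, "k" = 5L, "m" = 5L,
         "b" = 5L, "d" = 5L, "h" = 5L, "v" = 5L, "n" = 5L, "x" = 5L)
  m
})

.encodeChars <- function(chars, what = "sequence") {
  codes <- .CHAR2CODE[chars]
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1L]
    stop("symbol '", chars[bad], "' at position ", bad - 1L,
         " of ", what, " is outside the IUPAC DNA set", call. = FALSE)
  }
  unname(codes)
}

.newGenome <- function(codes, seqTable = NULL) {
  n <- length(codes)
  if (is.null(seqTable))
    seqTable <- data.frame(name = "seq", start = 0L, length = n,
                           stringsAsFactors = FALSE)
  new("EncodedGenome", text = c(as.integer(codes), 0L), n = as.integer(n),
      seqTable = seqTable)
}

# Parse a plain character string (a/c/g/t/x + IUPAC) into an EncodedGenome.
# Mostly used in examples and tests; FASTA files go through loadFasta().

#' Encode a DNA string as an EncodedGenome
#'
#' @param x a single character string over the IUPAC DNA alphabet
#'   (case-insensitive); any code other than a/c/g/t becomes the ambiguity
#'   symbol `x`. A trailing `$` may be included and is ignored (the
#'   terminator is always appended).
#' @return an [EncodedGenome].
#' @examples
#' g <- encodeGenome("acaaacatat")
#' genomeLength(g)
#' @export
encodeGenome <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- tolower(x)
  x <- sub("\\$$", "", x)
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  .newGenome(.encodeChars(chars))
}

#' Load a (multi-)FASTA file into an EncodedGenome
#'
#' Sequences are concatenated in file order. Adjacent sequences are separated
#' by a run of the ambiguity character `x` (which never matches a query, so
#' separators cannot create spurious matches), and a single terminator `$` is
#' appended to the whole text. Lowercase input is accepted; IUPAC ambiguity
#' codes other than a/c/g/t map to `x`.
#'
#' @param path path to a FASTA file (gzip-compressed accepted).
#' @param xRunLen length of the `x` run inserted between adjacent sequences
#'   (default 1).
#' @return an [EncodedGenome] with `seqTable` recording the name, 0-based
#'   start offset and length of every input sequence.
#' @seealso [writeFasta()] for the inverse operation.
#' @export
loadFasta <- function(path, xRunLen = 1L) {
  stopifnot(xRunLen >= 0L)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L)
    stop("FASTA file '", path, "' contains no sequences", call. = FALSE)
  if (any(Biostrings::width(set) == 0L))
    stop("FASTA file '", path, "' contains an empty sequence", call. = FALSE)
  seqs <- tolower(as.character(set))
  nm <- names(set)
  if (is.null(nm)) nm <- paste0("seq", seq_along(seqs))
  nm <- sub("\\s.*$", "", nm)
  codes <- vector("list", length(seqs))
  starts <- integer(length(seqs))
  off <- 0L
  for (s in seq_along(seqs)) {
    ch <- strsplit(seqs[s], "", fixed = TRUE)[[1L]]
    codes[[s]] <- .encodeChars(ch, what = paste0("record '", nm[s], "'"))
    starts[s] <- off
    off <- off + length(ch)
    if (s < length(seqs)) {
      codes[[s]] <- c(codes[[s]], rep.int(5L, xRunLen))
      off <- off + as.integer(xRunLen)
    }
  }
  .newGenome(unlist(codes),
             data.frame(name = nm, start = starts,
                        length = lengths(strsplit(seqs, "", fixed = TRUE)),
                        stringsAsFactors = FALSE))
}

#' Write an EncodedGenome back to FASTA
#'
#' Each `seqTable` record is written as one FASTA record; ambiguity symbols
#' `x` are written as `N` and reload as `x`, so a round trip with the same
#' separator policy reproduces the identical text.
#'
#' @param genome an [EncodedGenome].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(genome, path) {
  stopifnot(is(genome, "EncodedGenome"))
  st <- genome@seqTable
  chars <- c("$", "a", "c", "g", "t", "n")
  seqs <- vapply(seq_len(nrow(st)), function(s) {
    idx <- st$start[s] + seq_len(st$length[s])
    paste(chars[genome@text[idx] + 1L], collapse = "")
  }, character(1L))
  set <- Biostrings::DNAStringSet(toupper(seqs))
  names(set) <- st$name
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Genome length and symbol access
#'
#' `genomeLength()` returns `n`, the number of symbols excluding the
#' terminator. `charAt()` returns the symbol at 0-based position `a`;
#' `charAt(genome, n)` is the terminator `"$"`.
#'
#' @param genome an [EncodedGenome].
#' @param a 0-based position(s), each in `0..n`.
#' @return `charAt`: character vector of symbols; `genomeLength`: integer.
#' @examples
#' g <- encodeGenome("acaaacatat")
#' charAt(g, c(0, 7, 10))
#' @export
charAt <- function(genome, a) {
  stopifnot(is(genome, "EncodedGenome"))
  if (any(a < 0L | a > genome@n))
    stop("position out of range 0..n", call. = FALSE)
  .SYMBOLS[genome@text[a + 1L] + 1L]
}

#' @rdname charAt
#' @export
genomeLength <- function(genome) genome@n

#' Decode an EncodedGenome to a character string
#'
#' @param genome an [EncodedGenome].
#' @param withTerminator include the trailing `$`?
#' @return a single character string.
#' @export
genomeString <- function(genome, withTerminator = TRUE) {
  codes <- genome@text
  if (!withTerminator) codes <- codes[-length(codes)]
  paste(.SYMBOLS[codes + 1L], collapse = "")
}

# Run `expr` under a temporary RNG state seeded with `seed`.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic genome
#'
#' Draws an i.i.d. uniform a/c/g/t background, then copies `dupCount`
#' segments of length `dupLen` to random non-overlapping locations (a planted
#' duplication of length L forces a pair of adjacent suffixes with a common
#' prefix of at least L, which exercises the 255-exception path of the
#' bytecoded arrays), and finally overwrites `xRunLen` symbols at both ends
#' with the ambiguity character `x`, emulating telomere-like masked ends.
#' Deterministic for a given seed.
#'
#' @param length genome length (>= 1).
#' @param dupCount number of duplicated segments.
#' @param dupLen length of each duplicated segment (< `length`).
#' @param xRunLen length of the `x` run placed at each end.
#' @param seed integer seed.
#' @return an [EncodedGenome].
#' @examples
#' g <- synthGenome(1000, dupCount = 1, dupLen = 300, seed = 7)
#' @export
synthGenome <- function(length, dupCount = 0L, dupLen = 0L, xRunLen = 0L,
                        seed = 1L) {
  stopifnot(length >= 1L, dupLen >= 0L, dupCount >= 0L, xRunLen >= 0L)
  if (dupCount > 0L && dupLen >= length)
    stop("dupLen must be smaller than the genome length", call. = FALSE)
  if (2L * xRunLen > length)
    stop("x runs longer than the genome", call. = FALSE)
  .withSeed(seed, {
    codes <- sample.int(4L, length, replace = TRUE)
    if (dupCount > 0L && dupLen > 0L) {
      lo <- xRunLen + 1L
      hi <- length - xRunLen - dupLen + 1L
      if (hi < lo)
        stop("no room to place duplicated segments", call. = FALSE)
      taken <- matrix(numeric(0), ncol = 2L)
      place <- function() {
        for (try in seq_len(200L)) {
          s <- sample(lo:hi, 1L)
          if (all(s + dupLen - 1L < taken[, 1L] | s > taken[, 2L]))
            return(s)
        }
        stop("could not place non-overlapping duplicate segments",
             call. = FALSE)
      }
      for (d in seq_len(dupCount)) {
        src <- place()
        taken <- rbind(taken, c(src, src + dupLen - 1L))
        dst <- place()
        taken <- rbind(taken, c(dst, dst + dupLen - 1L))
        codes[dst:(dst + dupLen - 1L)] <- codes[src:(src + dupLen - 1L)]
      }
    }
    if (xRunLen > 0L) {
      codes[seq_len(xRunLen)] <- 5L
      codes[(length - xRunLen + 1L):length] <- 5L
    }
    .newGenome(codes)
  })
}

#' Sample query patterns from a genome
#'
#' Draws substrings of the genome uniformly over all start positions whose
#' window is free of `x` (and of the terminator), so every query is a genuine
#' a/c/g/t substring of the genome. Deterministic for a given seed.
#'
#' @param genome an [EncodedGenome].
#' @param lengths integer vector of query lengths.
#' @param countPerLength number of queries per length.
#' @param seed integer seed.
#' @return character vector of `length(lengths) * countPerLength` patterns.
#' @export
sampleQueries <- function(genome, lengths, countPerLength, seed = 1L) {
  stopifnot(is(genome, "EncodedGenome"), all(lengths >= 1L),
            countPerLength >= 1L)
  n <- genome@n
  ok <- genome@text[seq_len(n)] >= 1L & genome@text[seq_len(n)] <= 4L
  bad <- cumsum(!ok)
  .withSeed(seed, {
    out <- character(0L)
    for (L in lengths) {
      if (L > n)
        stop("query length ", L, " exceeds the genome length", call. = FALSE)
      starts <- seq_len(n - L + 1L)
      clean <- starts[bad[starts + L - 1L] -
                        c(0, bad)[starts] == 0L]
      if (length(clean) == 0L)
        stop("no x-free window of length ", L, " exists", call. = FALSE)
      picks <- clean[sample.int(length(clean), countPerLength,
                                replace = TRUE)]
      out <- c(out, vapply(picks, function(s) {
        paste(.SYMBOLS[genome@text[s:(s + L - 1L)] + 1L], collapse = "")
      }, character(1L)))
    }
    out
  })
}

# Encode an a/c/g/t query pattern to symbol codes, rejecting $ and x.
.encodePattern <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nchar(pattern) >= 1L)
  chars <- strsplit(tolower(pattern), "", fixed = TRUE)[[1L]]
  codes <- c("a" = 1L, "c" = 2L, "g" = 3L, "t" = 4L)[chars]
  if (anyNA(codes))
    stop("query patterns may contain only a, c, g, t (found '",
         chars[which(is.na(codes))[1L]], "')", call. = FALSE)
  unname(codes)
}

setMethod("show", "EncodedGenome", function(object) {
  cat("EncodedGenome of length ", object@n, " (+ terminator), ",
      nrow(object@seqTable), " sequence(s)\n", sep = "")
  head <- genomeString(object)
  if (nchar(head) > 60) head <- paste0(substr(head, 1, 57), "...")
  cat("  text: ", head, "\n", sep = "")
})
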