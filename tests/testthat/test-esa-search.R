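exampleEsa <- buildEsa(encodeGenome("acaaacatat"))

test_that("countMatches compares pattern suffixes against genome suffixes", {
  g <- encodeGenome("acaaacatat")
  expect_equal(countMatches(g, "aca", 0, 0), 3)
  expect_equal(countMatches(g, "ta", 0, 0), 0) # first-symbol mismatch
  expect_equal(countMatches(g, "ca", 1, 1), 2) # resumes at c = 1
  expect_equal(countMatches(g, "at", 0, 8), 2)
  expect_equal(countMatches(g, "atat", 0, 8), 2) # hits the terminator
  gx <- encodeGenome("ax")
  expect_equal(countMatches(gx, "aa", 0, 0), 1) # x never matches
})

test_that("child selection reproduces the worked example's branches", {
  esa <- exampleEsa
  expect_equal(getIntervalGenome(esa, 1, 10, "a"), c(1L, 6L))
  expect_equal(getIntervalGenome(esa, 1, 10, "c"), c(7L, 8L))
  expect_equal(getIntervalGenome(esa, 1, 10, "t"), c(9L, 10L))
  expect_null(getIntervalGenome(esa, 1, 10, "g"))
  expect_equal(getIntervalGenome(esa, 7, 8, "a"), c(7L, 7L))
  expect_equal(getIntervalGenome(esa, 7, 8, "t"), c(8L, 8L))
  expect_null(getIntervalGenome(esa, 7, 8, "g"))
  expect_null(getIntervalGenome(esa, 7, 8, "c"))

  expect_equal(getIntervalDc(esa, 1, 10, "a"), c(1L, 6L))
  expect_equal(getIntervalDc(esa, 1, 10, "c"), c(7L, 8L))
  expect_equal(getIntervalDc(esa, 7, 8, "a"), c(7L, 7L))
  expect_equal(getIntervalDc(esa, 7, 8, "t"), c(8L, 8L))
  expect_null(getIntervalDc(esa, 7, 8, "g"))
  expect_error(getIntervalGenome(esa, 7, 7, "a"), "non-singleton")
})

test_that("search returns the matched prefix length and maximal interval", {
  esa <- exampleEsa
  res <- esaSearch(esa, "aca")
  expect_equal(res@c, 3L)
  expect_equal(c(res@i, res@j), c(3L, 4L))
  res <- esaSearch(esa, "at")
  expect_equal(res@c, 2L)
  expect_equal(c(res@i, res@j), c(5L, 6L))
  res <- esaSearch(esa, "g")
  expect_equal(res@c, 0L)
  expect_equal(c(res@i, res@j), c(1L, 10L)) # root: empty shared prefix
  res <- esaSearch(esa, "ta")
  expect_equal(res@c, 2L)
  expect_equal(c(res@i, res@j), c(10L, 10L))
  # identical under DC-based branch lookup
  for (p in c("aca", "at", "g", "ta", "acg", "acataa")) {
    a <- esaSearch(esa, p, "genome")
    b <- esaSearch(esa, p, "dc")
    expect_equal(c(a@c, a@i, a@j), c(b@c, b@i, b@j), info = p)
  }
})

test_that("locating and counting use full-match semantics", {
  esa <- exampleEsa
  expect_equal(esaLocate(esa, "a"), c(0L, 2L, 3L, 4L, 6L, 8L))
  expect_equal(esaCount(esa, "a"), 6L)
  expect_equal(esaLocate(esa, "at"), c(6L, 8L))
  expect_equal(esaLocate(esa, "g"), integer(0))
  expect_equal(esaCount(esa, "g"), 0L)
  expect_equal(esaLocate(esa, "acg"), integer(0)) # partial match only
  expect_equal(esaCount(esa, "acaaacatat"), 1L)
})

test_that("degenerate and unary genomes search correctly", {
  g0 <- encodeGenome("")
  esa0 <- buildEsa(g0)
  expect_equal(esaCount(esa0, "a"), 0L)
  expect_equal(esaLocate(esa0, "acg"), integer(0))

  g1 <- buildEsa(encodeGenome("aaaaa"))
  expect_equal(esaLocate(g1, "aa"), 0:3)
  expect_equal(esaCount(g1, "aaaaa"), 1L)
  expect_equal(esaCount(g1, "c"), 0L)
  expect_equal(esaSearch(g1, "aac")@c, 2L)
  expect_equal(esaLocate(g1, "aa", variant = "dc"), 0:3)
})

test_that("search equals naive scan for every variant on random genomes", {
  set.seed(606)
  genomes <- testGenomes(10, maxN = 1500, seed = 707)
  for (g in genomes) {
    esa <- buildEsa(g, bucketQ = 2L)
    vs <- lapply(c("esa", "byte", "guide", "dc", "gdi"),
                 function(nm) esaVariant(esa, nm, guideInterval = 64L))
    n <- genomeLength(g)
    present <- sampleQueries(g, sample(c(1:6, 10, 20, 40), 6),
                             2, seed = sample.int(1e6, 1))
    absent <- vapply(seq_len(8), function(z) {
      paste(sample(c("a", "c", "g", "t"), sample(1:12, 1), replace = TRUE),
            collapse = "")
    }, character(1))
    for (p in c(present, absent)) {
      hits <- oracleLocate(g, p)
      maxc <- oracleMaxMatch(g, p)
      base <- esaSearch(esa, p)
      expect_equal(base@c, maxc, info = p)
      for (v in vs) {
        expect_equal(esaLocate(v, p), hits, info = paste(v@name, p))
        expect_equal(esaCount(v, p), length(hits), info = paste(v@name, p))
        r <- esaSearch(v, p)
        expect_equal(c(r@c, r@i, r@j), c(base@c, base@i, base@j),
                     info = paste(v@name, p))
      }
      # bucket-seeded search must agree with the unseeded one
      seeded <- esaSearch(esa, p, useBucket = TRUE)
      expect_equal(c(seeded@c, seeded@i, seeded@j),
                   c(base@c, base@i, base@j), info = p)
      expect_equal(esaLocate(esa, p, useBucket = TRUE), hits, info = p)
      # monotonicity: extending a pattern cannot add matches
      ext <- paste0(p, sample(c("a", "c", "g", "t"), 1))
      expect_lte(esaCount(esa, ext), esaCount(esa, p))
    }
  }
})

test_that("DC-based and genome-based child selection agree everywhere", {
  genomes <- c(list(encodeGenome("acaaacatat")),
               testGenomes(8, maxN = 1000, seed = 808))
  for (g in genomes) {
    esa <- buildEsa(g)
    accG <- esagdi:::.accessorsRaw(esa, "genome")
    accD <- esagdi:::.accessorsRaw(esa, "dc")
    n <- genomeLength(g)
    iv <- lcpIntervals(esa)
    mismatches <- 0L
    for (r in seq_len(nrow(iv))) {
      i <- iv$i[r]; j <- iv$j[r]
      k1 <- esagdi:::.firstLIndex(accG, i, j, isRoot = (r == 1L))
      d <- accG$lcpAt(k1)
      for (p in 1:4) {
        a <- esagdi:::.selectChildGenome(accG, i, j, k1, d, p)
        b <- esagdi:::.selectChildDc(accD, i, j, k1, d, p)
        if (!identical(a, b)) mismatches <- mismatches + 1L
      }
    }
    expect_identical(mismatches, 0L)
  }
})

test_that("search through a saved and reloaded index is identical", {
  g <- synthGenome(600, dupCount = 1, dupLen = 50, seed = 909)
  esa <- buildEsa(g, bucketQ = 2L)
  f <- tempfile(fileext = ".esa")
  saveIndex(esa, f)
  back <- loadIndex(f)
  for (p in sampleQueries(g, c(3, 8, 15), 4, seed = 1)) {
    expect_equal(esaLocate(back, p), esaLocate(esa, p))
    expect_equal(esaCount(back, p, variant = "dc"),
                 esaCount(esa, p, variant = "dc"))
  }
})
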