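test_that("integrated blocks hold LCP, child and DC together", {
  esa <- buildEsa(encodeGenome("acaaacatat"))
  idx <- buildIntegrated(esa)
  expect_length(idx@blocks, 5 * 6) # ceiling(11 / 2) blocks of 5 bytes

  v8 <- integratedGet(idx, 8)
  expect_equal(v8$lcp, 2)
  expect_equal(dcPairDecode(v8$dc), c("a", "t"))

  vn <- integratedGet(idx, 10) # slot n holds Up[n+1] = 1, stored 9
  expect_equal(vn$child, 9)

  expect_equal(integratedGet(idx, 0)$dc, 15) # reserved nibble at index 0
  expect_error(integratedGet(idx, 11), "out of range")

  # odd-tail padding bytes are zero: n = 10 pads index 11
  lastBlock <- as.integer(idx@blocks[26:30])
  expect_equal(lastBlock[c(2, 4)], c(0, 0))
  expect_lt(lastBlock[5], 16) # high nibble of the DC byte is zero
})

test_that("integratedGet equals the separate arrays for all k", {
  genomes <- c(testGenomes(6, maxN = 800, seed = 111),
               list(synthGenome(4000, dupCount = 2, dupLen = 300,
                                seed = 7)))
  for (g in genomes) {
    esa <- buildEsa(g)
    idx <- buildIntegrated(esa, guideInterval = 64L)
    n <- genomeLength(g)
    got <- vapply(0:n, function(k) {
      v <- integratedGet(idx, k)
      c(v$lcp, v$child, v$dc)
    }, numeric(3))
    expect_equal(got[1, ], as.numeric(esa@lcp))
    expect_equal(got[2, ], as.numeric(esa@child@rel))
    expect_equal(got[3, ], as.numeric(esa@dc))
  }
})

test_that("exception-path entries resolve through the guided arrays", {
  g <- synthGenome(4000, dupCount = 2, dupLen = 300, seed = 7)
  esa <- buildEsa(g)
  expect_gte(max(esa@lcp), 255) # the duplication forces LCP exceptions
  idx <- buildIntegrated(esa, guideInterval = 256L)
  expect_gt(length(idx@lcpExcKeys), 0)
  for (k in idx@lcpExcKeys)
    expect_equal(integratedGet(idx, k)$lcp, esa@lcp[k + 1])
  # searches crossing exception entries stay oracle-correct
  for (p in sampleQueries(g, c(8, 260), 5, seed = 3)) {
    hits <- oracleLocate(g, p)
    expect_equal(esaLocate(idx, p, variant = "dc"), hits, info = p)
    for (nm in c("byte", "guide", "dc", "gdi"))
      expect_equal(esaLocate(esaVariant(esa, nm, 256L), p), hits,
                   info = paste(nm, p))
  }
})

test_that("space accounting matches the documented formulas", {
  g <- synthGenome(3000, dupCount = 1, dupLen = 300, seed = 5)
  esa <- buildEsa(g)
  idx <- buildIntegrated(esa)
  sz <- integratedSizeBytes(idx)
  n1 <- genomeLength(g) + 1
  expect_equal(unname(sz["blocks"]), 5 * ceiling(n1 / 2))
  expect_equal(unname(sz["exceptions"]),
               8 * (length(idx@lcpExcKeys) + length(idx@childExcKeys)))
  expect_equal(unname(sz["total"]),
               unname(sz["blocks"] + sz["exceptions"] + sz["guides"]))
})

test_that("index files round-trip byte-identically for both layouts", {
  g <- synthGenome(500, dupCount = 1, dupLen = 40, xRunLen = 4, seed = 13)
  esa <- buildEsa(g, bucketQ = 2L)
  idx <- buildIntegrated(esa, 64L)
  for (x in list(esa, idx)) {
    f <- tempfile(fileext = ".esa")
    saveIndex(x, f)
    back <- loadIndex(f)
    expect_s4_class(back, class(x))
    f2 <- tempfile(fileext = ".esa")
    saveIndex(back, f2)
    expect_identical(readBin(f2, "raw", file.size(f2)),
                     readBin(f, "raw", file.size(f)))
    for (p in c("ac", "gttg", sampleQueries(g, 7, 2, seed = 2)))
      expect_equal(esaLocate(back, p), esaLocate(x, p), info = p)
  }
})

test_that("corrupted index files are rejected", {
  esa <- buildEsa(encodeGenome("acaaacatat"))
  f <- tempfile(fileext = ".esa")
  saveIndex(esa, f)
  r <- readBin(f, "raw", file.size(f))

  bad <- r; bad[1:4] <- charToRaw("XXXX")
  f2 <- tempfile(); writeBin(bad, f2)
  expect_error(loadIndex(f2), "magic")

  bad <- r; bad[30] <- as.raw(bitwXor(as.integer(bad[30]), 255L))
  f3 <- tempfile(); writeBin(bad, f3)
  expect_error(loadIndex(f3))

  f4 <- tempfile(); writeBin(r[1:40], f4)
  expect_error(loadIndex(f4))
})
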