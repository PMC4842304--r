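test_that("suffix array and LCP match the worked example", {
  g <- encodeGenome("acaaacatat")
  sa <- buildSuffixArray(g)
  expect_equal(sa, c(10, 2, 3, 0, 4, 8, 6, 1, 5, 9, 7))
  lcp <- buildLcpArray(g, sa)
  expect_equal(lcp[-1], c(0, 2, 1, 3, 1, 2, 0, 2, 0, 1))
  expect_equal(lcp[9], 2) # LCP[8]

  expect_equal(buildSuffixArray(encodeGenome("")), 0L)
  expect_equal(buildSuffixArray(encodeGenome("aaa")), c(3, 2, 1, 0))
  expect_equal(buildLcpArray(encodeGenome("aaa"),
                             c(3L, 2L, 1L, 0L))[-1], c(0, 1, 2))
})

test_that("suffix array and LCP equal brute-force oracles", {
  for (g in testGenomes(12, maxN = 2000, seed = 101)) {
    sa <- buildSuffixArray(g)
    expect_equal(sa, oracleSuffixArray(g))
    expect_equal(buildLcpArray(g, sa), oracleLcp(g, sa))
  }
  # tiny and degenerate texts
  for (s in c("a", "at", "tttt", "acgt", "aaaaaaaaaa", "axa")) {
    g <- encodeGenome(s)
    sa <- buildSuffixArray(g)
    expect_equal(sa, oracleSuffixArray(g), info = s)
    expect_equal(buildLcpArray(g, sa), oracleLcp(g, sa), info = s)
  }
})

test_that("child array reproduces the worked example's anchored values", {
  esa <- buildEsa(encodeGenome("acaaacatat"))
  n1 <- childAbsolute(esa, 1)
  expect_equal(n1$role, "next")
  expect_equal(n1$value, 7)
  expect_equal(n1$stored, 5) # 7 - 1 - 1 under the subtract-one rule
  n7 <- childAbsolute(esa, 7)
  expect_equal(n7$role, "next")
  expect_equal(n7$value, 9)
  up <- childAbsolute(esa, 10) # slot n holds Up[n+1]
  expect_equal(up$role, "up")
  expect_equal(up$value, 1)
  expect_equal(up$stored, 9) # (11 - 1) - 1
})

test_that("child-array traversal enumerates the brute-force interval tree", {
  g <- encodeGenome("acaaacatat")
  esa <- buildEsa(g)
  expect_equal(sortedIntervals(lcpIntervals(esa)),
               sortedIntervals(oracleIntervalTree(esa@lcp, 10L)))

  for (g in testGenomes(10, maxN = 2000, seed = 202)) {
    esa <- buildEsa(g)
    expect_equal(sortedIntervals(lcpIntervals(esa)),
                 sortedIntervals(oracleIntervalTree(esa@lcp,
                                                    genomeLength(g))))
  }
})

test_that("context-recovered traversal equals the role-tagged traversal", {
  for (g in testGenomes(8, maxN = 1000, seed = 303)) {
    esa <- buildEsa(g)
    rel <- esa@child@rel
    role <- esa@child@role
    acc <- esagdi:::.accessorsRaw(esa)
    iv <- lcpIntervals(esa)
    for (r in seq_len(nrow(iv))) {
      i <- iv$i[r]; j <- iv$j[r]
      isRoot <- i == 1L && j == genomeLength(g) &&
        iv$depth[r] == min(iv$depth[iv$i == i & iv$j == j])
      # tagged: use the role bits directly
      tagged <- if (isRoot) {
        genomeLength(g) - rel[genomeLength(g) + 1L]
      } else if (role[j + 1L] == 3L && j - rel[j + 1L] > i) {
        j - rel[j + 1L]
      } else {
        i + rel[i + 1L] + 1L
      }
      expect_equal(esagdi:::.firstLIndex(acc, i, j, isRoot), tagged)
    }
  }
})

test_that("DC array matches the example and the nibble codec is a bijection", {
  g <- encodeGenome("acaaacatat")
  esa <- buildEsa(g)
  expect_equal(dcPairDecode(dcArray(esa)[9]), c("a", "t")) # DC[8]
  decoded <- vapply(2:11, function(r) {
    paste(dcPairDecode(dcArray(esa)[r]), collapse = "")
  }, character(1))
  expect_equal(decoded, c("$a", "ac", "ac", "at", "ct",
                          "$a", "ac", "at", "ct", "$a"))
  expect_equal(dcArray(esa)[1], 15) # reserved code at index 0

  tab <- dcPairTable()
  expect_equal(nrow(tab), 15)
  expect_equal(paste0(tab$s1, tab$s2),
               c("$a", "$c", "$g", "$t", "$x", "ac", "ag", "at", "ax",
                 "cg", "ct", "cx", "gt", "gx", "tx"))
  expect_equal(dcPairCode("a", "t"), 7)
  expect_equal(dcPairCode("$", "a"), 0)
  for (r in seq_len(nrow(tab)))
    expect_equal(dcPairCode(tab$s1[r], tab$s2[r]), tab$code[r])
  expect_equal(dcPairDecode(7), c("a", "t"))
  expect_error(dcPairCode("t", "a"), "order")
  expect_error(dcPairCode("a", "a"), "order")
  expect_error(dcPairDecode(15), "0..14")
})

test_that("DC pairs are ordered and consistent with brute-force branching", {
  for (g in testGenomes(6, maxN = 800, seed = 404)) {
    esa <- buildEsa(g)
    n <- genomeLength(g)
    codes <- dcArray(esa)[-1]
    expect_true(all(codes >= 0 & codes <= 14))
    s1 <- esagdi:::.DC_S1[codes + 1L]
    s2 <- esagdi:::.DC_S2[codes + 1L]
    expect_true(all(s1 < s2))
    # left characters at the children of each interval = brute branch chars
    iv <- oracleIntervalTree(esa@lcp, n)
    for (r in seq_len(min(nrow(iv), 50L))) {
      branches <- oracleBranchChars(g, esa@sa, esa@lcp,
                                    iv$i[r], iv$j[r])
      vals <- esa@lcp[(iv$i[r] + 1L):iv$j[r] + 1L]
      ls <- ((iv$i[r] + 1L):iv$j[r])[vals == iv$depth[r]]
      expect_equal(sort(s1[ls]), sort(branches[-length(branches)]))
      expect_equal(sort(s2[ls]), sort(branches[-1]))
    }
  }
})

test_that("bucket arrays equal the top-level example and a scan oracle", {
  esa <- buildEsa(encodeGenome("acaaacatat"), bucketQ = 1L)
  expect_equal(bucketInterval(esa@bucket, "a"), c(1L, 6L))
  expect_equal(bucketInterval(esa@bucket, "c"), c(7L, 8L))
  expect_equal(bucketInterval(esa@bucket, "t"), c(9L, 10L))
  gi <- bucketInterval(esa@bucket, "g")
  expect_gt(gi[1], gi[2]) # empty

  for (g in testGenomes(5, maxN = 600, seed = 505)) {
    for (q in c(1L, 2L, 3L)) {
      bucket <- buildBucketArray(buildEsa(g), q)
      s <- genomeString(g)
      sa <- oracleSuffixArray(g)
      qmers <- do.call(paste0,
                       expand.grid(rep(list(c("a", "c", "g", "t")), q)))
      for (w in qmers) {
        pref <- substring(s, sa + 1L, sa + q)
        ranks <- which(pref == w) - 1L # SA indices with this q-mer prefix
        iv <- bucketInterval(bucket, w)
        if (length(ranks) == 0L) expect_gt(iv[1], iv[2])
        else expect_equal(iv, range(ranks))
      }
    }
  }
})

test_that("bucket storage arithmetic and memory guard", {
  b <- bucketStorageBytes(12)
  expect_equal(unname(b["perArray"]), 4^12 * 4)
  expect_equal(unname(b["pair"]), 2 * 4^12 * 4)
  expect_error(buildBucketArray(buildEsa(encodeGenome("acgt")), 14),
               "memory budget")
})
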