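test_that("bytecoding stores small values inline and flags 255 and above", {
  v <- byteGuideEncode(c(3, 1, 4))
  expect_equal(as.integer(v@bytes), c(3, 1, 4))
  expect_length(v@excKeys, 0)

  v2 <- byteGuideEncode(300)
  expect_equal(as.integer(v2@bytes), 255)
  expect_equal(v2@excKeys, 0)
  expect_equal(v2@excValues, 300)
  expect_equal(byteGuideGet(v2, 0), 300)

  # 255 itself is exceptional: only values strictly below 255 fit a byte
  v3 <- byteGuideEncode(255)
  expect_equal(as.integer(v3@bytes), 255)
  expect_equal(v3@excValues, 255)
  expect_equal(byteGuideGet(v3, 0), 255)

  expect_error(byteGuideEncode(-1), "negative")
  expect_error(byteGuideEncode(2^32), "2\\^32")
})

test_that("the guide array bounds the exception search window", {
  vals <- numeric(200)
  vals[c(70, 130) + 1] <- c(1000, 2000)
  v <- byteGuideEncode(vals, guideInterval = 64L)
  # first exception with key >= 0, 64, 128, 192 -> positions 0, 0, 1, 2
  expect_equal(v@guide, c(0, 0, 1, 2, 2))
  # bucket 1 covers keys [64, 128): the window for key 70 holds only key 70
  g <- 70 %/% 64
  win <- (v@guide[g + 1] + 1):v@guide[g + 2]
  expect_equal(v@excKeys[win], 70)
  expect_equal(byteGuideGet(v, c(70, 130, 0)), c(1000, 2000, 0))

  # definition check on random exception layouts
  set.seed(31)
  for (rep in 1:5) {
    vals <- sample(c(0:254, 255:5000), 3000, replace = TRUE)
    v <- byteGuideEncode(vals, guideInterval = 256L)
    for (g in seq_along(v@guide) - 1L) {
      if (g == length(v@guide) - 1L) break
      expect_equal(v@guide[g + 1L], sum(v@excKeys < g * 256),
                   info = paste("bucket", g))
    }
  }
})

test_that("bytecoded vectors decode to the source exactly", {
  set.seed(7)
  cases <- list(
    numeric(0),
    rep(0, 100),
    rep(1e6, 130),
    rep(c(3, 1e5), 100),
    sample(0:300, 1000, replace = TRUE),
    c(sample(0:254, 9000, replace = TRUE),
      sample(255:4e6, 1000, replace = TRUE))[sample.int(10000)])
  for (vals in cases) {
    for (gi in list(NULL, 64L, 1024L)) {
      v <- byteGuideEncode(vals, gi)
      if (length(vals) > 0)
        expect_equal(byteGuideGet(v, seq_along(vals) - 1L), vals)
      expect_equal(unname(bgvSizeBytes(v)["total"]),
                   length(vals) + 8 * length(v@excKeys) +
                     4 * length(v@guide))
    }
  }
})

test_that("BP64 blocks use the smallest even width and round-trip", {
  z <- bp64Encode(numeric(64))
  expect_equal(z@widths, 2L)
  expect_equal(bp64Get(z, 0:63), numeric(64))

  big <- bp64Encode(c(numeric(10), 2^32 - 1))
  expect_equal(big@widths, 32L)
  expect_equal(bp64Get(big, 10), 2^32 - 1)

  expect_equal(bp64Encode(rep(3, 64))@widths, 2L)
  expect_equal(bp64Encode(rep(4, 64))@widths, 4L)

  set.seed(17)
  cases <- list(
    sample(0:1e6, 1000, replace = TRUE),
    rep(c(0, 2^31), 64),
    sample(0:3, 200, replace = TRUE),
    c(2^32 - 1, numeric(63), 2^32 - 1),
    sample(0:50, 67, replace = TRUE)) # non-multiple of 64
  for (vals in cases) {
    v <- bp64Encode(vals)
    expect_equal(bp64Get(v, seq_along(vals) - 1L), vals)
  }
  expect_error(bp64Get(bp64Encode(1:10), 10), "out of range")
})

test_that("serialization round-trips bit-exactly and rejects corruption", {
  set.seed(23)
  vals <- c(sample(0:300, 500, replace = TRUE), 2^31 + 5)
  for (vec in list(byteGuideEncode(vals, 64L), byteGuideEncode(vals, NULL),
                   bp64Encode(vals))) {
    r <- serializeVector(vec)
    back <- deserializeVector(r)
    getter <- if (is(vec, "BP64Vector")) bp64Get else byteGuideGet
    expect_equal(getter(back, seq_along(vals) - 1L), vals)
    expect_identical(serializeVector(back), r)
  }

  empty <- serializeVector(byteGuideEncode(numeric(0)))
  expect_equal(bgvLength(deserializeVector(empty)), 0)
  expect_equal(bp64Length(deserializeVector(
    serializeVector(bp64Encode(numeric(0))))), 0)

  r <- serializeVector(byteGuideEncode(vals))
  bad <- r
  bad[1:4] <- charToRaw("NOPE")
  expect_error(deserializeVector(bad), "magic")
  expect_error(deserializeVector(r[1:20]), "truncated")
})
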