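worked <- list(
  euclidean = sqrt(3), euclidean_sq = 3, manhattan = 3,
  canberra = 1 + 1 / 3 + 1 / 3, braycurtis = 1 / 3, jaccard = 0.25,
  hamming_binary = 1, google = (log(5) - log(3)) / (log(9) - log(4)),
  d2_cosine = 1 - 5 / 6)

test_that("every metric reproduces its hand-derived value on the worked vectors", {
  cv <- figureVectors("count")
  for (m in names(worked))
    expect_equal(wordDistance(m, cv$x, cv$y), worked[[m]], tolerance = 1e-12,
                 info = m)
  expect_equal(d2Similarity(cv$x, cv$y), 5)
})

test_that("self-distance is zero and pairs are symmetric for every metric", {
  cv <- figureVectors("count")
  for (m in setdiff(listMetrics()$name, "pearson")) {
    expect_identical(wordDistance(m, cv$y, cv$y), 0, info = m)
    expect_equal(wordDistance(m, cv$x, cv$y), wordDistance(m, cv$y, cv$x),
                 info = m)
  }
  expect_identical(wordDistance("pearson", cv$x, cv$x), 0)
})

test_that("degenerate inputs raise the documented errors", {
  cv <- figureVectors("count")
  expect_error(wordDistance("pearson", cv$x, cv$y), "constant")
  z <- rawVectorPair(c(0, 0, 0), c(1, 2, 0))
  expect_error(wordDistance("google", z$u, z$v), "all-zero")
  expect_error(wordDistance("d2_cosine", z$u, z$v), "all-zero")
  zz <- rawVectorPair(c(0, 0, 0), c(0, 0, 0))
  expect_error(wordDistance("braycurtis", zz$u, zz$v), "all-zero")
  freq <- figureVectors("frequency")
  expect_error(wordDistance("euclidean", cv$x, freq$y), "mix modes")
  expect_error(wordDistance("google", freq$x, freq$y), "count-mode")
  shifted <- rawVectorPair(1:4, 4:1)
  expect_error(wordDistance("euclidean", cv$x, shifted$u),
               "different vocabularies")
  expect_error(wordDistance("nope", cv$x, cv$y), "unknown metric")
})

test_that("metrics agree with direct-summation oracles on random pairs", {
  set.seed(101)
  for (rep in 1:200) {
    len <- sample(3:30, 1)
    x <- rpois(len, 2)
    y <- rpois(len, 2)
    if (sum(x) == 0 || sum(y) == 0 || sd(x) == 0 || sd(y) == 0) next
    pr <- rawVectorPair(x, y)
    for (m in listMetrics()$name) {
      got <- tryCatch(wordDistance(m, pr$u, pr$v), error = function(e) NULL)
      want <- oracleMetric(m, x, y)
      if (is.null(got) || !is.finite(want)) next
      expect_equal(got, want, tolerance = 1e-12, info = m)
    }
  }
})

test_that("distances match the field-standard implementations", {
  skip_if_not_installed("vegan")
  set.seed(7)
  for (rep in 1:25) {
    x <- rpois(12, 1.5); y <- rpois(12, 1.5)
    if (sum(x) == 0 || sum(y) == 0) next
    pr <- rawVectorPair(x, y)
    M <- rbind(x, y)
    expect_equal(wordDistance("euclidean", pr$u, pr$v),
                 as.numeric(dist(M)), tolerance = 1e-12)
    expect_equal(wordDistance("manhattan", pr$u, pr$v),
                 as.numeric(dist(M, "manhattan")), tolerance = 1e-12)
    expect_equal(wordDistance("braycurtis", pr$u, pr$v),
                 as.numeric(vegan::vegdist(M, "bray")), tolerance = 1e-12)
    nz <- sum(x + y > 0)
    expect_equal(wordDistance("canberra", pr$u, pr$v),
                 as.numeric(vegan::vegdist(M, "canberra")) * nz,
                 tolerance = 1e-12)
    expect_equal(wordDistance("jaccard", pr$u, pr$v),
                 as.numeric(dist(rbind(x > 0, y > 0), "binary")),
                 tolerance = 1e-12)
    if (sd(x) > 0 && sd(y) > 0)
      expect_equal(wordDistance("pearson", pr$u, pr$v), 1 - cor(x, y),
                   tolerance = 1e-12)
  }
})

test_that("distances are invariant under a consistent vocabulary permutation", {
  set.seed(13)
  x <- rpois(10, 2) + 1; y <- rpois(10, 2) + 1
  pr <- rawVectorPair(x, y)
  perm <- sample(10)
  # re-sorting the permuted words restores sorted order with entries moved
  prP <- rawVectorPair(x[perm], y[perm])
  for (m in listMetrics()$name)
    expect_equal(wordDistance(m, pr$u, pr$v),
                 wordDistance(m, prP$u, prP$v), tolerance = 1e-12, info = m)
})

test_that("triangle inequality holds for the metric subset", {
  set.seed(19)
  for (rep in 1:60) {
    x <- rpois(8, 1.5); y <- rpois(8, 1.5); z <- rpois(8, 1.5)
    tri <- rawVectorPair(x, y); trz <- rawVectorPair(y, z); txz <- rawVectorPair(x, z)
    for (m in c("euclidean", "manhattan", "hamming_binary", "jaccard")) {
      dxy <- wordDistance(m, tri$u, tri$v)
      dyz <- wordDistance(m, trz$u, trz$v)
      dxz <- wordDistance(m, txz$u, txz$v)
      expect_lte(dxz, dxy + dyz + 1e-12)
    }
  }
})
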