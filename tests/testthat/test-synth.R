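test_that("random sequences honour length, alphabet, seed, and composition", {
  s <- randomSequence(7, "DNA", seed = 1)
  expect_identical(nchar(unname(as.character(s))), 7L)
  expect_true(all(strsplit(as.character(s), "")[[1L]] %in%
                    c("A", "C", "G", "T")))
  expect_identical(as.character(randomSequence(7, "DNA", seed = 1)),
                   as.character(s))
  big <- as.character(randomSequence(10000, "DNA", seed = 2))
  freqs <- table(strsplit(big, "")[[1L]]) / 10000
  expect_true(all(abs(freqs - 0.25) < 0.02))   # binomial 99% band
  expect_error(randomSequence(0), ">= 1")
})

test_that("evolution without divergence is the identity", {
  root <- randomSequence(100, "DNA", seed = 3)
  ev <- evolveSequences(root, 2, pSub = 0, pIndel = 0)
  expect_true(all(as.character(ev$sequences) == as.character(root)))
  expect_identical(length(ev$sequences), 4L)
  expect_s3_class(ev$tree, "phylo")
})

test_that("per-branch substitutions are Binomial(L, pSub)", {
  root <- randomSequence(5000, "DNA", seed = 5)
  ev <- evolveSequences(root, 1, pSub = 0.1)   # two single-branch leaves
  rootChars <- strsplit(as.character(root), "")[[1L]]
  for (leaf in as.character(ev$sequences)) {
    mm <- sum(strsplit(leaf, "")[[1L]] != rootChars)
    sigma <- sqrt(5000 * 0.1 * 0.9)
    expect_lt(abs(mm - 500), 3 * sigma)
  }
})

test_that("divergence grows with path length (sisters closer than cousins)", {
  sister <- numeric(20); cross <- numeric(20)
  for (r in 1:20) {
    root <- randomSequence(500, "DNA", seed = 600 + r)
    ev <- evolveSequences(root, 2, pSub = 0.05)
    M <- as.matrix(buildDistanceMatrix(ev$sequences, 2, "euclidean",
                                       mode = "frequency"))
    sister[r] <- (M["t1", "t2"] + M["t3", "t4"]) / 2    # 2 branches apart
    cross[r] <- mean(M[c("t1", "t2"), c("t3", "t4")])   # 4 branches apart
  }
  expect_gt(mean(cross), mean(sister))
  expect_gt(mean(cross > sister), 0.85)
})

test_that("indels change lengths with the configured geometry", {
  root <- randomSequence(2000, "DNA", seed = 6)
  ev <- evolveSequences(root, 1, pSub = 0, pIndel = 0.01, indelMean = 3,
                        seed = 7)
  lens <- nchar(as.character(ev$sequences))
  expect_true(any(lens != 2000))
  expect_true(all(abs(lens - 2000) < 200))
})

test_that("rearrangements preserve what they must", {
  set.seed(111)
  s <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")

  sh <- applyRearrangement(s, "block_shuffle", blockSize = 20, seed = 8)
  p1 <- extractWordCounts(s, 1); p2 <- extractWordCounts(sh, 1)
  v <- unionVocabulary(list(p1, p2))
  expect_identical(vectorEntries(toCountVector(p1, v)),
                   vectorEntries(toCountVector(p2, v)))

  sw <- applyRearrangement(s, "segment_swap", seg1 = c(10, 30),
                           seg2 = c(100, 150))
  expect_identical(sort(strsplit(sw, "")[[1L]]), sort(strsplit(s, "")[[1L]]))
  expect_identical(nchar(sw), nchar(s))

  donor <- paste(rep("A", 50), collapse = "")
  lt <- applyRearrangement(s, "lateral_transfer", target = c(20, 40),
                           donor = donor, donorInterval = c(0, 30))
  expect_identical(substr(lt, 21, 50), paste(rep("A", 30), collapse = ""))
  expect_identical(substr(lt, 1, 20), substr(s, 1, 20))

  expect_error(applyRearrangement(s, "segment_swap", seg1 = c(10, 30),
                                  seg2 = c(20, 50)), "overlap")
  expect_error(applyRearrangement(s, "segment_swap", seg1 = c(10, 300),
                                  seg2 = c(0, 5)), "outside")
  expect_error(applyRearrangement(s, "lateral_transfer", target = c(5, 5),
                                  donor = donor, donorInterval = c(0, 10)),
               "outside|empty")
})

test_that("word profiles are robust to block shuffling (k = 1-2)", {
  probs <- c(0.4, 0.3, 0.2, 0.1)
  for (r in 1:50) {
    set.seed(300 + r)
    s <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE, prob = probs),
               collapse = "")
    sh <- applyRearrangement(s, "block_shuffle", blockSize = 500)
    ind <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE, prob = probs),
                 collapse = "")
    ss <- SequenceSet(c(a = s, b = sh, c = ind))
    for (k in 1:2) {
      M <- as.matrix(buildDistanceMatrix(ss, k, "euclidean"))
      expect_lt(M["a", "b"], 0.1 * M["a", "c"])
    }
  }
})

test_that("hierarchies are nested, labelled, and byte-deterministic", {
  cfg <- hierarchyConfig(seed = 12, rootLength = 300)
  ds <- makeHierarchy(cfg)
  expect_identical(length(ds), 2L * 2L * 2L * 2L * 2L)
  expect_identical(levelNames(ds),
                   c("class", "fold", "superfamily", "family"))
  lb <- datasetLabels(ds)
  for (j in 2:4) {
    nested <- tapply(lb[[j - 1L]], lb[[j]], function(z) length(unique(z)))
    expect_true(all(nested == 1L))
  }
  ds2 <- makeHierarchy(hierarchyConfig(seed = 12, rootLength = 300))
  expect_identical(as.character(datasetSequences(ds2)),
                   as.character(datasetSequences(ds)))
  f1 <- tempfile(); f2 <- tempfile()
  writeFasta(datasetSequences(ds), f1)
  writeFasta(datasetSequences(ds2), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("hierarchy configuration is validated", {
  expect_error(hierarchyConfig(), "mandatory")
  expect_error(hierarchyConfig(seed = 1, branching = c(1L, 2L, 2L, 2L)),
               ">= 2")
  expect_error(hierarchyConfig(seed = 1, pSub = c(0.2, 0.05, 0.1, 0.3)),
               "decrease")
  expect_error(hierarchyConfig(seed = 1, pWithin = 1.5), "\\[0, 1\\]")
  expect_error(hierarchyConfig(seed = 1, levelNames = "only"), "2 hierarchy")
})
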