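test_that("distance matrices over sequence sets match the pairwise measures", {
  s <- figureSequences()
  D <- buildDistanceMatrix(s, 3, "euclidean")
  expect_equal(as.matrix(D),
               matrix(c(0, sqrt(3), sqrt(3), 0), 2, 2,
                      dimnames = list(c("x", "y"), c("x", "y"))),
               tolerance = 1e-12)
  same <- SequenceSet(c(a = "ATGTGTG", b = "ATGTGTG", c = "ATGTGTG"))
  expect_true(all(as.matrix(buildDistanceMatrix(same, 3)) == 0))
  expect_error(buildDistanceMatrix(s[1], 3), "at least 2")
  expect_error(buildDistanceMatrix(s, 7), "'y'")
  expect_error(buildDistanceMatrix(s, 3, "nope"), "unknown method")
  # kl and ncd are usable as matrix methods too
  expect_gt(as.matrix(buildDistanceMatrix(s, 3, "kl"))[1, 2], 0)
  expect_equal(as.matrix(buildDistanceMatrix(s, 3, "ncd"))[1, 2], 0.2)
})

test_that("NJ recovers the worked additive examples exactly", {
  lab <- c("A", "B", "C", "D")
  M <- matrix(0, 4, 4, dimnames = list(lab, lab))
  M["A", "B"] <- 3; M["A", "C"] <- 5; M["A", "D"] <- 6
  M["B", "C"] <- 6; M["B", "D"] <- 7; M["C", "D"] <- 7
  M <- M + t(M)
  expect_true(fourPointHolds(M))
  tr <- njTree(DistanceMatrix(M))
  expect_equal(ape::cophenetic.phylo(tr)[lab, lab], M, tolerance = 1e-9)
  expect_identical(names(treeBipartitions(tr)), paste("C", "D", sep = "\t"))
  expect_equal(sort(tr$edge.length), c(1, 1, 2, 3, 4), tolerance = 1e-9)

  M3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
               dimnames = list(lab[1:3], lab[1:3]))
  expect_equal(sort(njTree(DistanceMatrix(M3))$edge.length),
               c(0.5, 1.5, 2.5), tolerance = 1e-9)

  M2 <- matrix(c(0, 5, 5, 0), 2, 2, dimnames = list(lab[1:2], lab[1:2]))
  t2 <- njTree(DistanceMatrix(M2))
  expect_equal(unname(ape::cophenetic.phylo(t2)["A", "B"]), 5)
})

test_that("NJ reproduces random additive matrices (path lengths, 1e-9)", {
  for (seed in 1:8) {
    ad <- randomAdditive(sample(4:8, 1), seed = 400 + seed)
    M <- as.matrix(ad$D)
    expect_true(fourPointHolds(M))
    tr <- njTree(ad$D)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(M), colnames(M)], M,
                 tolerance = 1e-9)
    expect_identical(robinsonFoulds(tr, ad$tree), 0L)
  }
  bad <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(njTree(bad), "symmetric")
  neg <- matrix(c(0, -1, -1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(njTree(neg), "non-negative")
})

test_that("UPGMA agglomeration is ultrametric with the expected heights", {
  lab <- c("A", "B", "C")
  M <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3, dimnames = list(lab, lab))
  tu <- upgmaTree(DistanceMatrix(M))
  cp <- ape::cophenetic.phylo(tu)
  expect_equal(cp[lab, lab], M, tolerance = 1e-9)      # ((A:1,B:1):1,C:2)
  expect_equal(sort(tu$edge.length), c(1, 1, 1, 2), tolerance = 1e-9)

  eq <- matrix(3, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(eq) <- 0
  te <- upgmaTree(DistanceMatrix(eq))
  depths <- ape::node.depth.edgelength(te)[1:4]
  expect_equal(max(depths) - min(depths), 0, tolerance = 1e-9)

  t2 <- upgmaTree(DistanceMatrix(matrix(c(0, 4, 4, 0), 2, 2,
                                        dimnames = list(c("a", "b"),
                                                        c("a", "b")))))
  expect_equal(t2$edge.length, c(2, 2))

  set.seed(51)
  for (rep in 1:5) {
    n <- sample(4:8, 1)
    M <- as.matrix(dist(matrix(rnorm(n * 3), n)))
    dimnames(M) <- list(paste0("t", 1:n), paste0("t", 1:n))
    tu <- upgmaTree(DistanceMatrix(M))
    depths <- ape::node.depth.edgelength(tu)[1:n]
    expect_equal(max(depths) - min(depths), 0, tolerance = 1e-9)
  }
})

test_that("majority consensus keeps exactly the >threshold splits with supports", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")

  same <- majorityConsensus(list(t1, t1, t1))
  expect_identical(robinsonFoulds(same, t1), 0L)
  sup <- as.numeric(same$node.label[nzchar(same$node.label)])
  expect_true(all(sup == 1))

  cons <- majorityConsensus(list(t1, t1, t2))
  expect_identical(names(treeBipartitions(cons)), paste("C", "D", sep = "\t"))
  expect_identical(cons$node.label[nzchar(cons$node.label)], "0.667")

  star <- majorityConsensus(list(t1, t2))
  expect_identical(length(treeBipartitions(star)), 0L)

  t3 <- ape::read.tree(text = "((A,B),(C,E));")
  expect_error(majorityConsensus(list(t1, t3)), "mismatch")
})

test_that("consensus supports equal brute-force bipartition frequencies", {
  skip_if_not_installed("phangorn")
  set.seed(61)
  for (rep in 1:5) {
    trees <- replicate(7, ape::rtree(6, br = NULL), simplify = FALSE)
    cons <- majorityConsensus(trees)
    splits <- treeBipartitions(cons)
    sup <- as.numeric(cons$node.label[nzchar(cons$node.label)])
    # oracle: count each consensus split across trees with phangorn splits
    for (i in seq_along(splits)) {
      block <- splits[[i]]
      count <- sum(vapply(trees, function(t) {
        sp <- phangorn::as.splits(t)
        labs <- attr(sp, "labels")
        any(vapply(sp, function(ix) {
          b <- sort(labs[ix])
          setequal(b, block) || setequal(labs[-ix], block)
        }, logical(1L)))
      }, logical(1L)))
      expect_gt(count / length(trees), 0.5)
      expect_identical(sprintf("%.3f", count / length(trees)),
                       sprintf("%.3f", sup[i]))
    }
  }
})

test_that("Robinson-Foulds counts the split symmetric difference", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_identical(robinsonFoulds(t1, t1), 0L)
  expect_identical(robinsonFoulds(t1, t2), 2L)
  expect_error(robinsonFoulds(t1, ape::read.tree(text = "((A,B),(C,E));")),
               "different leaf")
  skip_if_not_installed("phangorn")
  set.seed(71)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    a <- ape::rtree(n, br = NULL); b <- ape::rtree(n, br = NULL)
    expect_identical(robinsonFoulds(a, b),
                     as.integer(phangorn::RF.dist(a, b)))
    expect_lte(robinsonFoulds(a, b), 2L * (n - 3L))
  }
})

test_that("PHYLIP output is the square 10-character format", {
  D <- buildDistanceMatrix(figureSequences(), 3, "euclidean")
  f <- tempfile()
  writePhylip(D, f)
  expect_identical(readLines(f),
                   c("2",
                     "x          0.000000 1.732051",
                     "y          1.732051 0.000000"))
  lab <- c("averylongname1", "averylongname2")
  clash <- DistanceMatrix(matrix(c(0, 1, 1, 0), 2, 2,
                                 dimnames = list(lab, lab)))
  expect_error(writePhylip(clash, f), "collide")
})

test_that("Newick output round-trips through a standard parser", {
  ad <- randomAdditive(6, seed = 99)
  tr <- njTree(ad$D)
  f <- tempfile()
  writeNewick(tr, f)
  back <- ape::read.tree(f)
  expect_identical(robinsonFoulds(tr, back), 0L)
  expect_equal(sort(back$edge.length), sort(round(tr$edge.length, 6)),
               tolerance = 1e-9)

  cons <- majorityConsensus(list(ape::read.tree(text = "((A,B),(C,D));"),
                                 ape::read.tree(text = "((A,B),(C,D));"),
                                 ape::read.tree(text = "((A,C),(B,D));")))
  writeNewick(cons, f)
  line <- readLines(f)
  expect_match(line, "0\\.667")
  expect_match(line, ";$")
  back <- ape::read.tree(f)
  expect_identical(robinsonFoulds(cons, back), 0L)
  expect_identical(sort(back$node.label), sort(cons$node.label))

  single <- list(edge = matrix(nrow = 0, ncol = 2), tip.label = "A",
                 Nnode = 0L)
  class(single) <- "phylo"
  expect_error(writeNewick(single, f), "fewer than 2")
})
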