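# Shared fixtures and independent oracles. Oracles are deliberately written
# as plain, slow loops so they share no code path with the implementation.

figureSequences <- function() SequenceSet(c(x = "ATGTGTG", y = "CATGTG"))

figureVectors <- function(mode = "count") {
  ps <- extractWordCounts(figureSequences(), 3)
  v <- unionVocabulary(ps)
  lapply(ps, toCountVector, vocab = v, mode = mode)
}

writeTempFasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

# direct-summation oracles for every registry metric, on raw numeric vectors
oracleMetric <- function(metric, x, y) {
  switch(metric,
    euclidean = {
      s <- 0
      for (i in seq_along(x)) s <- s + (x[i] - y[i])^2
      sqrt(s)
    },
    euclidean_sq = {
      s <- 0
      for (i in seq_along(x)) s <- s + (x[i] - y[i])^2
      s
    },
    manhattan = {
      s <- 0
      for (i in seq_along(x)) s <- s + abs(x[i] - y[i])
      s
    },
    canberra = {
      s <- 0
      for (i in seq_along(x))
        if (x[i] + y[i] > 0) s <- s + abs(x[i] - y[i]) / (x[i] + y[i])
      s
    },
    braycurtis = {
      num <- 0; den <- 0
      for (i in seq_along(x)) {
        num <- num + abs(x[i] - y[i])
        den <- den + x[i] + y[i]
      }
      num / den
    },
    jaccard = {
      inter <- 0; un <- 0
      for (i in seq_along(x)) {
        if (x[i] > 0 && y[i] > 0) inter <- inter + 1
        if (x[i] > 0 || y[i] > 0) un <- un + 1
      }
      if (un == 0) 0 else 1 - inter / un
    },
    hamming_binary = {
      s <- 0
      for (i in seq_along(x)) if ((x[i] > 0) != (y[i] > 0)) s <- s + 1
      s
    },
    google = {
      fu <- sum(x); fv <- sum(y)
      fuv <- 0
      for (i in seq_along(x)) fuv <- fuv + min(x[i], y[i])
      (max(log(fu), log(fv)) - log(fuv)) /
        (log(fu + fv) - min(log(fu), log(fv)))
    },
    pearson = {
      mx <- mean(x); my <- mean(y)
      num <- sum((x - mx) * (y - my))
      1 - num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
    },
    d2_cosine = {
      ip <- 0
      for (i in seq_along(x)) ip <- ip + x[i] * y[i]
      1 - ip / (sqrt(sum(x^2)) * sqrt(sum(y^2)))
    },
    stop("no oracle for ", metric))
}

# build a CountVector pair over a dummy vocabulary from raw entries
rawVectorPair <- function(x, y, mode = "count") {
  words <- sprintf("w%03d", seq_along(x))  # same length, sorted
  vocab <- new("Vocabulary", k = 4L, words = words)
  list(u = new("CountVector", seqId = "u", vocabulary = vocab,
               entries = as.numeric(x), mode = mode),
       v = new("CountVector", seqId = "v", vocabulary = vocab,
               entries = as.numeric(y), mode = mode))
}

# naive O(n^3) exhaustive-history parser: explicit position-by-position
# substring comparison, no regex/grepl
naiveLZ <- function(s) {
  n <- nchar(s)
  comp <- 0L
  i <- 1L
  while (i <= n) {
    j <- i
    repeat {
      len <- j - i + 1L
      w <- substr(s, i, j)
      found <- FALSE
      if (j > 1L && j - 1L >= len) {
        for (st in 1L:(j - len)) {
          if (substr(s, st, st + len - 1L) == w) {
            found <- TRUE
            break
          }
        }
      }
      if (!found) {
        comp <- comp + 1L
        i <- j + 1L
        break
      }
      if (j == n) {
        comp <- comp + 1L
        i <- n + 1L
        break
      }
      j <- j + 1L
    }
  }
  comp
}

# brute-force AUC over all positive x negative pairs
bruteAUC <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg) {
    if (p < q) wins <- wins + 1
    else if (p == q) wins <- wins + 0.5
  }
  wins / (length(pos) * length(neg))
}

# random additive distance matrix from a random binary tree; returns the
# matrix and the generating tree
randomAdditive <- function(ntaxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(ntaxa, br = function(n) stats::runif(n, 0.2, 1.5))
  tr <- ape::unroot(tr)
  D <- ape::cophenetic.phylo(tr)
  o <- sort(rownames(D))
  list(D = DistanceMatrix(D[o, o]), tree = tr)
}

# exhaustive four-point condition check (oracle for additivity)
fourPointHolds <- function(M, tol = 1e-9) {
  n <- nrow(M)
  for (q in utils::combn(n, 4, simplify = FALSE)) {
    i <- q[1]; j <- q[2]; k <- q[3]; l <- q[4]
    sums <- sort(c(M[i, j] + M[k, l], M[i, k] + M[j, l], M[i, l] + M[j, k]))
    if (abs(sums[2] - sums[3]) > tol) return(FALSE)
  }
  TRUE
}
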