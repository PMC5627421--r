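## Seeded simulator of sequence families: i.i.d. root sequences, per-branch
## substitution/indel divergence along a guide topology, optional
## rearrangements, and a nested multi-level hierarchy generator that stands
## in for structurally classified benchmark data. All functions draw from
## R's global RNG in a fixed, documented order, so a single set.seed() call
## (or the `seed` arguments) makes every output byte-identical across runs.

.alphabetSymbols <- function(alphabet) {
  if (!alphabet %in% names(.CORE_ALPHABETS))
    stop(sprintf("unsupported simulation alphabet '%s'", alphabet))
  .CORE_ALPHABETS[[alphabet]]
}

#' Random i.i.d. sequence
#'
#' @param L Sequence length (>= 1).
#' @param alphabet `"DNA"`, `"RNA"` or `"protein"`.
#' @param seed Optional integer seed (sets the global RNG).
#' @param id Sequence id.
#' @param probs Optional symbol probabilities (default uniform); used by
#'   the hierarchy generator to give top-level families distinct
#'   compositional signatures.
#' @return A single-sequence [SequenceSet-class].
#' @export
randomSequence <- function(L, alphabet = "DNA", seed = NULL, id = "seq1",
                           probs = NULL) {
  if (!is.numeric(L) || L < 1) stop("sequence length must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  symbols <- .alphabetSymbols(alphabet)
  if (!is.null(probs)) stopifnot(length(probs) == length(symbols))
  s <- paste(sample(symbols, as.integer(L), replace = TRUE, prob = probs),
             collapse = "")
  SequenceSet(stats::setNames(s, id), alphabet = alphabet)
}

## Substitutions first (each site independently with prob pSub, to a
## uniformly chosen *different* symbol), then indels (each site with prob
## pIndel starts an insertion or deletion, 50/50, of geometric length with
## mean indelMean, applied right to left so coordinates stay valid).
.mutateResidues <- function(s, symbols, pSub, pIndel = 0, indelMean = 3,
                            replProbs = NULL) {
  chars <- strsplit(s, "")[[1L]]
  n <- length(chars)
  if (pSub > 0) {
    hit <- stats::runif(n) < pSub
    m <- sum(hit)
    if (m > 0) {
      if (is.null(replProbs)) {
        ## neutral model: uniform over the other symbols
        pos <- match(chars[hit], symbols)
        shift <- sample.int(length(symbols) - 1L, m, replace = TRUE)
        chars[hit] <- symbols[((pos - 1L + shift) %% length(symbols)) + 1L]
      } else {
        ## biased model: replacements drawn from a lineage-specific
        ## attractor distribution (compositional drift, GC-bias-like)
        chars[hit] <- sample(symbols, m, replace = TRUE, prob = replProbs)
      }
    }
  }
  if (pIndel > 0) {
    sites <- which(stats::runif(length(chars)) < pIndel)
    for (site in rev(sites)) {
      len <- stats::rgeom(1L, prob = 1 / indelMean) + 1L
      if (stats::runif(1L) < 0.5) {  # insertion after `site`
        ins <- sample(symbols, len, replace = TRUE)
        chars <- append(chars, ins, after = site)
      } else {                        # deletion starting at `site`
        last <- min(site + len - 1L, length(chars))
        if (last - site + 1L < length(chars))  # never delete everything
          chars <- chars[-(site:last)]
      }
    }
  }
  paste(chars, collapse = "")
}

.balancedNewick <- function(depth, branchLength) {
  counter <- 0L
  f <- function(d) {
    if (d == 0L) {
      counter <<- counter + 1L
      return(sprintf("t%d:%g", counter, branchLength))
    }
    sprintf("(%s,%s):%g", f(d - 1L), f(d - 1L), branchLength)
  }
  body <- sprintf("(%s,%s);", f(depth - 1L), f(depth - 1L))
  ape::read.tree(text = body)
}

#' Evolve a root sequence along a guide topology
#'
#' Along every branch, each site is independently substituted with
#' probability `pSub` (to a uniformly chosen different symbol) and then
#' indels are applied with per-site probability `pIndel` (geometric
#' lengths, mean `indelMean`). Branches are processed depth-first in
#' pre-order, so a fixed seed reproduces the leaves exactly.
#'
#' @param root A single-sequence [SequenceSet-class] (or residue string).
#' @param topology Either an integer depth (balanced binary tree with
#'   `2^depth` leaves, tips `t1..t2^depth`) or a `phylo` tree whose every
#'   branch receives the same `pSub`/`pIndel`.
#' @param pSub Per-branch, per-site substitution probability.
#' @param pIndel Per-branch, per-site indel probability.
#' @param indelMean Mean geometric indel length.
#' @param seed Optional integer seed.
#' @return List with `sequences` (a [SequenceSet-class] of the leaves, in
#'   tip order) and `tree` (the generating topology as a `phylo`).
#' @export
evolveSequences <- function(root, topology, pSub, pIndel = 0, indelMean = 3,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (any(c(pSub, pIndel) < 0) || any(c(pSub, pIndel) > 1))
    stop("substitution and indel probabilities must be in [0, 1]")
  if (is(root, "SequenceSet")) {
    alphabet <- alphabetType(root)
    rootSeq <- unname(as.character(root))
  } else {
    rootSeq <- as.character(root)
    alphabet <- .detectAlphabet(rootSeq)
  }
  symbols <- .alphabetSymbols(alphabet)
  phy <- if (inherits(topology, "phylo")) topology
         else .balancedNewick(as.integer(topology), pSub)
  ntip <- length(phy$tip.label)
  children <- split(phy$edge[, 2L], phy$edge[, 1L])
  rootNode <- setdiff(unique(phy$edge[, 1L]), phy$edge[, 2L])
  leaves <- character(ntip)
  walk <- function(node, s) {
    if (node <= ntip) {
      leaves[node] <<- s
      return(invisible(NULL))
    }
    for (ch in sort(children[[as.character(node)]]))
      walk(ch, .mutateResidues(s, symbols, pSub, pIndel, indelMean))
    invisible(NULL)
  }
  walk(rootNode, rootSeq)
  list(sequences = SequenceSet(leaves, ids = phy$tip.label,
                               alphabet = alphabet),
       tree = phy)
}

#' Apply a rearrangement to a sequence
#'
#' Coordinates are 0-based, half-open `[start, end)`. `block_shuffle`
#' permutes consecutive equal-length blocks (a trailing partial block stays
#' in place), `segment_swap` exchanges two non-overlapping segments, and
#' `lateral_transfer` replaces the target segment with a donor segment
#' verbatim. The first two preserve the residue multiset exactly.
#'
#' @param x Residue string or single-sequence [SequenceSet-class].
#' @param op `"block_shuffle"`, `"segment_swap"` or `"lateral_transfer"`.
#' @param blockSize Block length for `block_shuffle`.
#' @param seg1,seg2 Length-2 integer vectors `c(start, end)` for
#'   `segment_swap`; must not overlap.
#' @param target Length-2 `c(start, end)` replaced by `lateral_transfer`.
#' @param donor Donor residue string (or single-sequence set).
#' @param donorInterval Length-2 `c(start, end)` within the donor.
#' @param seed Optional integer seed (`block_shuffle` draws the block
#'   permutation from the RNG).
#' @return Object of the same type as `x`.
#' @export
applyRearrangement <- function(x,
                               op = c("block_shuffle", "segment_swap",
                                      "lateral_transfer"),
                               blockSize = NULL, seg1 = NULL, seg2 = NULL,
                               target = NULL, donor = NULL,
                               donorInterval = NULL, seed = NULL) {
  op <- match.arg(op)
  if (!is.null(seed)) set.seed(as.integer(seed))
  wasSet <- is(x, "SequenceSet")
  s <- .asResidueString(x)
  n <- nchar(s)
  checkIval <- function(iv, len, what) {
    if (length(iv) != 2L || iv[1L] < 0L || iv[2L] > len || iv[1L] >= iv[2L])
      stop(sprintf("%s [%s) is outside the sequence or empty",
                   what, paste(iv, collapse = ", ")))
  }
  out <- switch(op,
    block_shuffle = {
      if (is.null(blockSize) || blockSize < 1L)
        stop("block_shuffle needs a positive blockSize")
      nb <- n %/% blockSize
      if (nb < 2L) return(x)
      starts <- (seq_len(nb) - 1L) * blockSize + 1L
      blocks <- substring(s, starts, starts + blockSize - 1L)
      tail <- substr(s, nb * blockSize + 1L, n)
      paste0(paste(blocks[sample.int(nb)], collapse = ""), tail)
    },
    segment_swap = {
      checkIval(seg1, n, "segment 1"); checkIval(seg2, n, "segment 2")
      if (max(seg1[1L], seg2[1L]) < min(seg1[2L], seg2[2L]))
        stop("swap segments overlap")
      a <- if (seg1[1L] <= seg2[1L]) seg1 else seg2
      b <- if (seg1[1L] <= seg2[1L]) seg2 else seg1
      paste0(substr(s, 1L, a[1L]),
             substr(s, b[1L] + 1L, b[2L]),
             substr(s, a[2L] + 1L, b[1L]),
             substr(s, a[1L] + 1L, a[2L]),
             substr(s, b[2L] + 1L, n))
    },
    lateral_transfer = {
      checkIval(target, n, "target segment")
      d <- .asResidueString(donor)
      checkIval(donorInterval, nchar(d), "donor segment")
      paste0(substr(s, 1L, target[1L]),
             substr(d, donorInterval[1L] + 1L, donorInterval[2L]),
             substr(s, target[2L] + 1L, n))
    })
  if (wasSet) SequenceSet(stats::setNames(out, seqIds(x)),
                          alphabet = alphabetType(x))
  else out
}

#' Configuration for the hierarchy generator
#'
#' Validated parameter bag for [makeHierarchy()]. The defaults define a
#' strongly separated four-level hierarchy (class/fold/superfamily/family):
#' top-level families start from independent root sequences with distinct
#' compositional signatures, per-branch substitution probabilities decrease
#' toward the finer levels, and each family holds `nPerFamily` sequences
#' diverged by `pWithin` from the family ancestor.
#'
#' @param seed Mandatory integer seed.
#' @param rootLength Root sequence length in residues.
#' @param alphabet Simulation alphabet.
#' @param levelNames Ordered level names, coarse to fine.
#' @param branching Groups per level (first entry: number of top-level
#'   families).
#' @param pSub Per-level, per-branch substitution probability; entry 1 is
#'   used only when `independentRoots = FALSE`. Must not increase toward
#'   finer levels.
#' @param pWithin Per-site substitution probability between a family
#'   ancestor and each of its member sequences.
#' @param pIndel,indelMean Per-branch indel probability and mean length.
#' @param independentRoots If `TRUE` (default) top-level roots are drawn
#'   independently, each with its own symbol-composition bias; if `FALSE`
#'   they diverge from one common root with `pSub[1]`.
#' @return Classed list of validated settings.
#' @export
hierarchyConfig <- function(seed,
                            rootLength = 4000L,
                            alphabet = "DNA",
                            levelNames = c("class", "fold", "superfamily",
                                           "family"),
                            branching = c(2L, 2L, 2L, 2L),
                            pSub = c(0.25, 0.30, 0.10, 0.03),
                            pWithin = 0.01,
                            pIndel = 0,
                            indelMean = 3,
                            independentRoots = TRUE) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  L <- length(levelNames)
  if (L < 2L) stop("at least 2 hierarchy levels are required")
  if (length(branching) != L || any(branching < 2L))
    stop("branching needs one entry >= 2 per level")
  if (length(pSub) != L) stop("pSub needs one entry per level")
  probs <- c(pSub, pWithin, pIndel)
  if (any(probs < 0) || any(probs > 1))
    stop("probabilities must be in [0, 1]")
  if (is.unsorted(rev(c(pSub[-1L], pWithin))))
    stop("divergence must decrease toward finer levels")
  if (rootLength < 1) stop("rootLength must be positive")
  structure(list(seed = as.integer(seed), rootLength = as.integer(rootLength),
                 alphabet = alphabet, levelNames = levelNames,
                 branching = as.integer(branching), pSub = pSub,
                 pWithin = pWithin, pIndel = pIndel, indelMean = indelMean,
                 nPerFamily = 2L, independentRoots = independentRoots),
            class = "afkitHierarchyConfig")
}

## Corner attractor: half uniform, half concentrated on one symbol. Each
## lineage at every level drifts toward its own corner of composition
## space; top-level roots are drawn directly from their corner mixture (a
## full-strength compositional signature, the word-frequency analogue of
## GC bias), and finer levels drift with decreasing substitution
## probability. Corner indices are offset cumulatively down the tree so
## sibling lineages never share a drift direction. Because the per-level
## magnitudes (1, pSub[2], ..., pWithin) form a strict Cantor chain (each
## exceeds twice the sum of all finer ones), groups at every level stay
## separated in word-frequency space by construction.
.cornerAttractor <- function(corner, nSymbols) {
  probs <- rep(0.5 / nSymbols, nSymbols)
  target <- ((corner - 1L) %% nSymbols) + 1L
  probs[target] <- probs[target] + 0.5
  probs
}

#' Generate a nested, labelled sequence hierarchy
#'
#' Recursive divergence: top-level roots (independent, with distinct
#' composition biases, or diverged from a common ancestor), then
#' `branching[l]` children per node at each finer level `l` with per-branch
#' substitution probability `pSub[l]`, and finally two member sequences per
#' family at `pWithin`. Traversal is depth-first, so output is
#' byte-identical for a fixed seed.
#'
#' @param config A [hierarchyConfig()] object (or the seed to use with all
#'   defaults).
#' @param nPerFamily Sequences per finest-level family (default 2).
#' @return A [LabeledDataset-class].
#' @examples
#' ds <- makeHierarchy(hierarchyConfig(seed = 1, rootLength = 200))
#' levelNames(ds)
#' @export
makeHierarchy <- function(config, nPerFamily = config$nPerFamily) {
  if (is.numeric(config)) config <- hierarchyConfig(seed = config)
  if (is.null(nPerFamily)) nPerFamily <- config$nPerFamily
  stopifnot(inherits(config, "afkitHierarchyConfig"))
  set.seed(config$seed)
  symbols <- .alphabetSymbols(config$alphabet)
  L <- length(config$levelNames)
  seqs <- character(0); ids <- character(0)
  labels <- matrix(character(0), nrow = 0L, ncol = L,
                   dimnames = list(NULL, config$levelNames))
  counter <- 0L
  commonRoot <- if (!config$independentRoots)
    paste(sample(symbols, config$rootLength, replace = TRUE), collapse = "")
  descend <- function(node, level, path, corner) {
    if (level > L) {
      for (m in seq_len(nPerFamily)) {
        counter <<- counter + 1L
        seqs <<- c(seqs, .mutateResidues(node, symbols, config$pWithin,
                                         config$pIndel, config$indelMean))
        ids <<- c(ids, sprintf("s%03d", counter))
        labels <<- rbind(labels, path)
      }
      return(invisible(NULL))
    }
    for (b in seq_len(config$branching[level])) {
      childLabel <- if (level == 1L) sprintf("c%d", b)
                    else sprintf("%s.%d", path[level - 1L], b)
      childCorner <- corner + b
      attractor <- .cornerAttractor(childCorner, length(symbols))
      child <-
        if (level == 1L && config$independentRoots) {
          paste(sample(symbols, config$rootLength, replace = TRUE,
                       prob = attractor), collapse = "")
        } else if (level == 1L) {
          .mutateResidues(commonRoot, symbols, config$pSub[1L],
                          config$pIndel, config$indelMean,
                          replProbs = attractor)
        } else {
          .mutateResidues(node, symbols, config$pSub[level],
                          config$pIndel, config$indelMean,
                          replProbs = attractor)
        }
      newPath <- path
      newPath[level] <- childLabel
      descend(child, level + 1L, newPath, childCorner)
    }
    invisible(NULL)
  }
  descend(NA_character_, 1L, character(L), 0L)
  LabeledDataset(SequenceSet(seqs, ids = ids, alphabet = config$alphabet),
                 as.data.frame(labels, stringsAsFactors = FALSE))
}
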