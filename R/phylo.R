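## Distance matrices -> trees -> consensus: the whole-set workflow. Tree
## containers are ape `phylo` objects throughout; neighbor joining is
## delegated to ape and UPGMA to average-linkage hclust, while bipartition
## bookkeeping, majority-rule consensus, Robinson-Foulds, and the
## PHYLIP/Newick writers live here so the strict majority rule and the
## 0-1 supports are under the package's control.

.SEQ_METRICS <- c("kl", "ncd")

#' Methods accepted by buildDistanceMatrix and the CLI
#'
#' The word-vector registry (see [listMetrics()]) plus the profile-level
#' `kl` divergence and the sequence-level `ncd`.
#'
#' @return Character vector of method names.
#' @export
allMethods <- function() sort(c(.METRIC_REGISTRY$name, .SEQ_METRICS))

#' Pairwise distance matrix for a sequence set
#'
#' Computes entry (i, j) as the dissimilarity between sequences i and j:
#' word metrics operate on vectors over the union vocabulary of the whole
#' set, `kl` on add-`pseudocount` smoothed profiles, and `ncd` directly on
#' the residue strings (ignoring `k`).
#'
#' @param x A [SequenceSet-class] with at least two sequences.
#' @param k Word length; every sequence must be at least `k` long.
#' @param metric A name from [allMethods()].
#' @param mode `"count"` or `"frequency"` vectors (word metrics; `google`
#'   requires `"count"`).
#' @param pseudocount Smoothing constant for `kl`.
#' @return A [DistanceMatrix-class], symmetric with zero diagonal.
#' @examples
#' s <- SequenceSet(c(x = "ATGTGTG", y = "CATGTG"))
#' as.matrix(buildDistanceMatrix(s, 3, "euclidean"))  # off-diagonal sqrt(3)
#' @export
buildDistanceMatrix <- function(x, k, metric = "euclidean",
                                mode = c("count", "frequency"),
                                pseudocount = 1) {
  mode <- match.arg(mode)
  stopifnot(is(x, "SequenceSet"))
  n <- length(x)
  if (n < 2L) stop("a distance matrix needs at least 2 sequences")
  metric <- as.character(metric)
  if (!metric %in% allMethods())
    stop(sprintf("unknown method '%s'; see allMethods()", metric))
  labels <- seqIds(x)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  if (metric == "ncd") {
    res <- as.character(x)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      D[i, j] <- D[j, i] <- ncd(res[[i]], res[[j]])
  } else {
    vecs <- countVectors(x, k, mode = if (metric %in% c("google", "kl"))
      "count" else mode)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d <- if (metric == "kl")
        klProfileDistance(vecs[[i]], vecs[[j]], pseudocount = pseudocount)
      else wordDistance(metric, vecs[[i]], vecs[[j]])
      if (!is.finite(d))
        stop(sprintf("metric '%s' produced a non-finite distance between '%s' and '%s' (word-disjoint profiles); use a smaller k",
                     metric, labels[i], labels[j]))
      D[i, j] <- D[j, i] <- d
    }
  }
  DistanceMatrix(D, labels)
}

.asDistanceMatrix <- function(D) {
  if (is(D, "DistanceMatrix")) return(D)
  DistanceMatrix(as.matrix(D))  # validity enforces symmetry/non-negativity
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]); on an additive matrix the
#' unique generating topology and branch lengths are recovered exactly.
#' Negative intermediate branch lengths are clamped to 0. The two-taxon
#' case returns the single edge of length d, represented as two half-length
#' branches meeting at a degree-2 root.
#'
#' @param D A [DistanceMatrix-class] (or a symmetric matrix with zero
#'   diagonal, which is validated on the way in).
#' @return An unrooted `phylo` tree.
#' @export
njTree <- function(D) {
  D <- .asDistanceMatrix(D)
  n <- length(D@labels)
  if (n == 2L) {
    d <- as.matrix(D)[1L, 2L]
    return(structure(list(
      edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L, byrow = TRUE),
      edge.length = c(d / 2, d / 2),
      tip.label = D@labels, Nnode = 1L), class = "phylo"))
  }
  tr <- ape::nj(stats::as.dist(as.matrix(D)))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration ([stats::hclust()] with
#' `method = "average"`); the result is rooted and ultrametric (every
#' leaf-to-root path has the same length).
#'
#' @inheritParams njTree
#' @return A rooted ultrametric `phylo` tree.
#' @export
upgmaTree <- function(D) {
  D <- .asDistanceMatrix(D)
  hc <- stats::hclust(stats::as.dist(as.matrix(D)), method = "average")
  ape::as.phylo(hc)
}

## ---------------------------------------------------------------------------
## Bipartitions, consensus, Robinson-Foulds
## ---------------------------------------------------------------------------

.tipSets <- function(phy) {
  ## tip-label set below each node, by postorder accumulation
  n <- length(phy$tip.label)
  phy <- ape::reorder.phylo(phy, "postorder")
  sets <- vector("list", n + phy$Nnode)
  for (i in seq_len(n)) sets[[i]] <- phy$tip.label[i]
  for (r in seq_len(nrow(phy$edge))) {
    p <- phy$edge[r, 1L]; ch <- phy$edge[r, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

.splitKey <- function(block) paste(sort(block, method = "radix"), collapse = "\t")

#' Non-trivial bipartitions of a tree
#'
#' Each internal edge splits the leaf-label set in two; trivial splits
#' (singleton | rest) are excluded. Splits are canonicalized to the block
#' not containing the lexicographically first leaf label, so rooted and
#' unrooted representations of the same topology yield identical split
#' sets.
#'
#' @param phy A `phylo` tree.
#' @return Named list of character vectors (the canonical blocks); names
#'   are internal split keys.
#' @export
treeBipartitions <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  labels <- sort(phy$tip.label, method = "radix")
  n <- length(labels)
  ref <- labels[1L]
  sets <- .tipSets(phy)
  internal <- unique(phy$edge[, 2L])
  internal <- internal[internal > length(phy$tip.label)]
  out <- list()
  for (node in internal) {
    block <- sets[[node]]
    if (ref %in% block) block <- setdiff(labels, block)
    if (length(block) < 2L || length(block) > n - 2L) next
    out[[.splitKey(block)]] <- sort(block, method = "radix")
  }
  out
}

#' Robinson-Foulds distance between two trees
#'
#' Size of the symmetric difference of the non-trivial bipartition sets.
#' Identical topologies give 0; two fully resolved n-leaf trees differ by
#' at most 2(n - 3).
#'
#' @param t1,t2 `phylo` trees over the same leaf-label set.
#' @return Non-negative integer.
#' @export
robinsonFoulds <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf-label sets")
  s1 <- names(treeBipartitions(t1))
  s2 <- names(treeBipartitions(t2))
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Majority-rule consensus tree with 0-1 supports
#'
#' Keeps exactly the non-trivial bipartitions occurring in strictly more
#' than `threshold` of the input trees (classical majority rule at the
#' default 0.5, which guarantees the retained splits are mutually
#' compatible). Each retained edge is annotated with its occurrence
#' fraction as a support in \[0, 1\] (internal node label, 3 decimals);
#' unresolved parts collapse to multifurcations and no branch lengths are
#' assigned.
#'
#' @param trees List of `phylo` trees (or a `multiPhylo`) over identical
#'   leaf-label sets.
#' @param threshold Retention threshold (strictly-greater-than); default
#'   0.5.
#' @return A `phylo` tree whose `node.label` holds the supports.
#' @export
majorityConsensus <- function(trees, threshold = 0.5) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (!length(trees)) stop("at least one input tree is required")
  labels <- sort(trees[[1L]]$tip.label, method = "radix")
  for (t in trees)
    if (!setequal(t$tip.label, labels))
      stop("input trees have mismatching leaf-label sets")
  ntree <- length(trees)
  perTree <- lapply(trees, treeBipartitions)
  keys <- unlist(lapply(perTree, names), use.names = FALSE)
  counts <- table(keys)
  freq <- as.numeric(counts) / ntree
  keep <- freq > threshold
  blocks <- list(); supports <- numeric(0)
  if (any(keep)) {
    keptKeys <- names(counts)[keep]
    allBlocks <- do.call(c, perTree)
    blocks <- allBlocks[!duplicated(names(allBlocks))][keptKeys]
    supports <- freq[keep]
    names(supports) <- keptKeys
  }
  nwk <- paste0("(", .renderConsensus(labels, blocks, supports), ");")
  ape::read.tree(text = nwk)
}

## Children of a group: maximal retained blocks inside it plus bare leaves.
## Retained majority blocks are laminar (pairwise nested or disjoint), so a
## simple containment scan suffices.
.renderConsensus <- function(members, blocks, supports) {
  inside <- blocks[vapply(blocks, function(b)
    all(b %in% members) && length(b) < length(members), logical(1L))]
  if (length(inside)) {
    isMax <- vapply(seq_along(inside), function(i) {
      !any(vapply(seq_along(inside), function(j)
        j != i && length(inside[[j]]) > length(inside[[i]]) &&
          all(inside[[i]] %in% inside[[j]]), logical(1L)))
    }, logical(1L))
    top <- inside[isMax]
  } else top <- list()
  covered <- unlist(top, use.names = FALSE)
  singles <- setdiff(members, covered)
  parts <- c(
    vapply(top, function(b)
      paste0("(", .renderConsensus(b, blocks, supports), ")",
             sprintf("%.3f", supports[[.splitKey(b)]])),
      character(1L)),
    singles)
  firstMember <- c(vapply(top, function(b) min(b), character(1L)), singles)
  paste(parts[order(firstMember, method = "radix")], collapse = ",")
}

## ---------------------------------------------------------------------------
## Writers
## ---------------------------------------------------------------------------

#' Write a distance matrix in square PHYLIP format
#'
#' First line is the taxon count; each following row is the name padded (or
#' truncated) to 10 characters followed by the space-separated distances
#' with 6 decimals. Names that collide after truncation are an error.
#'
#' @param D A [DistanceMatrix-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writePhylip <- function(D, path) {
  D <- .asDistanceMatrix(D)
  nm <- substr(D@labels, 1L, 10L)
  if (anyDuplicated(nm))
    stop(sprintf("taxon names collide after 10-character truncation ('%s')",
                 nm[duplicated(nm)][1L]))
  v <- as.matrix(D)
  rows <- vapply(seq_along(nm), function(i)
    paste0(formatC(nm[i], width = -10L),
           " ", paste(sprintf("%.6f", v[i, ]), collapse = " ")),
    character(1L))
  writeLines(c(as.character(length(nm)), rows), path)
  invisible(path)
}

.newickString <- function(phy, digits = 6L) {
  ntip <- length(phy$tip.label)
  children <- split(phy$edge[, 2L], phy$edge[, 1L])
  lenOf <- rep(NA_real_, ntip + phy$Nnode)
  if (!is.null(phy$edge.length))
    lenOf[phy$edge[, 2L]] <- phy$edge.length
  nodeLab <- function(node) {
    if (is.null(phy$node.label)) return("")
    lab <- phy$node.label[node - ntip]
    if (is.na(lab)) "" else lab
  }
  render <- function(node, isRoot = FALSE) {
    if (node <= ntip) {
      s <- phy$tip.label[node]
    } else {
      kids <- children[[as.character(node)]]
      s <- paste0("(", paste(vapply(kids, render, character(1L)),
                             collapse = ","), ")", nodeLab(node))
    }
    if (!isRoot && !is.na(lenOf[node]))
      s <- paste0(s, ":", sprintf(paste0("%.", digits, "f"), lenOf[node]))
    s
  }
  root <- setdiff(unique(phy$edge[, 1L]), phy$edge[, 2L])
  paste0(render(root, isRoot = TRUE), ";")
}

#' Write a tree in Newick format
#'
#' Branch lengths, when present, are printed with 6 decimals; internal node
#' labels (consensus supports) are printed verbatim. The output is
#' terminated by ';' and a newline.
#'
#' @param phy A `phylo` tree with at least two leaves.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeNewick <- function(phy, path) {
  stopifnot(inherits(phy, "phylo"))
  if (length(phy$tip.label) < 2L)
    stop("a tree with fewer than 2 leaves cannot be written")
  writeLines(.newickString(phy), path)
  invisible(path)
}
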