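## Hierarchical AUC benchmark: pairwise distances on a labelled sequence
## set; at each hierarchy level, pairs sharing the label are "related"
## (positives) and all other pairs are "unrelated"; a good dissimilarity
## measure ranks positives below negatives, quantified by the area under
## the ROC curve computed as the Mann-Whitney rank statistic.

#' Positive and negative sequence pairs at one hierarchy level
#'
#' Unordered pairs sharing the label at `level` are positives; all other
#' pairs are negatives (the inclusive definition: finer-level structure is
#' ignored). The two sets are disjoint and exhaustive over the
#' n(n-1)/2 pairs.
#'
#' @param ds A [LabeledDataset-class] with at least 2 sequences.
#' @param level Level name (or index), see [levelNames()].
#' @return List with integer two-column matrices `positives` and
#'   `negatives` (row = pair of sequence indices, i < j).
#' @export
pairLabels <- function(ds, level) {
  stopifnot(is(ds, "LabeledDataset"))
  n <- length(ds)
  if (n < 2L) stop("pair construction needs at least 2 sequences")
  lb <- datasetLabels(ds)
  if (is.character(level) && !level %in% colnames(lb))
    stop(sprintf("unknown level '%s' (levels: %s)", level,
                 paste(colnames(lb), collapse = ", ")))
  lab <- lb[[level]]
  pairs <- t(utils::combn(n, 2L))
  pos <- lab[pairs[, 1L]] == lab[pairs[, 2L]]
  if (all(pos)) stop(sprintf("all pairs are positive at level '%s'; AUC is undefined", level))
  if (!any(pos)) stop(sprintf("all pairs are negative at level '%s'; AUC is undefined", level))
  list(positives = pairs[pos, , drop = FALSE],
       negatives = pairs[!pos, , drop = FALSE])
}

#' AUC from positive- and negative-pair distances
#'
#' `AUC = [#(d_pos < d_neg) + 0.5 * #(ties)] / (|P| * |N|)` -- the
#' probability that a randomly chosen related pair is closer than a
#' randomly chosen unrelated pair, with ties counted one half. Computed as
#' the Mann-Whitney statistic with midrank tie handling (equivalent to the
#' trapezoidal ROC area), so no threshold sweep is involved.
#'
#' @param posDistances,negDistances Numeric distance vectors for the
#'   positive and negative pairs; both non-empty.
#' @return AUC in \[0, 1\].
#' @examples
#' aucFromDistances(c(0.3, 0.7), c(0.5, 0.9))  # 0.75
#' @export
aucFromDistances <- function(posDistances, negDistances) {
  np <- length(posDistances); nn <- length(negDistances)
  if (np == 0L || nn == 0L)
    stop("both positive and negative distances are required")
  r <- rank(c(posDistances, negDistances))       # midranks on ties
  Rpos <- sum(r[seq_len(np)])
  concordantAgainst <- Rpos - np * (np + 1) / 2  # #(neg < pos) + 0.5 ties
  (np * nn - concordantAgainst) / (np * nn)
}

.pairDist <- function(M, pairs) M[cbind(pairs[, 1L], pairs[, 2L])]

#' Run the hierarchical AUC benchmark
#'
#' For each configuration (method, word size, vector mode) one distance
#' matrix is computed and reused across all hierarchy levels; at each level
#' the AUC of related-vs-unrelated separation is reported.
#'
#' @param ds A [LabeledDataset-class].
#' @param configs `data.frame` with columns `metric`, `k`, `mode`
#'   (and optionally `pseudocount`); see [allMethods()].
#' @param levels Level names to evaluate (default: all).
#' @return `data.frame` with columns `metric`, `k`, `mode`, `level`, `auc`,
#'   `n_pos`, `n_neg`. The pair definition is recorded in the
#'   `"pair_definition"` attribute.
#' @export
runBenchmark <- function(ds, configs, levels = levelNames(ds)) {
  stopifnot(is(ds, "LabeledDataset"))
  configs <- as.data.frame(configs, stringsAsFactors = FALSE)
  if (!all(c("metric", "k") %in% colnames(configs)))
    stop("configs needs 'metric' and 'k' columns")
  if (is.null(configs$mode)) configs$mode <- "count"
  if (is.null(configs$pseudocount)) configs$pseudocount <- 1
  pairSets <- lapply(levels, function(lv) pairLabels(ds, lv))
  names(pairSets) <- levels
  rows <- vector("list", nrow(configs) * length(levels))
  idx <- 1L
  for (ci in seq_len(nrow(configs))) {
    M <- as.matrix(buildDistanceMatrix(
      datasetSequences(ds), k = configs$k[ci], metric = configs$metric[ci],
      mode = configs$mode[ci], pseudocount = configs$pseudocount[ci]))
    for (lv in levels) {
      ps <- pairSets[[lv]]
      rows[[idx]] <- data.frame(
        metric = configs$metric[ci], k = configs$k[ci],
        mode = configs$mode[ci], level = lv,
        auc = aucFromDistances(.pairDist(M, ps$positives),
                               .pairDist(M, ps$negatives)),
        n_pos = nrow(ps$positives), n_neg = nrow(ps$negatives),
        stringsAsFactors = FALSE)
      idx <- idx + 1L
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "pair_definition") <-
    "positives share the label at exactly the evaluated level; finer-level structure is ignored"
  out
}

#' Rank benchmark configurations by mean AUC across levels
#'
#' @param result Output of [runBenchmark()].
#' @return `data.frame` with one row per configuration, sorted by
#'   decreasing `mean_auc`.
#' @export
benchmarkRanking <- function(result) {
  key <- interaction(result$metric, result$k, result$mode, drop = TRUE)
  agg <- aggregate(result$auc, by = list(key = key), FUN = mean)
  meta <- result[!duplicated(key), c("metric", "k", "mode")]
  meta <- meta[match(agg$key, unique(key)), ]
  out <- data.frame(meta, mean_auc = agg$x, row.names = NULL)
  out[order(-out$mean_auc), ]
}

#' Write a benchmark result table as TSV
#'
#' @param result Output of [runBenchmark()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeBenchmark <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a hierarchy label file
#'
#' Tab-separated: a header row naming the levels, then one row per
#' sequence: `sequence_id TAB level1 TAB ... TAB levelL` (coarse to fine).
#'
#' @param path Label file path.
#' @param seqs A [SequenceSet-class] the labels describe; every sequence
#'   must be labelled.
#' @return A [LabeledDataset-class].
#' @export
readLabels <- function(path, seqs) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 2L)
    stop(sprintf("label file '%s' needs an id column plus at least one level", path))
  ids <- tab[[1L]]
  missing <- setdiff(seqIds(seqs), ids)
  if (length(missing))
    stop(sprintf("sequence '%s' has no label row in '%s'", missing[1L], path))
  tab <- tab[match(seqIds(seqs), ids), -1L, drop = FALSE]
  LabeledDataset(seqs, tab)
}

#' Write the hierarchy labels of a dataset as TSV
#'
#' @param ds A [LabeledDataset-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeLabels <- function(ds, path) {
  stopifnot(is(ds, "LabeledDataset"))
  tab <- cbind(sequence_id = seqIds(ds), datasetLabels(ds))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
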