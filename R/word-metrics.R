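## Word-vector dissimilarity measures. Every function here takes two
## CountVector objects aligned to the same vocabulary and returns a single
## non-negative number, symmetric in its arguments and zero on identical
## vectors.

.METRIC_REGISTRY <- data.frame(
  name = c("euclidean", "euclidean_sq", "manhattan", "canberra",
           "braycurtis", "jaccard", "hamming_binary", "google",
           "pearson", "d2_cosine"),
  input_mode = c("any", "any", "any", "any",
                 "any", "binary", "binary", "count",
                 "any", "any"),
  description = c(
    "sqrt of summed squared coordinate differences",
    "summed squared coordinate differences (count- and frequency-mode runs are the two benchmark variants)",
    "summed absolute coordinate differences",
    "sum of |u-v|/(u+v) over coordinates with u+v > 0",
    "sum |u-v| / sum (u+v)",
    "1 - |A intersect B| / |A union B| on the sets of present words",
    "size of the symmetric difference of the sets of present words",
    "normalized Google distance on word mass: [max(ln fu, ln fv) - ln fuv] / [ln(fu+fv) - min(ln fu, ln fv)]",
    "1 - Pearson correlation of the vectors",
    "1 - cosine similarity (the raw d2 inner product is d2Similarity())"),
  stringsAsFactors = FALSE
)

#' Registry of word-vector dissimilarity measures
#'
#' The stable metric names accepted by [wordDistance()],
#' [buildDistanceMatrix()] and the CLI, with the vector mode each expects:
#' `any` metrics accept count or frequency vectors (for the squared
#' Euclidean distance those are the two benchmark variants), `binary`
#' metrics look only at word presence/absence, and `google` needs raw
#' counts because it works on word mass totals.
#'
#' @return `data.frame` with columns `name`, `input_mode`, `description`,
#'   rows in registry (alphabetical) order.
#' @export
listMetrics <- function() .METRIC_REGISTRY[order(.METRIC_REGISTRY$name), ]

.checkPair <- function(u, v) {
  stopifnot(is(u, "CountVector"), is(v, "CountVector"))
  if (!identical(u@vocabulary@words, v@vocabulary@words))
    stop("count vectors are over different vocabularies")
  if (!identical(u@mode, v@mode))
    stop(sprintf("count vectors mix modes ('%s' vs '%s')", u@mode, v@mode))
}

#' Raw d2 similarity (inner product) of two word vectors
#'
#' @param u,v [CountVector-class] objects over the same vocabulary.
#' @return `sum(u_i * v_i)`.
#' @export
d2Similarity <- function(u, v) {
  .checkPair(u, v)
  sum(u@entries * v@entries)
}

.metricImpl <- list(
  euclidean = function(x, y) sqrt(sum((x - y)^2)),
  euclidean_sq = function(x, y) sum((x - y)^2),
  manhattan = function(x, y) sum(abs(x - y)),
  canberra = function(x, y) {
    s <- x + y
    idx <- s > 0            # 0/0 coordinates contribute 0 by convention
    sum(abs(x - y)[idx] / s[idx])
  },
  braycurtis = function(x, y) {
    tot <- sum(x + y)
    if (tot == 0) stop("Bray-Curtis is undefined when both vectors are all-zero")
    sum(abs(x - y)) / tot
  },
  jaccard = function(x, y) {
    a <- x > 0; b <- y > 0
    un <- sum(a | b)
    if (un == 0) return(0)  # two empty profiles are identical
    1 - sum(a & b) / un
  },
  hamming_binary = function(x, y) sum(xor(x > 0, y > 0)),
  google = function(x, y) {
    fu <- sum(x); fv <- sum(y)
    if (fu == 0 || fv == 0)
      stop("Google distance is undefined for an all-zero vector")
    fuv <- sum(pmin(x, y))
    num <- max(log(fu), log(fv)) - log(fuv)
    den <- log(fu + fv) - min(log(fu), log(fv))
    num / den
  },
  pearson = function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("Pearson dissimilarity is undefined for a constant vector")
    1 - stats::cor(x, y)
  },
  d2_cosine = function(x, y) {
    nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
    if (nx == 0 || ny == 0)
      stop("d2 cosine dissimilarity is undefined for an all-zero vector")
    1 - sum(x * y) / (nx * ny)
  }
)

#' Word-based dissimilarity between two count vectors
#'
#' Applies one of the registry measures (see [listMetrics()]) to two vectors
#' over the same vocabulary. All measures are symmetric, non-negative, and
#' zero for identical vectors. Binary measures (`jaccard`,
#' `hamming_binary`) use only which words are present; `google` requires
#' count-mode vectors. Tiny negative values from floating-point
#' cancellation (pearson, d2_cosine) are clamped to 0.
#'
#' @param metric Metric name from the registry.
#' @param u,v [CountVector-class] objects over the same vocabulary and in
#'   the same mode.
#' @return A single non-negative number. `google` on word-disjoint profiles
#'   is `Inf` (maximally distant).
#' @examples
#' cv <- countVectors(SequenceSet(c(x = "ATGTGTG", y = "CATGTG")), 3)
#' wordDistance("euclidean", cv$x, cv$y)  # sqrt(3)
#' @export
wordDistance <- function(metric, u, v) {
  metric <- as.character(metric)
  if (!metric %in% .METRIC_REGISTRY$name)
    stop(sprintf("unknown metric '%s'; see listMetrics()", metric))
  .checkPair(u, v)
  mode_req <- .METRIC_REGISTRY$input_mode[.METRIC_REGISTRY$name == metric]
  if (mode_req == "count" && u@mode != "count")
    stop(sprintf("metric '%s' requires count-mode vectors", metric))
  d <- as.numeric(.metricImpl[[metric]](u@entries, v@entries))
  if (is.finite(d) && d < 0) {
    if (d < -1e-9) stop("internal error: negative distance")
    d <- 0
  }
  d
}
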