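## Information-theory measures: LZ76 complexity, normalized compression
## distance, Shannon entropy, and a symmetrized Kullback-Leibler divergence
## on smoothed word profiles.

.asResidueString <- function(x) {
  if (is(x, "SequenceSet")) {
    if (length(x) != 1L)
      stop("expected a single sequence; subset the SequenceSet first")
    return(unname(as.character(x)))
  }
  stopifnot(is.character(x), length(x) == 1L)
  x
}

#' Lempel-Ziv (LZ76) complexity of a symbol string
#'
#' Exhaustive-history parsing, scanned left to right: the current word
#' `w = s[i..j]` keeps extending while it occurs as a substring of
#' `s[1..j-1]` (overlap with itself allowed). When extension fails, the
#' component ends at `j` (it includes the first irreproducible symbol) and a
#' new component starts at `j + 1`. The final word counts as one component
#' even if it is still reproducible when the input ends. The component
#' count is a practical stand-in for Kolmogorov complexity: repetitive
#' strings parse into few components, random strings into many.
#'
#' @param x A non-empty residue string (or single-sequence
#'   [SequenceSet-class]).
#' @return Integer component count, between 1 and `nchar(x)`.
#' @examples
#' lzComplexity("ATGTGTG")  # 4: A | T | G | TGTG
#' lzComplexity("AAAA")     # 2: A | AAA
#' @export
lzComplexity <- function(x) {
  s <- .asResidueString(x)
  n <- nchar(s)
  if (n == 0L) stop("cannot compute complexity of an empty string")
  components <- 0L
  i <- 1L
  while (i <= n) {
    j <- i
    repeat {
      w <- substr(s, i, j)
      reproducible <- j > 1L && grepl(w, substr(s, 1L, j - 1L), fixed = TRUE)
      if (!reproducible) {          # component = reproducible part + 1 new symbol
        components <- components + 1L
        i <- j + 1L
        break
      }
      if (j == n) {                 # input ended while still reproducible
        components <- components + 1L
        i <- n + 1L
        break
      }
      j <- j + 1L
    }
  }
  components
}

#' Normalized compression distance between two sequences
#'
#' `NCD = [C_pair - min(C(x), C(y))] / max(C(x), C(y))` where
#' `C_pair = min(C(xy), C(yx))` is the complexity of the concatenation,
#' taken over both orders so the result is symmetric. The default backend
#' is [lzComplexity()]; any function mapping a string to a positive number
#' (e.g. a compressor-based estimator) can be plugged in.
#'
#' Note that the crude LZ76 estimator does not reach 0 on identical short
#' strings (concatenating a sequence with itself still costs one extra
#' component), which is expected behaviour, not a defect.
#'
#' @param x,y Non-empty residue strings (or single-sequence
#'   [SequenceSet-class] objects).
#' @param backend Complexity function, string -> positive number.
#' @return Non-negative dissimilarity, symmetric in `(x, y)`.
#' @examples
#' ncd("ATGTGTG", "CATGTG")  # 0.2
#' @export
ncd <- function(x, y, backend = lzComplexity) {
  sx <- .asResidueString(x)
  sy <- .asResidueString(y)
  cx <- backend(sx)
  cy <- backend(sy)
  cpair <- min(backend(paste0(sx, sy)), backend(paste0(sy, sx)))
  (cpair - min(cx, cy)) / max(cx, cy)
}

#' Shannon entropy of a frequency vector, in bits
#'
#' `H = -sum(p_i log2 p_i)` over the positive entries.
#'
#' @param p Numeric vector of non-negative entries summing to 1
#'   (tolerance 1e-9).
#' @return Entropy in bits.
#' @examples
#' shannonEntropy(rep(0.25, 4))  # 2
#' @export
shannonEntropy <- function(p) {
  if (is(p, "CountVector")) p <- p@entries
  stopifnot(is.numeric(p))
  if (any(p < 0)) stop("frequencies must be non-negative")
  if (abs(sum(p) - 1) > 1e-9)
    stop(sprintf("frequencies must sum to 1 (got %.12g)", sum(p)))
  pos <- p[p > 0]
  -sum(pos * log2(pos))
}

#' Symmetrized Kullback-Leibler divergence between two word profiles
#'
#' Each count vector is smoothed by an add-`pseudocount` rule over the
#' shared vocabulary, `p_i = (u_i + c) / (sum(u) + c * m)` with `m` the
#' vocabulary size, so that every word has positive probability; the
#' returned value is `KL(p || q) + KL(q || p)` in bits. Zero if and only if
#' the two vectors are identical.
#'
#' @param u,v [CountVector-class] objects over the same (non-empty)
#'   vocabulary.
#' @param pseudocount Positive smoothing constant `c` (default 1).
#' @return Non-negative symmetric divergence in bits.
#' @examples
#' cv <- countVectors(SequenceSet(c(x = "ATGTGTG", y = "CATGTG")), 3)
#' klProfileDistance(cv$x, cv$y)  # about 0.2364 bits
#' @export
klProfileDistance <- function(u, v, pseudocount = 1) {
  .checkPair(u, v)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0)
    stop("pseudocount must be a single positive number")
  m <- length(u@entries)
  if (m == 0L) stop("KL divergence over an empty vocabulary is undefined")
  p <- (u@entries + pseudocount) / (sum(u@entries) + pseudocount * m)
  q <- (v@entries + pseudocount) / (sum(v@entries) + pseudocount * m)
  sum(p * log2(p / q)) + sum(q * log2(q / p))
}
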