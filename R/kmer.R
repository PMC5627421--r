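## Word extraction and vectorization: sequences are sliced into overlapping
## k-mers (step 1, strand-specific), profiles are merged into a sorted union
## vocabulary, and each profile is laid out as a dense count or frequency
## vector over that vocabulary.

.wordsOf <- function(s, k, ambig) {
  n <- nchar(s)
  starts <- seq_len(n - k + 1L)
  words <- substring(s, starts, starts + k - 1L)
  if (length(ambig)) {
    cls <- paste0("[", paste(ambig, collapse = ""), "]")
    words <- words[!grepl(cls, words)]
  }
  words
}

#' Extract overlapping word counts from a sequence
#'
#' Slides a window of width `k` over the sequence with step 1 (strand
#' specific; no reverse-complement merging) and counts each distinct word.
#' Windows containing an ambiguity symbol are skipped and do not contribute
#' to the total, keeping counts integral and reproducible.
#'
#' @param x A single residue string, or a [SequenceSet-class] (counts are
#'   extracted per sequence and a list of profiles is returned).
#' @param k Word length; must satisfy `1 <= k <= nchar(sequence)`.
#' @param seqId Identifier recorded in the profile (character input only).
#' @param ambig Ambiguity symbols whose windows are skipped. For a
#'   `SequenceSet` this defaults to the set implied by its alphabet; for a
#'   bare string it defaults to `"N"`.
#' @return A [WordProfile-class], or a named list of them.
#' @examples
#' p <- extractWordCounts("ATGTGTG", 3, seqId = "x")
#' profileCounts(p)  # ATG:1, GTG:2, TGT:2
#' @export
extractWordCounts <- function(x, k, seqId = "seq", ambig = NULL) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  if (is(x, "SequenceSet")) {
    if (is.null(ambig)) ambig <- ambiguitySymbols(alphabetType(x))
    res <- as.character(x)
    out <- lapply(seqIds(x), function(id)
      extractWordCounts(res[[id]], k, seqId = id, ambig = ambig))
    names(out) <- seqIds(x)
    return(out)
  }
  stopifnot(is.character(x), length(x) == 1L)
  if (is.null(ambig)) ambig <- "N"
  n <- nchar(x)
  if (k > n)
    stop(sprintf("k = %d exceeds the length (%d) of sequence '%s'", k, n, seqId))
  words <- .wordsOf(x, k, ambig)
  if (!length(words)) {
    counts <- integer(0)
  } else {
    tab <- table(words)
    counts <- as.integer(tab)
    names(counts) <- names(tab)
  }
  new("WordProfile", seqId = seqId, k = k, counts = counts)
}

#' Union vocabulary of a collection of word profiles
#'
#' The sorted (byte-order, hence platform-independent) union of all words
#' seen in the profiles. Deterministic regardless of profile order.
#'
#' @param profiles List of [WordProfile-class] objects sharing the same `k`.
#' @return A [Vocabulary-class]. An empty profile collection yields the
#'   empty vocabulary.
#' @examples
#' ps <- extractWordCounts(SequenceSet(c(x = "ATGTGTG", y = "CATGTG")), 3)
#' vocabWords(unionVocabulary(ps))  # ATG CAT GTG TGT
#' @export
unionVocabulary <- function(profiles) {
  if (is(profiles, "WordProfile")) profiles <- list(profiles)
  if (!length(profiles))
    return(new("Vocabulary", k = NA_integer_, words = character(0)))
  ks <- unique(vapply(profiles, wordSize, integer(1L)))
  if (length(ks) != 1L)
    stop(sprintf("profiles mix word sizes (%s)", paste(sort(ks), collapse = ", ")))
  words <- sort(unique(unlist(lapply(profiles, function(p) names(p@counts)),
                              use.names = FALSE)),
                method = "radix")
  if (is.null(words)) words <- character(0)
  new("Vocabulary", k = ks, words = words)
}

#' Lay a word profile out as a vector over a vocabulary
#'
#' Entry i is the count of vocabulary word i (0 when absent). In
#' `"frequency"` mode the counts are divided by the profile total; an empty
#' profile gives the all-zero frequency vector.
#'
#' @param profile A [WordProfile-class]; every profile word must appear in
#'   `vocab`.
#' @param vocab A [Vocabulary-class] with the same `k`.
#' @param mode `"count"` or `"frequency"`.
#' @return A [CountVector-class].
#' @examples
#' ps <- extractWordCounts(SequenceSet(c(x = "ATGTGTG", y = "CATGTG")), 3)
#' v <- unionVocabulary(ps)
#' vectorEntries(toCountVector(ps$x, v))             # 1 0 2 2
#' vectorEntries(toCountVector(ps$x, v, "frequency")) # 0.2 0 0.4 0.4
#' @export
toCountVector <- function(profile, vocab, mode = c("count", "frequency")) {
  mode <- match.arg(mode)
  stopifnot(is(profile, "WordProfile"), is(vocab, "Vocabulary"))
  if (length(profile@counts) && !is.na(vocab@k) && profile@k != vocab@k)
    stop(sprintf("profile k (%d) differs from vocabulary k (%d)",
                 profile@k, vocab@k))
  missing <- setdiff(names(profile@counts), vocab@words)
  if (length(missing))
    stop(sprintf("profile word '%s' is missing from the vocabulary", missing[1L]))
  entries <- rep(0, length(vocab@words))
  names(entries) <- vocab@words
  entries[names(profile@counts)] <- as.numeric(profile@counts)
  if (mode == "frequency") {
    tot <- sum(entries)
    if (tot > 0) entries <- entries / tot
  }
  new("CountVector", seqId = profile@seqId, vocabulary = vocab,
      entries = unname(entries), mode = mode)
}

#' Count vectors for a whole sequence set over their union vocabulary
#'
#' Convenience wrapper chaining [extractWordCounts()], [unionVocabulary()]
#' and [toCountVector()].
#'
#' @param x A [SequenceSet-class].
#' @param k Word length.
#' @param mode `"count"` or `"frequency"`.
#' @return Named list of [CountVector-class] objects sharing one vocabulary.
#' @export
countVectors <- function(x, k, mode = c("count", "frequency")) {
  mode <- match.arg(mode)
  profiles <- extractWordCounts(x, k)
  vocab <- unionVocabulary(profiles)
  lapply(profiles, toCountVector, vocab = vocab, mode = mode)
}

#' Size of the dense word space
#'
#' Number of possible words of length `k` over an alphabet of
#' `alphabetSize` symbols, i.e. `alphabetSize ^ k`. Dense indexing over this
#' space grows quickly (the DNA word space at k = 14 already has
#' 268,435,456 cells), which is why the package only ever materializes the
#' sparse union vocabulary.
#'
#' @param alphabetSize Number of symbols.
#' @param k Word length.
#' @return The count, as a double (exact for all practical sizes).
#' @export
wordSpaceSize <- function(alphabetSize, k) {
  stopifnot(alphabetSize >= 1, k >= 0)
  as.numeric(alphabetSize)^as.numeric(k)
}

#' Dump a word profile as a two-column tab-separated file
#'
#' Lines are `word TAB count` in vocabulary (byte) order.
#'
#' @param profile A [WordProfile-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeProfile <- function(profile, path) {
  stopifnot(is(profile, "WordProfile"))
  words <- sort(names(profile@counts), method = "radix")
  writeLines(sprintf("%s\t%d", words, profile@counts[words]), path)
  invisible(path)
}
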