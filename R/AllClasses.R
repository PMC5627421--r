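#' @import methods
NULL

## Core alphabets; ambiguity extensions follow IUPAC usage as far as the
## package needs them: N for nucleotides, X/B/Z for protein. Reduced
## alphabets are open (any uppercase letters) because user schemes may pick
## arbitrary target symbols.
.CORE_ALPHABETS <- list(
  DNA     = c("A", "C", "G", "T"),
  RNA     = c("A", "C", "G", "U"),
  protein = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
)

.AMBIGUITY <- list(
  DNA     = "N",
  RNA     = "N",
  protein = c("X", "B", "Z")
)

#' Ambiguity symbols for an alphabet
#'
#' Windows containing these symbols are skipped during word counting, and
#' the symbols are passed through unchanged by alphabet reduction.
#'
#' @param alphabet `"DNA"`, `"RNA"`, `"protein"`, or a `"reduced-<n>"` tag.
#' @return Character vector of ambiguity symbols.
#' @export
ambiguitySymbols <- function(alphabet) {
  if (alphabet %in% names(.AMBIGUITY)) return(.AMBIGUITY[[alphabet]])
  ## reduced or unknown: retain every ambiguity code any source alphabet uses
  c("N", "X", "B", "Z")
}

## ---------------------------------------------------------------------------
## SequenceSet
## ---------------------------------------------------------------------------

#' SequenceSet: identified residue strings over a declared alphabet
#'
#' An ordered, named collection of sequences. Residues are stored uppercase
#' in a [Biostrings::BStringSet] so that any alphabet (including reduced
#' encodings) is representable; the declared alphabet is carried alongside
#' and checked by the validity method.
#'
#' @slot set A `BStringSet` holding the residues, names are the sequence ids.
#' @slot alphabet One of `"DNA"`, `"RNA"`, `"protein"`, or `"reduced-<n>"`.
#' @export
setClass("SequenceSet",
         representation(set = "BStringSet", alphabet = "character"))

setValidity("SequenceSet", function(object) {
  ids <- names(object@set)
  if (length(object@alphabet) != 1L || is.na(object@alphabet))
    return("alphabet must be a single string")
  ok_alpha <- object@alphabet %in% names(.CORE_ALPHABETS) ||
    grepl("^reduced-[0-9]+$", object@alphabet)
  if (!ok_alpha)
    return(sprintf("unknown alphabet '%s'", object@alphabet))
  if (length(object@set) == 0L) return(TRUE)
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
    return("every sequence needs a non-empty id")
  if (anyDuplicated(ids))
    return(sprintf("duplicate sequence id '%s'", ids[duplicated(ids)][1L]))
  res <- as.character(object@set)
  if (any(!nzchar(res)))
    return(sprintf("sequence '%s' has empty residues", ids[!nzchar(res)][1L]))
  if (any(res != toupper(res)))
    return("residues must be uppercase")
  symbols <- unique(strsplit(paste(res, collapse = ""), "")[[1L]])
  if (object@alphabet %in% names(.CORE_ALPHABETS)) {
    allowed <- c(.CORE_ALPHABETS[[object@alphabet]],
                 .AMBIGUITY[[object@alphabet]])
  } else {
    allowed <- LETTERS
  }
  bad <- setdiff(symbols, allowed)
  if (length(bad))
    return(sprintf("symbol '%s' is not in the %s alphabet or its ambiguity extension",
                   bad[1L], object@alphabet))
  TRUE
})

.detectAlphabet <- function(residues) {
  symbols <- unique(strsplit(paste(residues, collapse = ""), "")[[1L]])
  for (a in c("DNA", "RNA")) {
    if (all(symbols %in% c(.CORE_ALPHABETS[[a]], .AMBIGUITY[[a]])))
      return(a)
  }
  "protein"
}

#' Construct a SequenceSet
#'
#' @param residues Character vector of residue strings (any case; uppercased
#'   on construction), or a named vector if `ids` is omitted.
#' @param ids Sequence identifiers; defaults to `names(residues)`.
#' @param alphabet `"auto"` (detect DNA/RNA/protein from the symbols seen)
#'   or an explicit alphabet tag.
#' @return A [SequenceSet-class] object.
#' @examples
#' SequenceSet(c(x = "ATGTGTG", y = "CATGTG"))
#' @export
SequenceSet <- function(residues, ids = names(residues), alphabet = "auto") {
  force(ids)
  residues <- toupper(as.character(residues))
  if (is.null(ids) && length(residues))
    stop("sequence ids are required")
  if (identical(alphabet, "auto"))
    alphabet <- .detectAlphabet(residues)
  set <- Biostrings::BStringSet(residues)
  names(set) <- ids
  new("SequenceSet", set = set, alphabet = alphabet)
}

#' @describeIn SequenceSet Number of sequences.
#' @param x A `SequenceSet`.
#' @export
setMethod("length", "SequenceSet", function(x) length(x@set))

#' @export
setMethod("names", "SequenceSet", function(x) names(x@set))

#' @export
setMethod("as.character", "SequenceSet", function(x) {
  out <- as.character(x@set)
  names(out) <- names(x@set)
  out
})

#' @export
setMethod("[", "SequenceSet", function(x, i, j, ..., drop = TRUE) {
  initialize(x, set = x@set[i], alphabet = x@alphabet)
})

#' @export
setMethod("show", "SequenceSet", function(object) {
  cat(sprintf("SequenceSet of %d sequence%s (%s alphabet)\n",
              length(object), if (length(object) == 1L) "" else "s",
              object@alphabet))
  n <- min(length(object), 6L)
  if (n > 0L) {
    res <- as.character(object@set[seq_len(n)])
    shown <- ifelse(nchar(res) > 40L, paste0(substr(res, 1L, 40L), "..."), res)
    cat(sprintf("  %-12s %6d  %s\n", names(object@set)[seq_len(n)],
                nchar(res), shown), sep = "")
    if (length(object) > n) cat(sprintf("  ... and %d more\n", length(object) - n))
  }
  invisible(NULL)
})

#' Sequence ids of an object
#' @param x A `SequenceSet` or `LabeledDataset`.
#' @return Character vector of ids.
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))

#' @rdname seqIds
#' @export
setMethod("seqIds", "SequenceSet", function(x) names(x@set))

#' Declared alphabet of a SequenceSet
#' @param x A `SequenceSet`.
#' @export
setGeneric("alphabetType", function(x) standardGeneric("alphabetType"))

#' @rdname alphabetType
#' @export
setMethod("alphabetType", "SequenceSet", function(x) x@alphabet)

## ---------------------------------------------------------------------------
## WordProfile / Vocabulary / CountVector
## ---------------------------------------------------------------------------

#' WordProfile: k-mer occurrence counts of one sequence
#'
#' @slot seqId Sequence identifier.
#' @slot k Word length in residues.
#' @slot counts Named integer vector, word -> positive occurrence count.
#'   Windows containing ambiguity symbols are skipped, so the total may be
#'   smaller than `len - k + 1` (or zero).
#' @export
setClass("WordProfile",
         representation(seqId = "character", k = "integer",
                        counts = "integer"))

setValidity("WordProfile", function(object) {
  if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
    return("k must be a single positive integer")
  if (length(object@counts)) {
    w <- names(object@counts)
    if (is.null(w) || anyDuplicated(w)) return("counts must be uniquely named")
    if (any(nchar(w) != object@k)) return("every word must have length k")
    if (any(object@counts < 1L)) return("all counts must be >= 1")
  }
  TRUE
})

#' @describeIn WordProfile Total number of counted (unambiguous) windows.
#' @param x A `WordProfile`.
#' @export
setGeneric("profileTotal", function(x) standardGeneric("profileTotal"))

#' @rdname WordProfile-class
#' @export
setMethod("profileTotal", "WordProfile", function(x) sum(x@counts))

#' Word->count mapping of a profile
#' @param x A `WordProfile`.
#' @export
setGeneric("profileCounts", function(x) standardGeneric("profileCounts"))

#' @rdname profileCounts
#' @export
setMethod("profileCounts", "WordProfile", function(x) x@counts)

#' Word length of a profile, vocabulary or count vector
#' @param x A `WordProfile`, `Vocabulary` or `CountVector`.
#' @export
setGeneric("wordSize", function(x) standardGeneric("wordSize"))

#' @rdname wordSize
#' @export
setMethod("wordSize", "WordProfile", function(x) x@k)

#' @export
setMethod("show", "WordProfile", function(object) {
  cat(sprintf("WordProfile '%s': %d distinct %d-mer%s, total %d\n",
              object@seqId, length(object@counts), object@k,
              if (object@k == 1L) "" else "s", profileTotal(object)))
  invisible(NULL)
})

#' Vocabulary: ordered union word list
#'
#' Words are kept in strictly increasing lexicographic (byte) order so the
#' vector layout is deterministic across platforms and runs.
#'
#' @slot k Word length (NA for the empty vocabulary).
#' @slot words Sorted character vector of distinct words of length `k`.
#' @export
setClass("Vocabulary", representation(k = "integer", words = "character"))

setValidity("Vocabulary", function(object) {
  if (length(object@words) == 0L) return(TRUE)
  if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
    return("k must be a single positive integer")
  if (any(nchar(object@words) != object@k))
    return("every word must have length k")
  if (is.unsorted(object@words, strictly = TRUE) ||
      !identical(object@words, sort(object@words, method = "radix")))
    return("words must be in strictly increasing lexicographic order")
  TRUE
})

#' @rdname wordSize
#' @export
setMethod("wordSize", "Vocabulary", function(x) x@k)

#' Words of a vocabulary
#' @param x A `Vocabulary`.
#' @export
setGeneric("vocabWords", function(x) standardGeneric("vocabWords"))

#' @rdname vocabWords
#' @export
setMethod("vocabWords", "Vocabulary", function(x) x@words)

#' @export
setMethod("length", "Vocabulary", function(x) length(x@words))

#' @export
setMethod("show", "Vocabulary", function(object) {
  cat(sprintf("Vocabulary: %d word%s of length %s\n", length(object@words),
              if (length(object@words) == 1L) "" else "s",
              ifelse(is.na(object@k), "NA", object@k)))
  if (length(object@words))
    cat("  ", paste(utils::head(object@words, 12L), collapse = " "),
        if (length(object@words) > 12L) "..." else "", "\n")
  invisible(NULL)
})

#' CountVector: numeric vector of one sequence over a shared vocabulary
#'
#' @slot seqId Sequence identifier.
#' @slot vocabulary The [Vocabulary-class] the entries are aligned to.
#' @slot entries One non-negative number per vocabulary word.
#' @slot mode `"count"` (integer-valued) or `"frequency"` (sums to 1, or is
#'   all-zero for an empty profile).
#' @export
setClass("CountVector",
         representation(seqId = "character", vocabulary = "Vocabulary",
                        entries = "numeric", mode = "character"))

setValidity("CountVector", function(object) {
  if (!object@mode %in% c("count", "frequency"))
    return("mode must be 'count' or 'frequency'")
  if (length(object@entries) != length(object@vocabulary@words))
    return("entries length must equal vocabulary size")
  if (any(object@entries < 0)) return("entries must be non-negative")
  if (object@mode == "count" &&
      any(abs(object@entries - round(object@entries)) > 1e-9))
    return("count-mode entries must be integer-valued")
  if (object@mode == "frequency" && length(object@entries)) {
    s <- sum(object@entries)
    if (s != 0 && abs(s - 1) > 1e-9)
      return("frequency-mode entries must sum to 1 (or be all zero)")
  }
  TRUE
})

#' Numeric entries of a count vector
#' @param x A `CountVector`.
#' @export
setGeneric("vectorEntries", function(x) standardGeneric("vectorEntries"))

#' @rdname vectorEntries
#' @export
setMethod("vectorEntries", "CountVector", function(x) {
  out <- x@entries
  names(out) <- x@vocabulary@words
  out
})

#' Mode ("count" or "frequency") of a count vector
#' @param x A `CountVector`.
#' @export
setGeneric("vectorMode", function(x) standardGeneric("vectorMode"))

#' @rdname vectorMode
#' @export
setMethod("vectorMode", "CountVector", function(x) x@mode)

#' @rdname wordSize
#' @export
setMethod("wordSize", "CountVector", function(x) x@vocabulary@k)

#' @export
setMethod("show", "CountVector", function(object) {
  cat(sprintf("CountVector '%s' (%s mode) over %d words\n", object@seqId,
              object@mode, length(object@entries)))
  print(utils::head(vectorEntries(object), 8L))
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## DistanceMatrix
## ---------------------------------------------------------------------------

#' DistanceMatrix: labelled symmetric dissimilarity matrix
#'
#' @slot labels Ordered, unique sequence ids.
#' @slot values Square numeric matrix; symmetric, non-negative, zero
#'   diagonal.
#' @export
setClass("DistanceMatrix",
         representation(labels = "character", values = "matrix"))

setValidity("DistanceMatrix", function(object) {
  v <- object@values
  n <- length(object@labels)
  if (anyDuplicated(object@labels)) return("labels must be unique")
  if (!is.numeric(v) || nrow(v) != n || ncol(v) != n)
    return("values must be an n x n numeric matrix matching the labels")
  if (any(!is.finite(v)) ) return("distances must be finite")
  if (any(v < 0)) return("distances must be non-negative")
  if (any(abs(diag(v)) > 0)) return("diagonal must be zero")
  if (!isTRUE(all.equal(v, t(v), tolerance = 1e-12)))
    return("matrix must be symmetric")
  TRUE
})

#' Construct a DistanceMatrix from a square matrix
#'
#' @param values Square symmetric numeric matrix with zero diagonal.
#' @param labels Sequence ids; defaults to `rownames(values)`.
#' @export
DistanceMatrix <- function(values, labels = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(labels)) stop("labels are required")
  dimnames(values) <- list(labels, labels)
  new("DistanceMatrix", labels = labels, values = values)
}

#' Labels of a DistanceMatrix
#' @param x A `DistanceMatrix`.
#' @export
setGeneric("dmLabels", function(x) standardGeneric("dmLabels"))

#' @rdname dmLabels
#' @export
setMethod("dmLabels", "DistanceMatrix", function(x) x@labels)

#' @export
setMethod("as.matrix", "DistanceMatrix", function(x, ...) {
  v <- x@values
  dimnames(v) <- list(x@labels, x@labels)
  v
})

#' @export
setMethod("show", "DistanceMatrix", function(object) {
  cat(sprintf("DistanceMatrix over %d sequences\n", length(object@labels)))
  n <- min(length(object@labels), 6L)
  print(round(as.matrix(object)[seq_len(n), seq_len(n), drop = FALSE], 6))
  if (length(object@labels) > n) cat("  ...\n")
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## LabeledDataset
## ---------------------------------------------------------------------------

#' LabeledDataset: sequences with a path through an ordered label hierarchy
#'
#' Each sequence carries one label per hierarchy level, coarse to fine
#' (e.g. class/fold/superfamily/family). The validity method enforces the
#' hierarchy property: sequences sharing a label at a fine level must share
#' the labels at every coarser level.
#'
#' @slot seqs A [SequenceSet-class].
#' @slot labels `data.frame` of character columns, one row per sequence
#'   (rownames are the sequence ids), one column per level, coarse to fine.
#' @export
setClass("LabeledDataset",
         representation(seqs = "SequenceSet", labels = "data.frame"))

setValidity("LabeledDataset", function(object) {
  n <- length(object@seqs)
  lb <- object@labels
  if (nrow(lb) != n) return("one label row per sequence is required")
  if (ncol(lb) < 1L) return("at least one hierarchy level is required")
  if (!identical(rownames(lb), seqIds(object@seqs)))
    return("label rownames must equal the sequence ids, in order")
  if (!all(vapply(lb, is.character, logical(1L))))
    return("labels must be character")
  if (any(is.na(as.matrix(lb))) || any(!nzchar(as.matrix(lb))))
    return("every sequence needs a complete, non-empty label path")
  ## nesting: a fine label determines every coarser label
  if (ncol(lb) > 1L) {
    for (j in 2:ncol(lb)) {
      per <- tapply(lb[[j - 1L]], lb[[j]],
                    function(z) length(unique(z)))
      if (any(per > 1L))
        return(sprintf("labels are not hierarchical: level '%s' label maps to several '%s' labels",
                       colnames(lb)[j], colnames(lb)[j - 1L]))
    }
  }
  TRUE
})

#' Construct a LabeledDataset
#'
#' @param seqs A [SequenceSet-class].
#' @param labels `data.frame` (or matrix) of labels, one row per sequence in
#'   the same order, columns ordered coarse to fine.
#' @export
LabeledDataset <- function(seqs, labels) {
  labels <- as.data.frame(labels, stringsAsFactors = FALSE)
  labels[] <- lapply(labels, as.character)
  rownames(labels) <- seqIds(seqs)
  new("LabeledDataset", seqs = seqs, labels = labels)
}

#' @rdname seqIds
#' @export
setMethod("seqIds", "LabeledDataset", function(x) seqIds(x@seqs))

#' Sequences of a LabeledDataset
#' @param x A `LabeledDataset`.
#' @export
setGeneric("datasetSequences", function(x) standardGeneric("datasetSequences"))

#' @rdname datasetSequences
#' @export
setMethod("datasetSequences", "LabeledDataset", function(x) x@seqs)

#' Label table of a LabeledDataset
#' @param x A `LabeledDataset`.
#' @export
setGeneric("datasetLabels", function(x) standardGeneric("datasetLabels"))

#' @rdname datasetLabels
#' @export
setMethod("datasetLabels", "LabeledDataset", function(x) x@labels)

#' Ordered level names of a LabeledDataset (coarse to fine)
#' @param x A `LabeledDataset`.
#' @export
setGeneric("levelNames", function(x) standardGeneric("levelNames"))

#' @rdname levelNames
#' @export
setMethod("levelNames", "LabeledDataset", function(x) colnames(x@labels))

#' @export
setMethod("length", "LabeledDataset", function(x) length(x@seqs))

#' @export
setMethod("show", "LabeledDataset", function(object) {
  cat(sprintf("LabeledDataset: %d sequences, %d levels (%s)\n",
              length(object@seqs), ncol(object@labels),
              paste(colnames(object@labels), collapse = " > ")))
  for (j in seq_len(ncol(object@labels)))
    cat(sprintf("  %-14s %d group%s\n", colnames(object@labels)[j],
                length(unique(object@labels[[j]])),
                if (length(unique(object@labels[[j]])) == 1L) "" else "s"))
  invisible(NULL)
})
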