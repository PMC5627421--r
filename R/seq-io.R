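#' Read sequences from a FASTA file
#'
#' Parses a FASTA file (wrapped or unwrapped residue lines) into a
#' [SequenceSet-class]. Ids are the first whitespace-delimited token of each
#' header; residues are uppercased. Empty input, records with empty
#' residues, and duplicate ids are errors.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"auto"` (default) or an explicit alphabet tag.
#' @param rnaAsDna If `TRUE`, 'U' residues are rewritten to 'T' on read so
#'   RNA can be compared against DNA; by default the two are kept distinct.
#' @return A `SequenceSet`, record order preserved.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">x", "ATGTGTG", ">y", "CATGTG"), fa)
#' readFasta(fa)
#' @export
readFasta <- function(path, alphabet = "auto", rnaAsDna = FALSE) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop(sprintf("cannot parse FASTA '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE))
  if (length(set) == 0L)
    stop(sprintf("FASTA '%s' contains no records", path))
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1L), 1L)
  if (any(is.na(ids)) || any(!nzchar(ids)))
    stop(sprintf("FASTA '%s' has a record with an empty id", path))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sequence id '%s' in '%s'",
                 ids[duplicated(ids)][1L], path))
  res <- toupper(as.character(set))
  if (any(!nzchar(res)))
    stop(sprintf("record '%s' in '%s' has empty residues",
                 ids[!nzchar(res)][1L], path))
  if (rnaAsDna) res <- chartr("U", "T", res)
  SequenceSet(res, ids = ids, alphabet = alphabet)
}

#' Write sequences to a FASTA file
#'
#' Residue lines are wrapped at 60 columns; a round trip through
#' [readFasta()] preserves ids and residues exactly.
#'
#' @param x A non-empty [SequenceSet-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
  stopifnot(is(x, "SequenceSet"))
  if (length(x) == 0L) stop("refusing to write an empty SequenceSet")
  Biostrings::writeXStringSet(x@set, filepath = path, width = 60L)
  invisible(path)
}
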