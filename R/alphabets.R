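## Built-in alphabet reduction schemes.
##
## The nucleotide scheme is the classical purine/pyrimidine encoding
## (A,G -> R; C,T,U -> Y). The protein schemes of sizes 5/4/3/2 group the
## twenty residues by standard physico-chemical classes (Murphy-style
## hydrophobic / small / aromatic / charged-polar groupings); several such
## tables exist in the literature, and these are this package's defaults --
## user tables can be loaded with readSchemeFile().

.schemeFromGroups <- function(groups) {
  mapping <- character(0)
  for (target in names(groups)) {
    src <- strsplit(groups[[target]], "")[[1L]]
    mapping[src] <- target
  }
  mapping
}

.BUILTIN_SCHEMES <- list(
  ## nucleotide purine/pyrimidine
  ry = .schemeFromGroups(list(R = "AG", Y = "CTU")),
  ## protein, 5 classes: aliphatic / cysteine / small / aromatic / polar+charged
  protein5 = .schemeFromGroups(list(
    L = "LVIM", C = "C", A = "AGSTP", F = "FYW", E = "EDNQKRH")),
  ## protein, 4 classes (cysteine folded into the aliphatic group)
  protein4 = .schemeFromGroups(list(
    L = "LVIMC", A = "AGSTP", F = "FYW", E = "EDNQKRH")),
  ## protein, 3 classes: hydrophobic / small / polar+charged
  protein3 = .schemeFromGroups(list(
    H = "LVIMCFYW", S = "AGSTP", P = "EDNQKRH")),
  ## protein, 2 classes: hydrophobic / polar
  protein2 = .schemeFromGroups(list(
    H = "LVIMCAGSTPFYW", P = "EDNQKRH"))
)

#' Built-in alphabet reduction schemes
#'
#' Returns the shipped reduction tables: `ry` (nucleotide
#' purine/pyrimidine: A,G -> R; C,T,U -> Y) and `protein5`, `protein4`,
#' `protein3`, `protein2` (physico-chemical groupings of the 20 amino
#' acids). Each scheme is a named character vector mapping source symbol to
#' reduced symbol.
#'
#' @return Named list of schemes.
#' @examples
#' alphabetSchemes()$ry
#' @export
alphabetSchemes <- function() .BUILTIN_SCHEMES

#' Look up a reduction scheme by name or load one from a file
#'
#' @param scheme A built-in scheme name (see [alphabetSchemes()]), a path to
#'   a two-column tab-separated file (`symbol TAB reduced-symbol`, no
#'   header), or a named character vector used as-is.
#' @return Named character vector, source symbol -> reduced symbol.
#' @export
resolveScheme <- function(scheme) {
  if (is.character(scheme) && length(scheme) == 1L && is.null(names(scheme))) {
    if (scheme %in% names(.BUILTIN_SCHEMES)) return(.BUILTIN_SCHEMES[[scheme]])
    if (file.exists(scheme)) return(readSchemeFile(scheme))
    stop(sprintf("unknown reduction scheme '%s' (not a built-in name or a readable file)",
                 scheme))
  }
  if (is.character(scheme) && !is.null(names(scheme))) return(scheme)
  stop("scheme must be a name, a file path, or a named character vector")
}

#' Read a reduction scheme from a two-column tab-separated file
#'
#' @param path File with lines `symbol TAB reduced-symbol`; no header,
#'   `#` comments allowed.
#' @return Named character vector mapping.
#' @export
readSchemeFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop(sprintf("scheme file '%s' is empty", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop(sprintf("scheme file '%s' must have exactly two tab-separated columns", path))
  src <- toupper(vapply(parts, `[`, character(1L), 1L))
  dst <- toupper(vapply(parts, `[`, character(1L), 2L))
  if (any(nchar(src) != 1L) || any(nchar(dst) != 1L))
    stop("scheme entries must be single symbols")
  if (anyDuplicated(src))
    stop(sprintf("scheme maps symbol '%s' twice", src[duplicated(src)][1L]))
  mapping <- dst
  names(mapping) <- src
  mapping
}

#' Reduce the alphabet of a sequence set
#'
#' Applies a symbol-wise reduction (e.g. the purine/pyrimidine encoding) to
#' every sequence. Ambiguity symbols (N for nucleotides; X/B/Z for protein)
#' are retained unchanged; any other residue outside the scheme's domain is
#' an error. Length is always preserved.
#'
#' @param x A [SequenceSet-class].
#' @param scheme Scheme name, file path, or named mapping
#'   (see [resolveScheme()]).
#' @return A `SequenceSet` with alphabet `"reduced-<target size>"`.
#' @examples
#' reduceAlphabet(SequenceSet(c(x = "ATGTGTG")), "ry")  # RYRYRYR
#' @export
reduceAlphabet <- function(x, scheme) {
  stopifnot(is(x, "SequenceSet"))
  mapping <- resolveScheme(scheme)
  ambig <- ambiguitySymbols(alphabetType(x))
  res <- as.character(x)
  symbols <- unique(strsplit(paste(res, collapse = ""), "")[[1L]])
  bad <- setdiff(symbols, c(names(mapping), ambig))
  if (length(bad))
    stop(sprintf("residue '%s' is not covered by the reduction scheme", bad[1L]))
  reduced <- chartr(paste(names(mapping), collapse = ""),
                    paste(unname(mapping), collapse = ""), res)
  SequenceSet(reduced, ids = seqIds(x),
              alphabet = sprintf("reduced-%d", length(unique(unname(mapping)))))
}
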