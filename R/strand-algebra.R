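#' Validate and normalise a raw DNA sequence
#'
#' Strips whitespace, upper-cases, and checks the strict \{A, C, G, T\}
#' alphabet. IUPAC ambiguity codes (including N) and RNA letters are
#' rejected; the error names the first offending position in the
#' whitespace-stripped sequence.
#'
#' @param raw a single character string (may contain spaces/newlines/case).
#' @return the validated uppercase sequence as a character string.
#' @examples
#' validateSequence("gcg cgc ATG")  # "GCGCGCATG"
#' @export
validateSequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw))
    stop("'raw' must be a single character string")
  stripped <- gsub("[ \t\r\n]+", "", raw)
  if (nchar(stripped) == 0L)
    stop("empty sequence after removing whitespace")
  up <- toupper(stripped)
  codes <- utf8ToInt(up)
  bad <- which(!codes %in% c(65L, 67L, 71L, 84L))  # A C G T
  if (length(bad)) {
    p <- bad[1]
    stop(sprintf("invalid base '%s' at position %d (alphabet is A/C/G/T)",
                 substr(up, p, p), p))
  }
  up
}

#' Complement a single base
#'
#' Watson-Crick pairing: A pairs with T and G pairs with C, so the
#' complement map is A<->T, G<->C. Vectorised over single-character inputs.
#'
#' @param b character vector of single bases (case-insensitive).
#' @return complementary bases, uppercase.
#' @examples
#' complementBase(c("A", "G"))  # "T" "C"
#' @export
complementBase <- function(b) {
  if (!is.character(b) || any(is.na(b)) || any(nchar(b) != 1L))
    stop("'b' must be single characters")
  up <- toupper(b)
  if (any(!up %in% c("A", "C", "G", "T")))
    stop("bases must be one of A/C/G/T")
  chartr("ACGT", "TGCA", up)
}

# fast character-level primitives (inputs already validated)
.comp <- function(x) chartr("ACGT", "TGCA", x)
.rev1 <- function(x) intToUtf8(rev(utf8ToInt(x)))
.rev <- function(x) vapply(x, .rev1, character(1), USE.NAMES = FALSE)

#' @describeIn transforms antiparallel (standard reverse) complement: the
#'   strand that pairs with \code{x} in the usual antiparallel duplex.
#' @export
setMethod("antiparallelComplement", "character", function(x) {
  out <- .rev(.comp(vapply(x, validateSequence, character(1),
                           USE.NAMES = FALSE)))
  names(out) <- names(x)
  out
})

#' @describeIn transforms parallel (reverse Watson-Crick) complement:
#'   base-wise complement with order preserved — the strand that pairs with
#'   \code{x} when both run 5'->3' in the same direction.
#' @export
setMethod("parallelComplement", "character", function(x) {
  out <- .comp(vapply(x, validateSequence, character(1), USE.NAMES = FALSE))
  names(out) <- names(x)
  out
})

#' @describeIn transforms reversal without complementation (the
#'   opposite-polarity reading of the same bases).
#' @export
setMethod("reverseSequence", "character", function(x) {
  out <- .rev(vapply(x, validateSequence, character(1), USE.NAMES = FALSE))
  names(out) <- names(x)
  out
})

#' @importFrom Biostrings reverseComplement complement reverse DNAString
#'   DNAStringSet
setMethod("antiparallelComplement", "DNAString",
          function(x) Biostrings::reverseComplement(x))
setMethod("antiparallelComplement", "DNAStringSet",
          function(x) Biostrings::reverseComplement(x))
setMethod("parallelComplement", "DNAString",
          function(x) Biostrings::complement(x))
setMethod("parallelComplement", "DNAStringSet",
          function(x) Biostrings::complement(x))
setMethod("reverseSequence", "DNAString",
          function(x) Biostrings::reverse(x))
setMethod("reverseSequence", "DNAStringSet",
          function(x) Biostrings::reverse(x))
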