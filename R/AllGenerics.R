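#' @title Generics
#' @description Generic definitions for the sequence transforms and
#'   accessors. Character methods operate on validated plain strings;
#'   \code{DNAString}/\code{DNAStringSet} methods delegate to Biostrings and
#'   return the same class.
#' @param x a character vector, \code{DNAString} or \code{DNAStringSet}.
#' @name transforms
NULL

#' @rdname transforms
#' @export
setGeneric("antiparallelComplement",
           function(x) standardGeneric("antiparallelComplement"))

#' @rdname transforms
#' @export
setGeneric("parallelComplement",
           function(x) standardGeneric("parallelComplement"))

#' @rdname transforms
#' @export
setGeneric("reverseSequence", function(x) standardGeneric("reverseSequence"))

#' @rdname Strand-class
#' @param object,x a \linkS4class{Strand}.
#' @export
setGeneric("strandSeq", function(x) standardGeneric("strandSeq"))

#' @rdname Strand-class
#' @export
setGeneric("strandLabel", function(x) standardGeneric("strandLabel"))

#' @rdname Strand-class
#' @export
setGeneric("strandOrigin", function(x) standardGeneric("strandOrigin"))

#' @rdname AmpliconReport-class
#' @param x an \linkS4class{AmpliconReport}.
#' @export
setGeneric("amplicons", function(x) standardGeneric("amplicons"))

#' @rdname AmpliconReport-class
#' @export
setGeneric("trajectory", function(x) standardGeneric("trajectory"))

#' @rdname AmpliconReport-class
#' @export
setGeneric("runoffStrands", function(x) standardGeneric("runoffStrands"))

#' @rdname AmpliconReport-class
#' @export
setGeneric("initialCopies", function(x) standardGeneric("initialCopies"))

#' @rdname PrimerPair-class
#' @param x a \linkS4class{PrimerPair}.
#' @export
setGeneric("primer1", function(x) standardGeneric("primer1"))

#' @rdname PrimerPair-class
#' @export
setGeneric("primer2", function(x) standardGeneric("primer2"))

#' @rdname PrimerPair-class
#' @export
setGeneric("pairScheme", function(x) standardGeneric("pairScheme"))

#' @rdname PrimerPair-class
#' @export
setGeneric("productLength", function(x) standardGeneric("productLength"))

setMethod("strandSeq", "Strand", function(x) x@seq)
setMethod("strandLabel", "Strand", function(x) x@label)
setMethod("strandOrigin", "Strand", function(x) x@origin)

setMethod("amplicons", "AmpliconReport", function(x) x@amplicons)
setMethod("trajectory", "AmpliconReport", function(x) x@trajectory)
setMethod("runoffStrands", "AmpliconReport", function(x) x@runoffs)
setMethod("initialCopies", "AmpliconReport", function(x) x@initialCopies)

setMethod("primer1", "PrimerPair", function(x) x@primer1)
setMethod("primer2", "PrimerPair", function(x) x@primer2)
setMethod("pairScheme", "PrimerPair", function(x) x@scheme)
setMethod("productLength", "PrimerPair",
          function(x) x@predictedProductLength)

setMethod("show", "Strand", function(object) {
  cat(sprintf("Strand '%s' (%s), %d nt: %s\n", object@label, object@origin,
              nchar(object@seq), .abbrevSeq(object@seq)))
})

setMethod("show", "BindingSite", function(object) {
  cat(sprintf(
    "BindingSite %s on %s [%d,%d) %s, %d mismatch(es), Tm %.1f C\n",
    object@primerLabel, object@templateLabel, object@start, object@end,
    object@mode, object@mismatches, object@tmCelsius))
})

setMethod("show", "PrimerPair", function(object) {
  cat(sprintf("PrimerPair (%s scheme)\n", object@scheme))
  cat(sprintf("  primer1: %s [%d,%d)\n", object@primer1,
              object@footprint1[1], object@footprint1[2]))
  cat(sprintf("  primer2: %s [%d,%d)\n", object@primer2,
              object@footprint2[1], object@footprint2[2]))
  cat(sprintf("  predicted product: %d nt\n",
              object@predictedProductLength))
})

setMethod("show", "AmpliconReport", function(object) {
  cat(sprintf(
    "AmpliconReport: %d amplicon(s), %d run-off strand(s), %d cycle(s)%s\n",
    nrow(object@amplicons), nrow(object@runoffs), object@protocol@cycles,
    if (object@allowParallel) ", parallel annealing enabled" else ""))
  if (nrow(object@amplicons)) {
    for (i in seq_len(nrow(object@amplicons))) {
      a <- object@amplicons[i, ]
      cat(sprintf("  [%d] %d bp: %s / %s\n", i, a$lengthNt,
                  .abbrevSeq(a$topSeq), .abbrevSeq(a$bottomSeq)))
    }
  }
})

setMethod("show", "PairVerification", function(object) {
  cat(sprintf(
    "PairVerification: %s (%d amplicon(s), expected %d nt, observed %s)\n",
    if (object@verified) "verified" else "NOT verified", object@nAmplicons,
    object@expectedLengthNt,
    if (is.na(object@observedLengthNt)) "none"
    else paste0(object@observedLengthNt, " nt")))
})

setMethod("show", "QPCRResult", function(object) {
  cat(sprintf("QPCRResult: Ct(target) %.2f, Ct(reference) %.2f, 2^-dCt %.4g\n",
              object@ctTarget, object@ctReference, object@relativeQuantity))
})

.abbrevSeq <- function(s, n = 34L) {
  if (nchar(s) <= n) s else
    paste0(substr(s, 1, n %/% 2), "...",
           substr(s, nchar(s) - n %/% 2 + 1, nchar(s)))
}
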