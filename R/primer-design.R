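.makePair <- function(scheme, primer1, primer2, fp1, fp2) {
  span <- max(fp1[2], fp2[2]) - min(fp1[1], fp2[1])
  new("PrimerPair", scheme = scheme, primer1 = primer1, primer2 = primer2,
      footprint1 = as.integer(fp1), footprint2 = as.integer(fp2),
      predictedProductLength = as.integer(span))
}

.checkDesignLengths <- function(len, l1, l2, off1, off2) {
  if (l1 < 1L || l2 < 1L) stop("primer lengths must be >= 1")
  if (off1 < 0L || off2 < 0L) stop("offsets must be >= 0")
  if (off1 + l1 + l2 + off2 > len)
    stop("primer lengths (plus offsets) exceed the template")
}

#' Design a conventional (antiparallel) primer pair
#'
#' Positional design as used for a known single-stranded template: the
#' forward primer (primer2) is the template's 5' prefix (it anneals
#' antiparallel to the newly synthesised complementary strand) and the
#' reverse primer (primer1) is the antiparallel complement of the
#' template's 3' suffix (it anneals antiparallel to the template itself).
#' Primers sit flush with the template ends unless offsets (from the
#' respective end) are given.
#'
#' @param template template sequence (character, validated).
#' @param fwdLen,revLen primer lengths (nt).
#' @param fwdOffset,revOffset distances (nt) from the template 5'/3' end.
#' @return a \linkS4class{PrimerPair} with scheme \code{"conventional"}.
#' @examples
#' designConventionalPair("ACGTACGT", 4, 4)
#' @export
designConventionalPair <- function(template, fwdLen = 21, revLen = 22,
                                   fwdOffset = 0, revOffset = 0) {
  t <- validateSequence(template)
  len <- nchar(t)
  fwdLen <- as.integer(fwdLen); revLen <- as.integer(revLen)
  fwdOffset <- as.integer(fwdOffset); revOffset <- as.integer(revOffset)
  .checkDesignLengths(len, fwdLen, revLen, fwdOffset, revOffset)
  fp2 <- c(fwdOffset, fwdOffset + fwdLen)
  fp1 <- c(len - revOffset - revLen, len - revOffset)
  fwd <- substr(t, fp2[1] + 1L, fp2[2])
  rev <- .rev(.comp(substr(t, fp1[1] + 1L, fp1[2])))
  .makePair("conventional", primer1 = rev, primer2 = fwd, fp1, fp2)
}

#' Design a PD-PCR primer pair
#'
#' Positional design for the parallel-DNA scheme: primer1 is the parallel
#' (order-preserving) complement of the template's 5' prefix — it anneals to
#' the template in parallel orientation and is extended toward the
#' template's 3' end — and primer2 is the reversal of the template's 3'
#' suffix, which anneals antiparallel to the newly synthesised
#' parallel-complement strand. The resulting amplicon has polarity opposite
#' to the template: its strands are the parallel complement and the
#' reversal of the template span.
#'
#' @param template template sequence (character, validated).
#' @param p1Len,p2Len primer lengths (nt).
#' @param p1Offset,p2Offset distances (nt) from the template 5'/3' end.
#' @return a \linkS4class{PrimerPair} with scheme \code{"pdpcr"}.
#' @examples
#' designPdpcrPair("AAAATTTTCCCCGGGGAAAATTTTCCCCGGGGAAAATTTT", 8, 8)
#' @export
designPdpcrPair <- function(template, p1Len = 22, p2Len = 20,
                            p1Offset = 0, p2Offset = 0) {
  t <- validateSequence(template)
  len <- nchar(t)
  p1Len <- as.integer(p1Len); p2Len <- as.integer(p2Len)
  p1Offset <- as.integer(p1Offset); p2Offset <- as.integer(p2Offset)
  .checkDesignLengths(len, p1Len, p2Len, p1Offset, p2Offset)
  fp1 <- c(p1Offset, p1Offset + p1Len)
  fp2 <- c(len - p2Offset - p2Len, len - p2Offset)
  p1 <- .comp(substr(t, fp1[1] + 1L, fp1[2]))
  p2 <- .rev(substr(t, fp2[1] + 1L, fp2[2]))
  .makePair("pdpcr", primer1 = p1, primer2 = p2, fp1, fp2)
}

#' Verify a primer pair against its scheme
#'
#' Re-simulates amplification of the template with the pair under its
#' scheme (parallel annealing enabled only for PD-PCR pairs, unless
#' overridden) and reports whether exactly one amplicon of the predicted
#' length results. The annealing temperature defaults to the pair's
#' limiting predicted Tm — the minimum over both primers, with the
#' parallel-duplex penalty applied when parallel annealing is in play — so
#' that verification is well defined for arbitrary templates; pass a
#' \code{protocol} to pin it.
#'
#' @param template template sequence (character, validated).
#' @param pair a \linkS4class{PrimerPair}.
#' @param protocol optional \linkS4class{CycleProtocol}; default: 30 cycles
#'   at the pair's limiting Tm.
#' @param allowParallel override the scheme's parallel-annealing setting.
#' @param initialCopies input copies (default 100).
#' @param tmModel \linkS4class{TmModel}.
#' @return a \linkS4class{PairVerification}.
#' @examples
#' pair <- designConventionalPair("ACGGACTGACTTACGATCGGATCCGATTACGCGATATCGG", 18, 18)
#' verifyPair("ACGGACTGACTTACGATCGGATCCGATTACGCGATATCGG", pair)
#' @export
verifyPair <- function(template, pair, protocol = NULL,
                       allowParallel = NULL, initialCopies = 100,
                       tmModel = TmModel()) {
  stopifnot(is(pair, "PrimerPair"))
  t <- validateSequence(template)
  if (is.null(allowParallel)) allowParallel <- pair@scheme == "pdpcr"
  primers <- c(primer1 = pair@primer1, primer2 = pair@primer2)
  if (is.null(protocol)) {
    tms <- meltingTemperature(primers, "antiparallel", tmModel)
    if (allowParallel) tms <- tms - tmModel@psPenaltyCelsius
    anneal <- max(min(tms), 1)
    protocol <- CycleProtocol(cycles = 30, annealCelsius = min(anneal, 99))
  }
  rep <- runPCR(t, primers, protocol = protocol,
                allowParallel = allowParallel,
                initialCopies = initialCopies, tmModel = tmModel)
  amp <- rep@amplicons
  obs <- if (nrow(amp) == 1L) as.integer(amp$lengthNt[1]) else NA_integer_
  new("PairVerification",
      verified = nrow(amp) == 1L &&
        identical(obs, pair@predictedProductLength),
      nAmplicons = nrow(amp),
      expectedLengthNt = pair@predictedProductLength,
      observedLengthNt = obs,
      strands = if (nrow(amp) == 1L) c(amp$topSeq[1], amp$bottomSeq[1])
                else character(0),
      report = rep)
}
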