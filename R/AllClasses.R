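#' @importFrom methods new validObject is setClass setGeneric setMethod
#'   setValidity slot show
NULL

.ORIGINS <- c("input", "primer_extension")
.MODES <- c("antiparallel", "parallel")
.SCHEMES <- c("conventional", "pdpcr")
.SCHEMA_VERSION <- "1.0"

#' Duplex-mode-aware melting temperature model
#'
#' The Wallace rule, Tm = 2(A+T) + 4(G+C) in degrees Celsius, with a constant
#' penalty subtracted for parallel-stranded (reverse Watson-Crick) duplexes.
#' The default penalty of 15 degrees reflects the observed destabilisation of
#' parallel-stranded DNA relative to its antiparallel counterpart at matched
#' salt conditions.
#'
#' @slot rule character(1), the Tm rule; only \code{"wallace"} is supported.
#' @slot psPenaltyCelsius numeric(1), non-negative penalty (degrees C)
#'   subtracted from the antiparallel Tm when the duplex is parallel-stranded.
#' @export
setClass("TmModel",
  representation(rule = "character", psPenaltyCelsius = "numeric"),
  prototype(rule = "wallace", psPenaltyCelsius = 15)
)

setValidity("TmModel", function(object) {
  if (length(object@rule) != 1L || !object@rule %in% "wallace")
    return("unsupported Tm rule (only 'wallace' is available)")
  if (length(object@psPenaltyCelsius) != 1L ||
      is.na(object@psPenaltyCelsius) || object@psPenaltyCelsius < 0)
    return("psPenaltyCelsius must be a single non-negative number")
  TRUE
})

#' @param rule Tm rule name; only \code{"wallace"}.
#' @param psPenaltyCelsius penalty (degrees C) for parallel duplexes.
#' @rdname TmModel-class
#' @export
TmModel <- function(rule = "wallace", psPenaltyCelsius = 15) {
  new("TmModel", rule = rule, psPenaltyCelsius = psPenaltyCelsius)
}

#' Cycling protocol
#'
#' Holds the cycle count and temperatures of a denature/anneal/extend
#' protocol. Only \code{cycles} and \code{annealCelsius} affect the
#' simulation; denaturation and extension temperatures are recorded for
#' provenance (denaturation is assumed complete and extension ideal).
#'
#' @slot cycles integer(1), number of cycles (>= 1).
#' @slot annealCelsius numeric(1), annealing temperature in (0, 100).
#' @slot denatureCelsius,extendCelsius numeric(1), recorded only.
#' @export
setClass("CycleProtocol",
  representation(cycles = "integer", annealCelsius = "numeric",
                 denatureCelsius = "numeric", extendCelsius = "numeric"),
  prototype(cycles = 30L, annealCelsius = 55, denatureCelsius = 95,
            extendCelsius = 72)
)

setValidity("CycleProtocol", function(object) {
  if (length(object@cycles) != 1L || is.na(object@cycles) ||
      object@cycles < 1L)
    return("cycles must be a single integer >= 1")
  if (length(object@annealCelsius) != 1L || is.na(object@annealCelsius) ||
      object@annealCelsius <= 0 || object@annealCelsius >= 100)
    return("annealCelsius must lie strictly between 0 and 100")
  TRUE
})

#' @param cycles number of cycles.
#' @param annealCelsius annealing temperature (degrees C).
#' @param denatureCelsius,extendCelsius recorded temperatures (degrees C).
#' @rdname CycleProtocol-class
#' @export
CycleProtocol <- function(cycles = 30, annealCelsius = 55,
                          denatureCelsius = 95, extendCelsius = 72) {
  new("CycleProtocol", cycles = as.integer(cycles),
      annealCelsius = annealCelsius, denatureCelsius = denatureCelsius,
      extendCelsius = extendCelsius)
}

#' Single DNA strand
#'
#' A labelled single strand. The sequence is always stored in 5'->3' reading
#' order; polarity relative to other strands is a property of containers
#' (duplexes, reports), never of the stored string.
#'
#' @slot seq character(1), validated uppercase A/C/G/T sequence, 5'->3'.
#' @slot label character(1), display label.
#' @slot origin \code{"input"} or \code{"primer_extension"}.
#' @export
setClass("Strand",
  representation(seq = "character", label = "character", origin = "character"),
  prototype(origin = "input")
)

setValidity("Strand", function(object) {
  if (length(object@seq) != 1L || grepl("[^ACGT]", object@seq) ||
      nchar(object@seq) < 1L)
    return("seq must be a single non-empty A/C/G/T string")
  if (length(object@label) != 1L || is.na(object@label))
    return("label must be a single string")
  if (!object@origin %in% .ORIGINS)
    return("origin must be 'input' or 'primer_extension'")
  TRUE
})

#' @param seq raw sequence (validated and normalised).
#' @param label strand label.
#' @param origin \code{"input"} or \code{"primer_extension"}.
#' @rdname Strand-class
#' @export
Strand <- function(seq, label = "strand", origin = "input") {
  new("Strand", seq = validateSequence(seq), label = label, origin = origin)
}

#' Primer binding site
#'
#' An alignment of a primer to a single strand. Coordinates are 0-based and
#' half-open on the bound strand's own 5'->3' axis. In antiparallel mode the
#' primer's 3' end faces the window start; in parallel mode primer position i
#' pairs with window position i (both strands read 5'->3' left to right) and
#' the 3' end faces the window end.
#'
#' @slot primer character(1), primer sequence (5'->3').
#' @slot primerLabel,templateLabel character(1) labels.
#' @slot start,end integer(1), 0-based half-open window on the strand.
#' @slot mode \code{"antiparallel"} or \code{"parallel"}.
#' @slot mismatches integer(1), number of mismatched base pairs.
#' @slot tmCelsius numeric(1), predicted duplex Tm under the model in force.
#' @export
setClass("BindingSite",
  representation(primer = "character", primerLabel = "character",
                 templateLabel = "character", start = "integer",
                 end = "integer", mode = "character",
                 mismatches = "integer", tmCelsius = "numeric")
)

setValidity("BindingSite", function(object) {
  if (!object@mode %in% .MODES) return("invalid pairing mode")
  if (object@start < 0L || object@end <= object@start)
    return("require 0 <= start < end")
  if (object@end - object@start != nchar(object@primer))
    return("end - start must equal the primer length")
  if (object@mismatches < 0L) return("mismatches must be >= 0")
  TRUE
})

#' Pool of single strands with copy counts
#'
#' A multiset of strands: one entry per distinct (sequence, origin) pair with
#' a non-negative copy count. Counts are stored as doubles but always hold
#' exact integers (they exceed 32-bit range within 30 ideal cycles).
#'
#' @slot strands list of \linkS4class{Strand}.
#' @slot counts numeric vector of copy counts, parallel to \code{strands}.
#' @slot initialCopies numeric(1), total input copies at cycle 0.
#' @export
setClass("StrandPool",
  representation(strands = "list", counts = "numeric",
                 initialCopies = "numeric")
)

setValidity("StrandPool", function(object) {
  if (length(object@strands) != length(object@counts))
    return("strands and counts must have equal length")
  if (any(object@counts < 0) || any(object@counts != floor(object@counts)))
    return("counts must be non-negative integers")
  if (!all(vapply(object@strands, is, logical(1), class2 = "Strand")))
    return("strands must all be Strand objects")
  TRUE
})

#' Amplification report
#'
#' Result of \code{\link{runPCR}}: the distinct primer-bounded duplex
#' products (amplicons), linear run-off strands, the per-cycle copy-number
#' trajectory, and the run's provenance. Both strands of every amplicon are
#' primer-initiated mutual antiparallel complements; run-off strands are
#' primer-initiated but unpaired, and are never reported as products.
#'
#' @slot amplicons data.frame: topLabel, topSeq, topPrimer, bottomLabel,
#'   bottomSeq, bottomPrimer, lengthNt, selfComplementary.
#' @slot runoffs data.frame: label, sequence, count.
#' @slot strands data.frame: label, sequence, countInput, countExtension.
#' @slot trajectory data.frame (long): cycle, label, count; cycle 0 is the
#'   input pool.
#' @slot initialCopies numeric(1), total input template copies.
#' @slot protocol \linkS4class{CycleProtocol} used.
#' @slot allowParallel logical(1), whether parallel annealing was permitted.
#' @slot primers named character vector of primer sequences.
#' @slot schemaVersion character(1), report schema version.
#' @export
setClass("AmpliconReport",
  representation(amplicons = "data.frame", runoffs = "data.frame",
                 strands = "data.frame", trajectory = "data.frame",
                 initialCopies = "numeric", protocol = "CycleProtocol",
                 allowParallel = "logical", primers = "character",
                 schemaVersion = "character"),
  prototype(schemaVersion = .SCHEMA_VERSION)
)

#' Scheme-labelled primer pair
#'
#' A conventional or PD-PCR primer pair with its template footprints
#' (0-based, half-open intervals on the template's 5'->3' axis) and the
#' predicted product length (span from the leftmost footprint start to the
#' rightmost footprint end).
#'
#' @slot scheme \code{"conventional"} or \code{"pdpcr"}.
#' @slot primer1,primer2 character(1) primer sequences (5'->3').
#' @slot footprint1,footprint2 integer(2), c(start, end) template intervals.
#' @slot predictedProductLength integer(1), nt.
#' @export
setClass("PrimerPair",
  representation(scheme = "character", primer1 = "character",
                 primer2 = "character", footprint1 = "integer",
                 footprint2 = "integer", predictedProductLength = "integer")
)

setValidity("PrimerPair", function(object) {
  if (!object@scheme %in% .SCHEMES)
    return("scheme must be 'conventional' or 'pdpcr'")
  for (fp in list(object@footprint1, object@footprint2)) {
    if (length(fp) != 2L || fp[1] < 0L || fp[2] <= fp[1])
      return("footprints must be 0-based half-open c(start, end) intervals")
  }
  span <- max(object@footprint1[2], object@footprint2[2]) -
    min(object@footprint1[1], object@footprint2[1])
  if (object@predictedProductLength != span)
    return("predictedProductLength must equal the footprint span")
  TRUE
})

#' Pair verification result
#'
#' Produced by \code{\link{verifyPair}}: whether re-simulating the pair under
#' its scheme yields exactly one amplicon of the predicted length.
#'
#' @slot verified logical(1).
#' @slot nAmplicons integer(1).
#' @slot expectedLengthNt integer(1).
#' @slot observedLengthNt integer(1), NA when no amplicon formed.
#' @slot strands character, the product strand sequences (length 0 or 2).
#' @slot report the underlying \linkS4class{AmpliconReport}.
#' @export
setClass("PairVerification",
  representation(verified = "logical", nAmplicons = "integer",
                 expectedLengthNt = "integer", observedLengthNt = "integer",
                 strands = "character", report = "AmpliconReport")
)

#' Relative quantification result
#'
#' Threshold cycles of a target and a reference reaction together with the
#' 2^-dCt relative quantity.
#'
#' @slot ctTarget,ctReference numeric(1) threshold cycles.
#' @slot relativeQuantity numeric(1), 2^-(ctTarget - ctReference).
#' @export
setClass("QPCRResult",
  representation(ctTarget = "numeric", ctReference = "numeric",
                 relativeQuantity = "numeric")
)

setValidity("QPCRResult", function(object) {
  if (!is.finite(object@ctTarget) || !is.finite(object@ctReference))
    return("Ct values must be finite")
  if (object@relativeQuantity <= 0)
    return("relativeQuantity must be positive")
  TRUE
})
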