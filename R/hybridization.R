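#' Duplex-mode-aware melting temperature
#'
#' Wallace rule, Tm = 2(#A + #T) + 4(#G + #C) degrees C, for an antiparallel
#' duplex; for a parallel (reverse Watson-Crick) duplex the model's
#' parallel-strand penalty (default 15 C) is subtracted. The antiparallel
#' value depends only on primer composition, never on the template.
#'
#' @param primer primer sequence (character, validated on entry).
#' @param mode \code{"antiparallel"} or \code{"parallel"}.
#' @param model a \linkS4class{TmModel}.
#' @return predicted Tm in degrees Celsius (vectorised over \code{primer}).
#' @examples
#' meltingTemperature("ACGTACGTACGT", "antiparallel")
#' @export
meltingTemperature <- function(primer, mode = c("antiparallel", "parallel"),
                               model = TmModel()) {
  mode <- match.arg(mode)
  validObject(model)
  s <- vapply(primer, validateSequence, character(1), USE.NAMES = FALSE)
  nGC <- nchar(gsub("[AT]", "", s))
  nAT <- nchar(s) - nGC
  tm <- 2 * nAT + 4 * nGC
  if (mode == "parallel") tm <- tm - model@psPenaltyCelsius
  tm
}

#' Find primer binding sites on a single strand
#'
#' Slides the primer along the strand and reports every window the primer can
#' pair with, in antiparallel (Watson-Crick) and/or parallel (reverse
#' Watson-Crick) orientation, allowing up to \code{maxMismatches} mismatched
#' pairs. The primer's 3'-terminal \code{minAnchor} bases must pair exactly
#' in either mode (polymerases do not extend a mismatched 3' end). In
#' antiparallel mode the primer's 3' end faces the window's template-5' side;
#' in parallel mode primer position i pairs with window position i and the 3'
#' end faces the window's template-3' side.
#'
#' Sites are returned sorted by decreasing Tm, then increasing start.
#'
#' @param primer primer sequence (character(1)).
#' @param strand a \linkS4class{Strand} or character(1) sequence.
#' @param mode \code{"antiparallel"}, \code{"parallel"} or \code{"both"}.
#' @param maxMismatches maximum mismatched pairs per site (default 0:
#'   perfect match).
#' @param minAnchor exact-match 3' anchor length; default = primer length.
#' @param tmModel \linkS4class{TmModel} used to score sites.
#' @param primerLabel label recorded in the sites.
#' @return list of \linkS4class{BindingSite}.
#' @examples
#' findBindingSites("CGCG", "ATCGCGAT", mode = "antiparallel")
#' @export
findBindingSites <- function(primer, strand,
                             mode = c("antiparallel", "parallel", "both"),
                             maxMismatches = 0L, minAnchor = NULL,
                             tmModel = TmModel(), primerLabel = "primer") {
  mode <- match.arg(mode)
  primer <- validateSequence(primer)
  if (is(strand, "Strand")) {
    tmplSeq <- strand@seq
    tmplLab <- strand@label
  } else {
    tmplSeq <- validateSequence(strand)
    tmplLab <- "strand"
  }
  L <- nchar(primer)
  S <- nchar(tmplSeq)
  if (L > S) stop("primer is longer than the strand")
  if (maxMismatches < 0L) stop("maxMismatches must be >= 0")
  if (is.null(minAnchor)) minAnchor <- L
  if (minAnchor > L) stop("minAnchor cannot exceed the primer length")
  modes <- if (mode == "both") .MODES else mode

  sv <- strsplit(tmplSeq, "")[[1]]
  sites <- list()
  for (m in modes) {
    # expected window sequence if pairing were perfect, and the window
    # positions that must match exactly (the primer's 3' anchor)
    if (m == "antiparallel") {
      qv <- strsplit(.rev(.comp(primer)), "")[[1]]
      anchorIdx <- seq_len(minAnchor)
    } else {
      qv <- strsplit(.comp(primer), "")[[1]]
      anchorIdx <- seq.int(L - minAnchor + 1L, L)
    }
    if (minAnchor == 0L) anchorIdx <- integer(0)
    tm <- meltingTemperature(primer, m, tmModel)
    for (st in 0:(S - L)) {
      w <- sv[(st + 1L):(st + L)]
      neq <- w != qv
      if (sum(neq) <= maxMismatches && !any(neq[anchorIdx])) {
        sites[[length(sites) + 1L]] <- new("BindingSite",
          primer = primer, primerLabel = primerLabel,
          templateLabel = tmplLab, start = as.integer(st),
          end = as.integer(st + L), mode = m,
          mismatches = as.integer(sum(neq)), tmCelsius = tm)
      }
    }
  }
  if (length(sites) > 1L) {
    tms <- vapply(sites, slot, numeric(1), name = "tmCelsius")
    starts <- vapply(sites, slot, integer(1), name = "start")
    sites <- sites[order(-tms, starts)]
  }
  sites
}

#' Tabulate binding sites
#'
#' @param sites a list of \linkS4class{BindingSite} (as returned by
#'   \code{\link{findBindingSites}}).
#' @return data.frame with one row per site.
#' @export
bindingSiteTable <- function(sites) {
  if (length(sites) == 0L) {
    return(data.frame(primerLabel = character(0),
                      templateLabel = character(0), start = integer(0),
                      end = integer(0), mode = character(0),
                      mismatches = integer(0), tmCelsius = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(sites, function(s) data.frame(
    primerLabel = s@primerLabel, templateLabel = s@templateLabel,
    start = s@start, end = s@end, mode = s@mode,
    mismatches = s@mismatches, tmCelsius = s@tmCelsius,
    stringsAsFactors = FALSE)))
}
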