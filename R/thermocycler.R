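#' Extend a primer from a binding site
#'
#' Run-off extension of an annealed primer. In antiparallel mode synthesis
#' proceeds toward the template's 5' end, so the product is the primer
#' followed by the antiparallel complement of the template upstream of the
#' window; with a perfect-match site this equals
#' \code{antiparallelComplement(template[0:end))}. In parallel mode the
#' primer is paired in the same 5'->3' direction as the template and
#' synthesis proceeds toward the template's 3' end, appending
#' order-preserving complements; with a perfect-match site the product
#' equals \code{parallelComplement(template[start:length))}. Products are
#' stored 5'->3' with origin \code{"primer_extension"}.
#'
#' @param site a \linkS4class{BindingSite} on \code{template}.
#' @param template the bound \linkS4class{Strand} (or character sequence).
#' @return the product \linkS4class{Strand}.
#' @export
extendPrimer <- function(site, template) {
  stopifnot(is(site, "BindingSite"))
  if (is(template, "Strand")) {
    tseq <- template@seq
  } else {
    tseq <- validateSequence(template)
  }
  S <- nchar(tseq)
  if (site@end > S)
    stop("site does not fit on the template")
  # the site must actually lie on this template (up to recorded mismatches)
  w <- substr(tseq, site@start + 1L, site@end)
  expect <- if (site@mode == "antiparallel") .rev(.comp(site@primer))
            else .comp(site@primer)
  mm <- sum(strsplit(w, "")[[1]] != strsplit(expect, "")[[1]])
  if (mm != site@mismatches)
    stop("site/template mismatch: window does not pair with the primer ",
         "as recorded")
  prod <- if (site@mode == "antiparallel") {
    flank <- if (site@start > 0L) .rev(.comp(substr(tseq, 1L, site@start)))
             else ""
    paste0(site@primer, flank)
  } else {
    flank <- if (site@end < S) .comp(substr(tseq, site@end + 1L, S)) else ""
    paste0(site@primer, flank)
  }
  new("Strand", seq = prod, label = paste0(site@primerLabel, ".ext"),
      origin = "primer_extension")
}

.asStrandList <- function(templates) {
  if (is.null(templates)) return(list())
  if (is(templates, "Strand")) return(list(templates))
  if (is(templates, "DNAStringSet")) {
    seqs <- as.character(templates)
    nm <- names(templates)
    if (is.null(nm)) nm <- paste0("template", seq_along(seqs))
    return(mapply(function(s, n) Strand(s, n, "input"), seqs, nm,
                  SIMPLIFY = FALSE, USE.NAMES = FALSE))
  }
  if (is.character(templates)) {
    if (length(templates) == 0L) return(list())
    nm <- names(templates)
    if (is.null(nm)) nm <- if (length(templates) == 1L) "template"
                           else paste0("template", seq_along(templates))
    return(mapply(function(s, n) Strand(s, n, "input"), templates, nm,
                  SIMPLIFY = FALSE, USE.NAMES = FALSE))
  }
  if (is.list(templates)) {
    stopifnot(all(vapply(templates, is, logical(1), class2 = "Strand")))
    return(templates)
  }
  stop("unsupported template type")
}

.asPrimerVector <- function(primers) {
  if (is(primers, "DNAStringSet")) {
    p <- as.character(primers)
    if (is.null(names(p))) names(p) <- paste0("primer", seq_along(p))
    p <- vapply(p, validateSequence, character(1))
    return(p)
  }
  if (!is.character(primers) || length(primers) < 1L)
    stop("at least one primer is required")
  nm <- names(primers)
  if (is.null(nm)) nm <- paste0("primer", seq_along(primers))
  p <- vapply(primers, validateSequence, character(1), USE.NAMES = FALSE)
  names(p) <- nm
  p
}

#' Simulate cycles of denature/anneal/extend over a strand pool
#'
#' Deterministic in-silico thermocycler. Every cycle, all strands in the
#' pool are treated as available single-stranded templates (denaturation is
#' assumed complete); each primer anneals to each strand at its best
#' feasible site — predicted Tm at least \code{annealCelsius}, ties broken
#' by highest Tm then leftmost start, parallel-orientation sites considered
#' only when \code{allowParallel} — and produces one run-off extension
#' product per template copy (ideal efficiency). Copy bookkeeping is exact;
#' strands are never destroyed. After the final cycle, amplicons are the
#' duplexes whose two strands are mutual antiparallel complements, each
#' carrying primer-extension copies and beginning (5') with one of the
#' supplied primers; primer-initiated strands not in such a duplex are
#' reported separately as linear run-off strands.
#'
#' With \code{efficiency < 1}, each (primer, strand) priming event converts
#' a Binomial(copies, efficiency) number of copies instead, drawn from R's
#' RNG after \code{set.seed(seed)}; this is intended for stochastic property
#' checks, not for the default model.
#'
#' @param templates input single strands: character vector, Strand,
#'   \code{DNAStringSet}, or list of \linkS4class{Strand}; may be empty (a
#'   no-template control).
#' @param primers named character vector or \code{DNAStringSet} (>= 1).
#' @param protocol a \linkS4class{CycleProtocol}.
#' @param allowParallel permit parallel-orientation annealing (the PD-PCR
#'   scheme requires it; conventional PCR does not).
#' @param initialCopies input copies per template strand (default 100).
#' @param efficiency per-event priming probability (default 1 = ideal).
#' @param seed RNG seed used when \code{efficiency < 1}.
#' @param tmModel \linkS4class{TmModel} scoring annealing feasibility.
#' @param maxMismatches,minAnchor site-search stringency (defaults: perfect
#'   match over the full primer).
#' @return an \linkS4class{AmpliconReport}.
#' @examples
#' t <- "GCGCATGACTGACTGACTGAGTCCTGACGTTTACGTACGGATCTTGCCGG"
#' pair <- designConventionalPair(t, 18, 18)
#' rep <- runPCR(t, c(fwd = primer2(pair), rev = primer1(pair)),
#'               CycleProtocol(cycles = 5, annealCelsius = 40))
#' amplicons(rep)
#' @importFrom stats rbinom
#' @export
runPCR <- function(templates, primers, protocol = CycleProtocol(),
                   allowParallel = FALSE, initialCopies = 100,
                   efficiency = 1, seed = NULL, tmModel = TmModel(),
                   maxMismatches = 0L, minAnchor = NULL) {
  validObject(protocol)
  tmpl <- .asStrandList(templates)
  prim <- .asPrimerVector(primers)
  if (efficiency <= 0 || efficiency > 1)
    stop("efficiency must be in (0, 1]")
  if (efficiency < 1) set.seed(if (is.null(seed)) 1L else seed)
  if (initialCopies < 1 && length(tmpl) > 0L)
    stop("initialCopies must be >= 1")

  # pool state: one entry per distinct sequence; input and extension copies
  # tracked separately (amplicon membership needs the distinction, the
  # trajectory pools them)
  seqs <- character(0); labels <- character(0)
  cntIn <- numeric(0); cntExt <- numeric(0)
  for (s in tmpl) {
    i <- match(s@seq, seqs)
    if (is.na(i)) {
      seqs <- c(seqs, s@seq); labels <- c(labels, s@label)
      cntIn <- c(cntIn, initialCopies); cntExt <- c(cntExt, 0)
    } else cntIn[i] <- cntIn[i] + initialCopies
  }
  totalInitial <- initialCopies * length(tmpl)

  mode <- if (allowParallel) "both" else "antiparallel"
  siteCache <- new.env(parent = emptyenv())
  bestSite <- function(pIdx, strandSeq, strandLab) {
    key <- paste0(pIdx, "|", strandSeq)
    if (!is.null(siteCache[[key]])) {
      s <- siteCache[[key]]
      return(if (is.logical(s)) NULL else s)
    }
    sites <- if (nchar(prim[pIdx]) <= nchar(strandSeq)) {
      findBindingSites(prim[pIdx], Strand(strandSeq, strandLab),
                       mode = mode, maxMismatches = maxMismatches,
                       minAnchor = minAnchor, tmModel = tmModel,
                       primerLabel = names(prim)[pIdx])
    } else list()
    hit <- NULL
    # sites come sorted by descending Tm then ascending start, so the first
    # one at or above the annealing temperature is the winner
    for (s in sites) if (s@tmCelsius >= protocol@annealCelsius) {
      hit <- s; break
    }
    siteCache[[key]] <- if (is.null(hit)) FALSE else hit
    hit
  }

  newLabel <- function(base) {
    lab <- base
    k <- 1L
    while (lab %in% labels) { k <- k + 1L; lab <- sprintf("%s.%d", base, k) }
    lab
  }

  traj <- list(data.frame(cycle = rep(0L, length(seqs)), label = labels,
                          count = cntIn + cntExt, stringsAsFactors = FALSE))

  for (cyc in seq_len(protocol@cycles)) {
    avail <- cntIn + cntExt  # snapshot: strands present at cycle start
    addSeq <- character(0); addLab <- character(0); addN <- numeric(0)
    for (i in seq_along(seqs)) {
      if (avail[i] <= 0) next
      for (p in seq_along(prim)) {
        site <- bestSite(p, seqs[i], labels[i])
        if (is.null(site)) next
        n <- if (efficiency < 1) rbinom(1L, avail[i], efficiency)
             else avail[i]
        if (n <= 0) next
        product <- extendPrimer(site, Strand(seqs[i], labels[i]))
        addSeq <- c(addSeq, product@seq)
        addLab <- c(addLab, paste0(names(prim)[p], ".product"))
        addN <- c(addN, n)
      }
    }
    for (j in seq_along(addSeq)) {
      i <- match(addSeq[j], seqs)
      if (is.na(i)) {
        seqs <- c(seqs, addSeq[j]); labels <- c(labels, newLabel(addLab[j]))
        cntIn <- c(cntIn, 0); cntExt <- c(cntExt, addN[j])
      } else cntExt[i] <- cntExt[i] + addN[j]
    }
    traj[[cyc + 1L]] <- data.frame(cycle = rep(cyc, length(seqs)),
                                   label = labels, count = cntIn + cntExt,
                                   stringsAsFactors = FALSE)
  }
  trajectory <- do.call(rbind, traj)
  if (is.null(trajectory))
    trajectory <- data.frame(cycle = integer(0), label = character(0),
                             count = numeric(0), stringsAsFactors = FALSE)

  # amplicon detection: primer-initiated strands with extension copies
  primerInit <- vapply(seqs, function(s)
    any(vapply(prim, function(p) startsWith(s, p), logical(1))),
    logical(1), USE.NAMES = FALSE)
  eligible <- which(cntExt > 0 & primerInit)
  whichPrimer <- function(s) {
    hits <- which(vapply(prim, function(p) startsWith(s, p), logical(1)))
    hits[1]
  }
  ampRows <- list()
  paired <- logical(length(seqs))
  for (a in eligible) {
    rc <- .rev(.comp(seqs[a]))
    b <- match(rc, seqs)
    if (is.na(b) || !(b %in% eligible)) next
    if (b < a) next  # already recorded from the other side
    pa <- whichPrimer(seqs[a]); pb <- whichPrimer(seqs[b])
    # deterministic orientation: top strand initiated by the earlier primer
    if (pb < pa || (pb == pa && seqs[b] < seqs[a])) {
      top <- b; bottom <- a
    } else {
      top <- a; bottom <- b
    }
    paired[a] <- paired[b] <- TRUE
    ampRows[[length(ampRows) + 1L]] <- data.frame(
      topLabel = labels[top], topSeq = seqs[top],
      topPrimer = names(prim)[whichPrimer(seqs[top])],
      bottomLabel = labels[bottom], bottomSeq = seqs[bottom],
      bottomPrimer = names(prim)[whichPrimer(seqs[bottom])],
      lengthNt = nchar(seqs[top]), selfComplementary = (a == b),
      stringsAsFactors = FALSE)
  }
  ampDf <- if (length(ampRows)) do.call(rbind, ampRows) else
    data.frame(topLabel = character(0), topSeq = character(0),
               topPrimer = character(0), bottomLabel = character(0),
               bottomSeq = character(0), bottomPrimer = character(0),
               lengthNt = integer(0), selfComplementary = logical(0),
               stringsAsFactors = FALSE)
  runoffIdx <- setdiff(eligible, which(paired))
  runoffs <- data.frame(label = labels[runoffIdx], sequence = seqs[runoffIdx],
                        count = cntExt[runoffIdx], stringsAsFactors = FALSE)
  strandsDf <- data.frame(label = labels, sequence = seqs,
                          countInput = cntIn, countExtension = cntExt,
                          stringsAsFactors = FALSE)
  new("AmpliconReport", amplicons = ampDf, runoffs = runoffs,
      strands = strandsDf, trajectory = trajectory,
      initialCopies = totalInitial, protocol = protocol,
      allowParallel = allowParallel, primers = prim,
      schemaVersion = .SCHEMA_VERSION)
}

#' Predicted threshold cycle
#'
#' First cycle (0 = input pool) at which the total copy count of the
#' amplicon strand sequences reaches \code{thresholdFold} times the initial
#' template copy number. Copies are counted by sequence, so an input
#' template that is sequence-identical to an amplicon strand (as in the
#' conventional scheme) contributes from cycle 0 — which is exactly why the
#' PD-PCR trajectory, whose amplicon strands both differ from the template,
#' crosses one cycle later under ideal doubling.
#'
#' @param report an \linkS4class{AmpliconReport}.
#' @param thresholdFold fold over the initial copies (default 2^10).
#' @return the crossing cycle as a number, or \code{NA} if never crossed
#'   (e.g. single-primer or no-template runs).
#' @export
thresholdCycle <- function(report, thresholdFold = 1024) {
  stopifnot(is(report, "AmpliconReport"))
  if (thresholdFold < 1) stop("thresholdFold must be >= 1")
  amp <- report@amplicons
  if (nrow(amp) == 0L) return(NA_real_)
  ampSeqs <- unique(c(amp$topSeq, amp$bottomSeq))
  ampLabels <- report@strands$label[report@strands$sequence %in% ampSeqs]
  tr <- report@trajectory[report@trajectory$label %in% ampLabels, ]
  byCycle <- tapply(tr$count, tr$cycle, sum)
  cycles <- as.integer(names(byCycle))
  hit <- which(byCycle >= thresholdFold * report@initialCopies)
  if (length(hit) == 0L) NA_real_ else as.numeric(cycles[min(hit)])
}

#' Relative quantity by the 2^-dCt method
#'
#' \code{2^-(ctTarget - ctReference)}: the abundance of the target relative
#' to the reference given their threshold cycles.
#'
#' @param ctTarget,ctReference finite threshold cycle numbers.
#' @return dimensionless relative quantity.
#' @examples
#' relativeQuantity(23.29, 9.26)
#' @export
relativeQuantity <- function(ctTarget, ctReference) {
  if (!all(is.finite(ctTarget)) || !all(is.finite(ctReference)))
    stop("Ct values must be finite")
  2^-(ctTarget - ctReference)
}

#' @rdname QPCRResult-class
#' @param ctTarget,ctReference threshold cycles.
#' @export
QPCRResult <- function(ctTarget, ctReference) {
  new("QPCRResult", ctTarget = ctTarget, ctReference = ctReference,
      relativeQuantity = relativeQuantity(ctTarget, ctReference))
}
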