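demoRun <- function(scheme, primers = NULL, templates = c(template = DEMO_TEMPLATE),
                    cycles = 30, anneal = 55) {
  if (is.null(primers)) {
    primers <- if (scheme == "conventional") DEMO_PRIMERS[c("PCR-1", "PCR-2")]
               else DEMO_PRIMERS[c("PD-PCR-1", "PD-PCR-2")]
  }
  runPCR(templates, primers, CycleProtocol(cycles, anneal),
         allowParallel = scheme == "pdpcr")
}

randSeqFixed <- function() {
  set.seed(99)
  randSeq(40)
}

test_that("run-off extension follows the annealing geometry", {
  t <- Strand(DEMO_TEMPLATE, "template")
  site <- findBindingSites(DEMO_PRIMERS[["PD-PCR-1"]], t,
                           mode = "parallel")[[1]]
  prod <- extendPrimer(site, t)
  expect_identical(strandSeq(prod), parallelComplement(DEMO_TEMPLATE))
  expect_identical(strandOrigin(prod), "primer_extension")

  site <- findBindingSites(DEMO_PRIMERS[["PCR-1"]], t,
                           mode = "antiparallel")[[1]]
  expect_identical(strandSeq(extendPrimer(site, t)),
                   antiparallelComplement(DEMO_TEMPLATE))

  # a primer covering the whole strand has nothing to extend
  s25 <- Strand("GATCGGATCCATGCATGCAAATGCA", "s25")
  primer <- antiparallelComplement(strandSeq(s25))
  site <- findBindingSites(primer, s25, mode = "antiparallel")[[1]]
  expect_identical(strandSeq(extendPrimer(site, s25)), primer)

  # site transplanted onto a non-matching template is refused
  other <- Strand(randSeqFixed(), "other")
  expect_error(extendPrimer(site, other), "mismatch")
})

test_that("the conventional scheme amplifies the template without polarity change", {
  rep <- demoRun("conventional")
  amp <- amplicons(rep)
  expect_identical(nrow(amp), 1L)
  expect_identical(amp$lengthNt, 120L)
  expect_setequal(c(amp$topSeq, amp$bottomSeq),
                  c(DEMO_TEMPLATE, antiparallelComplement(DEMO_TEMPLATE)))
  # ideal doubling of the amplicon-sequence copies: N * 2^cycle
  tr <- trajectory(rep)
  ampLab <- rep@strands$label[rep@strands$sequence %in%
                                c(amp$topSeq, amp$bottomSeq)]
  tot <- tapply(tr$count[tr$label %in% ampLab], tr$cycle[tr$label %in% ampLab],
                sum)
  expect_equal(as.numeric(tot), 100 * 2^(0:30))
})

test_that("the PD-PCR scheme yields the opposite-polarity product", {
  rep <- demoRun("pdpcr")
  amp <- amplicons(rep)
  expect_identical(nrow(amp), 1L)
  expect_identical(amp$lengthNt, 120L)
  expect_setequal(c(amp$topSeq, amp$bottomSeq),
                  c(parallelComplement(DEMO_TEMPLATE),
                    reverseSequence(DEMO_TEMPLATE)))
  # the two schemes give two different products from the same template
  conv <- amplicons(demoRun("conventional"))
  expect_length(intersect(c(amp$topSeq, amp$bottomSeq),
                          c(conv$topSeq, conv$bottomSeq)), 0)
  # PD-PCR is infeasible when parallel annealing is disabled
  off <- runPCR(c(template = DEMO_TEMPLATE),
                DEMO_PRIMERS[c("PD-PCR-1", "PD-PCR-2")],
                CycleProtocol(30, 55), allowParallel = FALSE)
  expect_identical(nrow(amplicons(off)), 0L)
})

test_that("single-primer and no-template controls yield no amplicons", {
  for (p in c("PCR-1", "PCR-2", "PD-PCR-1", "PD-PCR-2")) {
    rep <- runPCR(c(template = DEMO_TEMPLATE), DEMO_PRIMERS[p],
                  CycleProtocol(10, 55),
                  allowParallel = startsWith(p, "PD"))
    expect_identical(nrow(amplicons(rep)), 0L)
    expect_true(is.na(thresholdCycle(rep)))
  }
  # a single parallel primer still produces linear run-off strands
  rep <- runPCR(c(template = DEMO_TEMPLATE), DEMO_PRIMERS["PD-PCR-1"],
                CycleProtocol(10, 55), allowParallel = TRUE)
  expect_identical(nrow(runoffStrands(rep)), 1L)
  expect_identical(runoffStrands(rep)$sequence,
                   parallelComplement(DEMO_TEMPLATE))

  for (scheme in c("conventional", "pdpcr")) {
    rep <- demoRun(scheme, templates = character(0))
    expect_identical(nrow(amplicons(rep)), 0L)
  }
  expect_error(runPCR(c(template = DEMO_TEMPLATE), character(0)),
               "primer")
})

test_that("copy counts are conserved and non-decreasing", {
  for (scheme in c("conventional", "pdpcr")) {
    rep <- demoRun(scheme, cycles = 12)
    tr <- trajectory(rep)
    total <- tapply(tr$count, tr$cycle, sum)
    expect_true(all(diff(total) >= 0))
    perStrand <- split(tr, tr$label)
    for (ps in perStrand) expect_true(all(diff(ps$count[order(ps$cycle)]) >= 0))
    expect_true(all(tr$count == floor(tr$count)))
  }
})

test_that("PD-PCR crosses the threshold exactly one cycle after conventional PCR", {
  conv <- demoRun("conventional")
  pd <- demoRun("pdpcr")
  for (fold in 2^c(4, 7, 10)) {
    expect_identical(thresholdCycle(pd, fold),
                     thresholdCycle(conv, fold) + 1)
  }
  expect_identical(thresholdCycle(conv, 1024), 10)
  expect_identical(thresholdCycle(pd, 1024), 11)
  # already at threshold at fold 1: the input template is itself an
  # amplicon strand in the conventional scheme
  expect_identical(thresholdCycle(conv, 1), 0)
  # never crossed within the protocol
  short <- demoRun("conventional", cycles = 3)
  expect_true(is.na(thresholdCycle(short, 1024)))
})

test_that("the PD-PCR amplicon equals the conventional amplicon of the reversed template", {
  set.seed(314)
  for (i in 1:50) {
    t <- randSeq(sample(40:200, 1))
    if (t == reverseSequence(t)) next
    maxL <- min(25, nchar(t) %/% 2)
    l1 <- sample(18:maxL, 1); l2 <- sample(18:maxL, 1)
    pd <- designPdpcrPair(t, l1, l2)
    pdRep <- verifyPair(t, pd)@report
    convRev <- designConventionalPair(reverseSequence(t),
                                      fwdLen = l2, revLen = l1)
    convRep <- verifyPair(reverseSequence(t), convRev)@report
    a <- amplicons(pdRep); b <- amplicons(convRep)
    expect_identical(nrow(a), 1L)
    expect_setequal(c(a$topSeq, a$bottomSeq), c(b$topSeq, b$bottomSeq))
  }
})

test_that("identical inputs give bit-identical reports, including stochastic mode", {
  a <- demoRun("pdpcr", cycles = 8)
  b <- demoRun("pdpcr", cycles = 8)
  expect_identical(amplicons(a), amplicons(b))
  expect_identical(trajectory(a), trajectory(b))
  sa <- runPCR(c(template = DEMO_TEMPLATE),
               DEMO_PRIMERS[c("PCR-1", "PCR-2")], CycleProtocol(8, 55),
               efficiency = 0.7, seed = 123)
  sb <- runPCR(c(template = DEMO_TEMPLATE),
               DEMO_PRIMERS[c("PCR-1", "PCR-2")], CycleProtocol(8, 55),
               efficiency = 0.7, seed = 123)
  expect_identical(trajectory(sa), trajectory(sb))
  # sub-unit efficiency slows but does not derail amplification
  expect_lte(max(trajectory(sa)$count), max(trajectory(a)$count))
})

test_that("2^-dCt relative quantification", {
  expect_equal(relativeQuantity(23.29, 9.26), 5.9779e-05,
               tolerance = 1e-4)
  expect_identical(relativeQuantity(20, 20), 1)
  expect_gt(relativeQuantity(8, 12), 1)
  q <- QPCRResult(23.29, 9.26)
  expect_equal(q@relativeQuantity, 2^-14.03)
  expect_error(relativeQuantity(Inf, 3), "finite")
})

test_that("strand pools enforce integer non-negative copy counts", {
  pool <- new("StrandPool",
              strands = list(Strand(DEMO_TEMPLATE, "template")),
              counts = 100, initialCopies = 100)
  expect_true(methods::validObject(pool))
  expect_error(new("StrandPool",
                   strands = list(Strand("ACGT", "s")),
                   counts = -1, initialCopies = 0), "non-negative")
  expect_error(new("StrandPool",
                   strands = list(Strand("ACGT", "s")),
                   counts = c(1, 2), initialCopies = 1), "equal length")
})

test_that("protocol validity is enforced", {
  expect_error(CycleProtocol(cycles = 0), "cycles")
  expect_error(CycleProtocol(annealCelsius = 100), "between")
  expect_error(runPCR(c(t = DEMO_TEMPLATE), DEMO_PRIMERS["PCR-1"],
                      efficiency = 0), "efficiency")
})
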