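test_that("Wallace Tm and the parallel-duplex penalty", {
  pd1 <- DEMO_PRIMERS[["PD-PCR-1"]]       # 8 A/T, 14 G/C
  expect_equal(meltingTemperature(pd1, "antiparallel"), 72)
  expect_equal(meltingTemperature(pd1, "parallel"), 57)
  expect_equal(meltingTemperature("AT", "antiparallel"), 4)
  # custom penalty and penalty invariance across arbitrary primers
  set.seed(11)
  model <- TmModel(psPenaltyCelsius = 10)
  for (i in 1:20) {
    p <- randSeq(sample(8:30, 1))
    expect_equal(meltingTemperature(p, "antiparallel", model) -
                   meltingTemperature(p, "parallel", model), 10)
    expect_equal(meltingTemperature(p, "antiparallel"),
                 2 * nchar(gsub("[GC]", "", p)) +
                   4 * nchar(gsub("[AT]", "", p)))
  }
  expect_error(TmModel(rule = "nearest-neighbor"), "rule")
  expect_error(TmModel(psPenaltyCelsius = -1), "non-negative")
})

test_that("the demonstration primers each find exactly their scheme site", {
  t <- Strand(DEMO_TEMPLATE, "template")
  s <- findBindingSites(DEMO_PRIMERS[["PD-PCR-1"]], t, mode = "parallel")
  expect_length(s, 1)
  expect_identical(c(s[[1]]@start, s[[1]]@end), c(0L, 22L))
  expect_equal(s[[1]]@tmCelsius, 57)
  expect_identical(s[[1]]@mismatches, 0L)

  s <- findBindingSites(DEMO_PRIMERS[["PCR-1"]], t, mode = "antiparallel")
  expect_length(s, 1)
  expect_identical(c(s[[1]]@start, s[[1]]@end), c(98L, 120L))

  # the second PD primer binds the newly synthesised parallel-complement
  # strand antiparallel at its 3' end
  newStrand <- Strand(parallelComplement(DEMO_TEMPLATE), "new")
  s <- findBindingSites(DEMO_PRIMERS[["PD-PCR-2"]], newStrand,
                        mode = "antiparallel")
  expect_length(s, 1)
  expect_identical(c(s[[1]]@start, s[[1]]@end), c(100L, 120L))

  # and no spurious sites in the orientations the schemes do not use
  expect_length(findBindingSites(DEMO_PRIMERS[["PD-PCR-1"]], t,
                                 mode = "antiparallel"), 0)
  expect_length(findBindingSites(DEMO_PRIMERS[["PCR-2"]], t,
                                 mode = "antiparallel"), 0)
  expect_length(findBindingSites(DEMO_PRIMERS[["PCR-1"]], t,
                                 mode = "parallel"), 0)
})

test_that("site search equals the brute-force window oracle on seeded random cases", {
  set.seed(2024)
  for (case in 1:200) {
    S <- sample(20:60, 1)
    strand <- randSeq(S)
    L <- sample(4:min(12, S), 1)
    mm <- sample(0:2, 1)
    anchor <- sample(c(L, L, sample(0:L, 1)), 1)
    mode <- sample(c("antiparallel", "parallel"), 1)
    # half the cases are guaranteed to contain a plantable site
    primer <- if (runif(1) < 0.5) {
      st <- sample(0:(S - L), 1)
      w <- substr(strand, st + 1, st + L)
      if (mode == "antiparallel") oracleRevComp(w) else oracleComplement(w)
    } else randSeq(L)
    got <- findBindingSites(primer, strand, mode = mode,
                            maxMismatches = mm, minAnchor = anchor)
    want <- oracleSites(primer, strand, mode, mm, anchor)
    expect_identical(sort(vapply(got, function(x) x@start, integer(1))),
                     sort(want$start))
    if (length(got)) {
      gotMm <- vapply(got, function(x) x@mismatches, integer(1))
      ord <- order(vapply(got, function(x) x@start, integer(1)))
      expect_identical(gotMm[ord], want$mismatches[order(want$start)])
    }
  }
})

test_that("sites are sorted by descending Tm then ascending start", {
  # a strand carrying the primer's parallel target left of its antiparallel
  # target: the antiparallel site scores a higher Tm and must sort first
  primer <- "GGCC"
  strand <- paste0("AT", parallelComplement(primer), "AT",
                   antiparallelComplement(primer), "AT")
  s <- findBindingSites(primer, strand, mode = "both")
  expect_length(s, 2)
  expect_identical(s[[1]]@mode, "antiparallel")
  expect_gt(s[[1]]@tmCelsius, s[[2]]@tmCelsius)
  expect_gt(s[[2]]@start, -1L)
})

test_that("a parallel-complement window only matches antiparallel when reversal-symmetric", {
  set.seed(5)
  for (i in 1:100) {
    w <- randSeq(sample(4:12, 1))
    primer <- parallelComplement(w)
    anti <- findBindingSites(primer, w, mode = "antiparallel")
    if (length(anti) > 0 && anti[[1]]@start == 0L &&
        anti[[1]]@end == nchar(w)) {
      expect_identical(w, reverseSequence(w))
    }
  }
})

test_that("degenerate inputs error cleanly", {
  expect_error(findBindingSites("ACGTACGT", "ACG"), "longer")
  expect_error(findBindingSites("ACGT", "ACGTACGT", minAnchor = 5),
               "minAnchor")
  expect_error(findBindingSites("ACGT", "ACGTACGT", maxMismatches = -1))
})

test_that("bindingSiteTable tabulates sites and handles the empty case", {
  t <- Strand(DEMO_TEMPLATE, "template")
  tab <- bindingSiteTable(findBindingSites(
    DEMO_PRIMERS[["PCR-1"]], t, mode = "both", primerLabel = "PCR-1"))
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$start, 98L)
  expect_identical(tab$mode, "antiparallel")
  empty <- bindingSiteTable(list())
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("start", "end", "mode", "tmCelsius") %in% names(empty)))
})
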