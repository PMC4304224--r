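# Independent oracles: deliberately naive character-by-character
# implementations, kept free of the package's own transform/search code so
# they can act as brute-force comparators.

.BASE_PAIR <- c(A = "T", C = "G", G = "C", T = "A")

oracleComplement <- function(s) {
  paste(.BASE_PAIR[strsplit(s, "")[[1]]], collapse = "")
}

oracleReverse <- function(s) {
  paste(rev(strsplit(s, "")[[1]]), collapse = "")
}

oracleRevComp <- function(s) {
  paste(rev(.BASE_PAIR[strsplit(s, "")[[1]]]), collapse = "")
}

# all windows where the primer can pair with the strand in the given mode:
# per-base pairing test against the window, never via string transforms
oracleSites <- function(primer, strand, mode, maxMismatches = 0L,
                        minAnchor = nchar(primer)) {
  pv <- strsplit(primer, "")[[1]]
  sv <- strsplit(strand, "")[[1]]
  L <- length(pv); S <- length(sv)
  hits <- data.frame(start = integer(0), mismatches = integer(0))
  if (L > S) return(hits)
  for (st in 0:(S - L)) {
    w <- sv[(st + 1):(st + L)]
    # pairs[i]: does primer base i pair with its partner in the window?
    if (mode == "antiparallel") {
      partner <- rev(w)            # primer pos i faces window pos L-1-i
    } else {
      partner <- w                 # primer pos i faces window pos i
    }
    pairs <- .BASE_PAIR[pv] == partner
    anchorOk <- minAnchor == 0L ||
      all(pairs[seq.int(L - minAnchor + 1L, L)])  # primer 3' terminal bases
    mm <- sum(!pairs)
    if (mm <= maxMismatches && anchorOk) {
      hits <- rbind(hits, data.frame(start = st, mismatches = mm))
    }
  }
  hits
}

randSeq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

allSeqsOfLength <- function(len) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), len),
                              stringsAsFactors = FALSE))
}

# the original demonstration reaction, inlined so fixture-file tests and
# algebra tests cannot mask each other
DEMO_TEMPLATE <- paste0(
  "GCGCGCATGCATGTGACTGACGATCGATCGATCAGTACTGACTGACAAATGACTGGATCC",
  "GGGAAGCTTGTGTTTAAAGTGTGAGGGTTGGCTGGGGTGTGGGGGTGGATGGGTAGCCGC")
DEMO_PRIMERS <- c(
  "PCR-1" = "GCGGCTACCCATCCACCCCCAC",
  "PCR-2" = "GCGCGCATGCATGTGACTGAC",
  "PD-PCR-1" = "CGCGCGTACGTACACTGACTGC",
  "PD-PCR-2" = "CGCCGATGGGTAGGTGGGGG")
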