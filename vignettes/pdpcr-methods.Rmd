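---
title: "Strand algebra and simulation model of parallel-DNA PCR"
author: "pdpcr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand algebra and simulation model of parallel-DNA PCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdpcr)
```

## The two pairing geometries

A Watson–Crick duplex is antiparallel: the strand pairing with a sequence
$s$ read 5'→3' is its **antiparallel complement** (the familiar reverse
complement). DNA can also form parallel-stranded (PS) duplexes in which
both strands run 5'→3' in the same direction and bases pair by reverse
Watson–Crick rules; the pairing partner of $s$ is then its **parallel
complement** — the base-wise complement with order preserved. Writing
$r$ for reversal and $c$ for base-wise complementation, the three
transforms obey

$$\mathrm{apc} = r \circ c = c \circ r, \qquad
  r^2 = c^2 = \mathrm{apc}^2 = \mathrm{id},$$

a commuting square of involutions that the test suite verifies
exhaustively for all sequences up to length 6 and on seeded random
100-mers. All sequences in this package are stored 5'→3'; polarity is
metadata of containers (duplexes, reports), never encoded by reversing a
stored string. The alphabet is strictly A/C/G/T — ambiguity codes are
rejected so that both pairing rules stay unambiguous.

## Why PD-PCR produces the opposite-polarity product

Conventional PCR on a single-stranded template $T$ uses a reverse primer
equal to $\mathrm{apc}$ of a 3' window of $T$ and a forward primer equal
to a 5' window of $T$; the amplified duplex is
$\{T', \mathrm{apc}(T')\}$ for the primer-bounded span $T'$ — the
template's polarity is conserved.

Parallel-DNA PCR (PD-PCR) starts with a first primer that is the
parallel complement of a 5' window of $T$. It anneals to the template in
parallel orientation and is extended toward the template's 3' end,
appending order-preserving complements, so the first product is
$c(T)$ — the template's parallel complement, a run-off strand. The
second primer, the reversal of a 3' window of $T$, anneals to $c(T)$
antiparallel (because $\mathrm{apc}(c(T)) = r(T)$), and from then on
both primers amplify conventionally. The final duplex is
$\{c(T),\, r(T)\}$: mutually antiparallel-complementary, but of polarity
opposite to the template. Algebraically the whole scheme is conventional
PCR on $r(T)$ with primer roles swapped, and the package tests that
identity directly, both on the primer designer
(`designPdpcrPair(t) == designConventionalPair(reverse(t))` with roles
swapped) and on the simulated amplicons.

## Binding-site search and the Tm model

`findBindingSites()` scans every window of a strand in one or both
orientations. In antiparallel mode primer position $i$ faces window
position $L-1-i$; in parallel mode position $i$ faces position $i$ (both
strands read 5'→3' left to right, the PS-duplex geometry). Coordinates
are 0-based half-open on the bound strand's own 5'→3' axis. Defaults are
maximally stringent — zero mismatches and a full-length exact 3' anchor —
because the demonstration system reports no mismatched priming; both are
configurable, and a mismatch-tolerant search still requires the primer's
3'-terminal `minAnchor` bases to pair exactly (a polymerase does not
extend a frayed 3' end). The search is checked against a brute-force
per-base window comparator on 200 seeded random cases.

Melting temperatures use the Wallace rule,
$T_m = 2(A{+}T) + 4(G{+}C)$ °C, appropriate for the short
oligonucleotides involved. Parallel duplexes melt lower than their
antiparallel counterparts; the model subtracts a constant
`psPenaltyCelsius` (default 15 °C, the reported PS/APS gap at matched
NaCl conditions) in parallel mode. A constant penalty is a deliberate
simplification: no PS nearest-neighbour parameter set is available, so a
sequence-context-dependent PS model would be invented numbers.
Salt/Mg²⁺ corrections, ΔG duplex models, hairpin and primer-dimer
screening are out of scope.

## The thermocycler model

`runPCR()` is deterministic and ideal by design:

* every cycle, all strands are fully denatured and available as
  single-stranded templates;
* each primer anneals to each strand at its best feasible site — predicted
  Tm ≥ the annealing temperature, ties broken by highest Tm then leftmost
  position; parallel-orientation sites are considered only when
  `allowParallel = TRUE`, and even then the 15 °C penalty makes
  antiparallel sites outcompete at stringent annealing temperatures
  rather than forbidding parallel chemistry by fiat;
* each feasible (primer, strand) pairing converts one extension product
  per template copy (ideal efficiency); extension always runs off the
  template end;
* strands are never destroyed, so copy counts are non-decreasing. Counts
  are exact integers kept in doubles (a 30-cycle run reaches ~10¹¹
  copies, past 32-bit integer range but far below 2⁵³).

An **amplicon** is defined structurally: a duplex whose two strands are
mutual antiparallel complements, each carrying primer-extension copies
and each beginning (5') with one of the supplied primers. Linear run-off
strands are reported separately and never as products — this is what
makes the single-primer and no-template controls come out empty.
Denaturation and extension temperatures are recorded in reports for
provenance only. A seeded Bernoulli efficiency (`efficiency < 1`) exists
for stochastic property tests; it is not the default model.

### Threshold cycles and the one-cycle lag

`thresholdCycle()` reports the first cycle at which the total copy count
of the amplicon strand *sequences* reaches `thresholdFold` × the initial
template copies (defaults: 100 input copies, fold 2¹⁰ — small integers
that keep the arithmetic exact). Counting by sequence matters: in the
conventional scheme the input template is itself one of the amplicon
strands, so the count starts at $N$ and doubles ($N\,2^c$), while in
PD-PCR both amplicon strands differ from the template and the count
follows $N(2^c - 1)$. At fold $2^{10}$ the conventional run crosses at
cycle 10 and the PD-PCR run at cycle 11 — the one-cycle lag that follows
from the PD scheme having to synthesise its template first. The
simulator reports this model lag only; the experimentally observed ΔCt
between the two schemes (≈14 cycles) reflects bench efficiencies the
ideal model deliberately does not fit, which is also why experimental Ct
magnitudes are outside what these simulations reproduce. The companion
`relativeQuantity()` helper implements the 2^−ΔCt comparison used for
such measurements.

The extension rule for a parallel-annealed primer (run-off toward the
template's 3' end appending order-preserving complements) is the
operational reading of the scheme; the enzymatic mechanism on a parallel
duplex is not modelled, and no claim is made about polymerase chemistry.

## Primer design and verification

Design is purely positional — primers are taken flush with the template
ends at caller-chosen lengths (interior placement via offsets), with no
Tm balancing or GC-clamp optimisation, mirroring how the demonstration
pairs were constructed (their 22/21/22/20-nt lengths are inherited as
defaults). `verifyPair()` re-simulates the pair under its scheme and
checks for exactly one amplicon of the predicted length. Its default
annealing temperature is the pair's limiting predicted Tm (minimum over
both primers, penalty applied when parallel annealing is in play): a
fixed default like 55 °C would make verification of arbitrary random
templates fail for reasons unrelated to the scheme, and with exact-match
site search a lower annealing temperature cannot create spurious sites.
The round-trip property — design then verify, one amplicon spanning the
template — is tested on 50 seeded random templates (lengths 40–200,
primer lengths 18–25).

## The synthetic template generator

`generateTemplates()` emulates the commercially synthesised
single-stranded template used in the demonstration: a given length
(≥ 40 nt, enough for two non-overlapping primers of practical length), a
GC target hit within ±5 percentage points, seeded and reproducible, with
the caller's RNG state restored. Literal-string palindromes
($s = r(s)$) are excluded because for them the conventional and PD-PCR
products coincide and scheme-contrast properties degenerate. Generated
templates are i.i.d. random sequences: they have no repeats, secondary
structure, or biased composition of real genomic DNA, so passing
property tests demonstrates the scheme algebra and the simulator's
bookkeeping — not primer specificity against real genomes, which the
designer does not screen for.

## Numerical and testing choices

All worked-example values are computed, never stored: the bundled FASTA
(`demoSequences()`) carries only the published 120-nt template and four
primers, and every derived quantity (site coordinates, Tm values,
amplicon strands, threshold cycles) is recomputed by the code under
test. Problem sizes in the property suites — exhaustive algebra to
length 6, 200 random site-search cases, 50 design round-trips, 50
scheme-relation templates — were chosen so the whole suite runs in well
under a minute while still exercising every branch; they are stated here
as the package's own test design. Determinism is itself a tested
property: identical inputs (including seeds in stochastic mode) produce
bit-identical reports, and CLI runs from the same config are
byte-identical.

## Known limitations

* No thermodynamic model beyond Wallace-plus-penalty; annealing is a
  sharp Tm threshold, not an equilibrium.
* Ideal efficiency by default; no polymerase errors, bias, or
  fluorescence chemistry, hence no attempt to reproduce experimental Ct
  magnitudes.
* Strict ACGT alphabet; no RNA, modified bases, or quality scores.
* Amplicon detection assumes complete denaturation every cycle; duplex
  reformation competing with primer annealing (the reason PD-PCR starts
  from a *single-stranded* template in the first place) is outside the
  simulated state.
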