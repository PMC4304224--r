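# pdpcr

In-silico sequence logic and thermocycling for **parallel-DNA PCR
(PD-PCR)** — an amplification scheme in which the first primer anneals to a
single-stranded template in *parallel* orientation (reverse Watson–Crick
pairing, both strands 5'→3' in the same direction), so that the amplified
duplex has polarity **opposite** to the template. The package is for
molecular biologists and tool builders who want to reason about, design,
or simulate reactions that mix antiparallel and parallel primer annealing.

## The core model

For a sequence $s$ written 5'→3', with $r$ = reversal and $c$ = base-wise
complement (A↔T, G↔C):

* **antiparallel complement** $\mathrm{apc}(s) = r(c(s))$ — the usual
  reverse complement, the partner strand in a Watson–Crick duplex;
* **parallel complement** $c(s)$ — order-preserving complement, the
  partner strand in a parallel-stranded duplex.

Conventional PCR on template $T$ amplifies $\{T, \mathrm{apc}(T)\}$.
PD-PCR's first primer is the parallel complement of a 5' window of $T$;
its extension synthesises $c(T)$, the second primer (the reversal of a 3'
window of $T$) anneals to that new strand antiparallel, and amplification
proceeds conventionally to the duplex $\{c(T), r(T)\}$ — the
opposite-polarity product. Melting temperatures use the Wallace rule
$T_m = 2(A{+}T) + 4(G{+}C)$ °C, with a 15 °C penalty for
parallel-stranded duplexes. The thermocycler is deterministic with exact
integer copy bookkeeping; an amplicon is a duplex whose strands are
primer-initiated mutual antiparallel complements (run-off strands are
reported separately, which is why single-primer and no-template controls
yield none).

## Worked example

The bundled FASTA carries the original demonstration reaction: a 120-nt
single-stranded template with a conventional pair (PCR-1/PCR-2) and a
PD-PCR pair (PD-PCR-1/PD-PCR-2).

```r
library(pdpcr)
seqs <- demoSequences()
t <- seqs[["template"]]

conv <- runPCR(c(template = t), seqs[c("PCR-1", "PCR-2")],
               CycleProtocol(cycles = 30, annealCelsius = 55))
pd   <- runPCR(c(template = t), seqs[c("PD-PCR-1", "PD-PCR-2")],
               CycleProtocol(cycles = 30, annealCelsius = 55),
               allowParallel = TRUE)

amplicons(conv)[, c("topLabel", "bottomLabel", "lengthNt")]
#>        topLabel bottomLabel lengthNt
#> 1 PCR-1.product    template      120

amplicons(pd)[, c("topLabel", "bottomLabel", "lengthNt")]
#>           topLabel      bottomLabel lengthNt
#> 1 PD-PCR-1.product PD-PCR-2.product      120

thresholdCycle(conv)   # 10
thresholdCycle(pd)     # 11  -- PD-PCR lags by exactly one cycle
meltingTemperature(seqs[["PD-PCR-1"]], "antiparallel")  # 72
meltingTemperature(seqs[["PD-PCR-1"]], "parallel")      # 57
relativeQuantity(23.29, 9.26)  # 5.977907e-05 (2^-dCt)
```

Both schemes produce a single 120-bp amplicon, but *different* ones: the
conventional product contains the template itself, the PD-PCR product
contains its parallel complement and its reversal. Under ideal doubling
the PD-PCR trajectory crosses any power-of-two threshold one cycle after
the conventional one, because its first cycle is spent synthesising the
new template.

Primer design is positional:

```r
pair <- designPdpcrPair(t, p1Len = 22, p2Len = 20)
primer1(pair)  # "CGCGCGTACGTACACTGACTGC" (= PD-PCR-1)
verifyPair(t, pair)
#> PairVerification: verified (1 amplicon(s), expected 120 nt, observed 120 nt)
```

A command-line interface mirrors the API
(`Rscript <pkg>/exec/pdpcr simulate|design|sites|complement|qpcr|fixtures ...`)
with FASTA in/out and JSON/TSV reports.

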