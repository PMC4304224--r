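#' Bundled demonstration reaction
#'
#' The packaged FASTA carries the 120-nt single-stranded template of the
#' original PD-PCR demonstration together with its two primer pairs:
#' PCR-1/PCR-2 (conventional scheme: PCR-1 is the antiparallel complement
#' of the template's 22-nt 3' suffix, PCR-2 its 21-nt 5' prefix) and
#' PD-PCR-1/PD-PCR-2 (parallel scheme: PD-PCR-1 is the parallel complement
#' of the 22-nt prefix, PD-PCR-2 the reversal of the 20-nt suffix).
#'
#' @return \code{demoFastaPath}: path to the FASTA file.
#'   \code{demoSequences}: named character vector with elements
#'   \code{template}, \code{PCR-1}, \code{PCR-2}, \code{PD-PCR-1},
#'   \code{PD-PCR-2}.
#' @examples
#' demoSequences()[["template"]]
#' @export
demoFastaPath <- function() {
  system.file("extdata", "pdpcr_demo.fasta", package = "pdpcr",
              mustWork = TRUE)
}

#' @rdname demoFastaPath
#' @export
demoSequences <- function() {
  readDNAFasta(demoFastaPath())
}
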