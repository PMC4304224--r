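#' Generate seeded synthetic single-stranded templates
#'
#' Deterministic random templates for property tests, standing in for a
#' commercially synthesised single-stranded oligonucleotide. Sequences are
#' drawn base-by-base with the requested GC probability and accepted only
#' if (i) the realised GC fraction is within 5 percentage points of the
#' target, (ii) the literal string is not its own reversal (for a
#' palindromic template the conventional and PD-PCR products coincide,
#' which would make scheme-contrast property tests degenerate), and (iii)
#' it has not been drawn before in this call. Templates shorter than 40 nt
#' are refused as too short to carry two non-overlapping primers of
#' practical length.
#'
#' The caller's RNG state is saved and restored, so the generator has no
#' side effects on global randomness.
#'
#' @param count number of templates.
#' @param length template length (nt, >= 40).
#' @param gcFraction target GC fraction in [0, 1].
#' @param seed integer seed; identical arguments always yield the same set.
#' @return character vector of \code{count} distinct sequences, named
#'   \code{fixture1..fixtureN}.
#' @examples
#' generateTemplates(2, length = 60, gcFraction = 0.5, seed = 7)
#' @export
generateTemplates <- function(count = 1L, length = 120L, gcFraction = 0.5,
                              seed = 1L) {
  count <- as.integer(count); length <- as.integer(length)
  if (count < 1L) stop("count must be >= 1")
  if (length < 40L)
    stop("template length must be >= 40 nt for PCR-compatible fixtures")
  if (gcFraction < 0 || gcFraction > 1)
    stop("gcFraction must lie in [0, 1]")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  probs <- c(A = (1 - gcFraction) / 2, C = gcFraction / 2,
             G = gcFraction / 2, T = (1 - gcFraction) / 2)
  out <- character(0)
  attempts <- 0L
  maxAttempts <- 1000L + 50L * count
  while (length(out) < count) {
    attempts <- attempts + 1L
    if (attempts > maxAttempts)
      stop("could not generate templates meeting the GC target of ",
           gcFraction, " within ", maxAttempts, " attempts")
    s <- paste(sample(names(probs), length, replace = TRUE, prob = probs),
               collapse = "")
    gc <- nchar(gsub("[AT]", "", s)) / length
    if (abs(gc - gcFraction) > 0.05 + 1e-12) next
    if (s == .rev1(s)) next
    if (s %in% out) next
    out <- c(out, s)
  }
  names(out) <- paste0("fixture", seq_len(count))
  out
}
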