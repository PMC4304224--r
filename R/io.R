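#' Read a FASTA file of strictly-validated DNA sequences
#'
#' Wraps \code{Biostrings::readDNAStringSet} and then applies the package's
#' strict A/C/G/T validation to every record (wrapped/multi-line records are
#' transparent; case and whitespace are normalised; ambiguity codes such as
#' N are rejected with the record name and offending position).
#'
#' @param path path to a FASTA file.
#' @return named character vector of validated sequences.
#' @export
readDNAFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e)
                    stop("malformed FASTA in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("no FASTA records in '", path, "'")
  seqs <- as.character(set)
  nm <- names(set)
  if (is.null(nm) || any(!nzchar(nm))) stop("malformed FASTA header")
  # header = first whitespace-delimited token, as most tools read it
  nm <- vapply(strsplit(nm, "[ \t]+"), `[`, character(1), 1)
  out <- vapply(seq_along(seqs), function(i) {
    tryCatch(validateSequence(seqs[i]), error = function(e)
      stop("record '", nm[i], "': ", conditionMessage(e), call. = FALSE))
  }, character(1))
  names(out) <- nm
  out
}

#' Write DNA sequences to FASTA
#'
#' @param x named character vector or \code{DNAStringSet}.
#' @param path output path.
#' @param width line-wrap width.
#' @return invisibly, \code{path}.
#' @importFrom Biostrings readDNAStringSet writeXStringSet
#' @export
writeDNAFasta <- function(x, path, width = 70L) {
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    x <- Biostrings::DNAStringSet(vapply(x, validateSequence, character(1)))
  }
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

.emptyAmpliconDf <- function() {
  data.frame(topLabel = character(0), topSeq = character(0),
             topPrimer = character(0), bottomLabel = character(0),
             bottomSeq = character(0), bottomPrimer = character(0),
             lengthNt = integer(0), selfComplementary = logical(0),
             stringsAsFactors = FALSE)
}

#' Serialise an amplification report
#'
#' JSON output is schema-versioned and round-trippable via
#' \code{\link{readReport}}; empty tables serialise as \code{[]}, never
#' null. TSV output is the long-format trajectory, one row per
#' (cycle, strand).
#'
#' @param report an \linkS4class{AmpliconReport}.
#' @param path output path.
#' @param format \code{"json"} or \code{"tsv"}.
#' @return invisibly, \code{path}.
#' @importFrom jsonlite write_json read_json
#' @importFrom utils write.table
#' @export
writeReport <- function(report, path, format = c("json", "tsv")) {
  stopifnot(is(report, "AmpliconReport"))
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(report@trajectory, path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  payload <- list(
    schema_version = report@schemaVersion,
    protocol = list(cycles = report@protocol@cycles,
                    anneal_celsius = report@protocol@annealCelsius,
                    denature_celsius = report@protocol@denatureCelsius,
                    extend_celsius = report@protocol@extendCelsius),
    allow_parallel = report@allowParallel,
    primers = as.list(report@primers),
    initial_copies = report@initialCopies,
    amplicons = report@amplicons,
    runoffs = report@runoffs,
    strands = report@strands,
    trajectory = report@trajectory)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

.dfFromJson <- function(rows, template) {
  if (length(rows) == 0L) return(template)
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  for (col in names(template)) {
    df[[col]] <- methods::as(df[[col]], class(template[[col]]))
  }
  df[, names(template), drop = FALSE]
}

#' Read back a JSON amplification report
#'
#' @param path a JSON file written by \code{\link{writeReport}}.
#' @return the reconstructed \linkS4class{AmpliconReport}.
#' @export
readReport <- function(path) {
  j <- jsonlite::read_json(path)
  if (is.null(j$schema_version))
    stop("not an amplification report (no schema_version)")
  proto <- CycleProtocol(cycles = j$protocol$cycles,
                         annealCelsius = j$protocol$anneal_celsius,
                         denatureCelsius = j$protocol$denature_celsius,
                         extendCelsius = j$protocol$extend_celsius)
  trajTemplate <- data.frame(cycle = integer(0), label = character(0),
                             count = numeric(0), stringsAsFactors = FALSE)
  strandsTemplate <- data.frame(label = character(0), sequence = character(0),
                                countInput = numeric(0),
                                countExtension = numeric(0),
                                stringsAsFactors = FALSE)
  runoffTemplate <- data.frame(label = character(0), sequence = character(0),
                               count = numeric(0), stringsAsFactors = FALSE)
  new("AmpliconReport",
      amplicons = .dfFromJson(j$amplicons, .emptyAmpliconDf()),
      runoffs = .dfFromJson(j$runoffs, runoffTemplate),
      strands = .dfFromJson(j$strands, strandsTemplate),
      trajectory = .dfFromJson(j$trajectory, trajTemplate),
      initialCopies = as.numeric(j$initial_copies),
      protocol = proto,
      allowParallel = isTRUE(j$allow_parallel),
      primers = unlist(j$primers),
      schemaVersion = j$schema_version)
}

#' Read/write a flat key-value run configuration
#'
#' A run configuration is a named list of scalar values stored as
#' \code{key = value} lines (\code{#} comments allowed). Values that parse
#' as numbers are returned numeric; \code{true}/\code{false} as logical.
#'
#' @param path config file path.
#' @return named list.
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line: '", ln, "'")
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    val <- gsub('^"|"$', "", val)
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
      else if (tolower(val) %in% c("true", "false")) tolower(val) == "true"
      else val
  }
  out
}

#' @rdname readRunConfig
#' @param config named list of scalar values.
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  fmt <- vapply(config, function(v) {
    if (is.logical(v)) tolower(as.character(v)) else as.character(v)
  }, character(1))
  writeLines(paste(names(config), "=", fmt), path)
  invisible(path)
}
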