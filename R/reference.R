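#' Read a reference genome from FASTA
#'
#' Reads a (possibly line-wrapped) FASTA file into a `reference_genome`
#' object. Sequences are uppercased, the part of each header after the first
#' whitespace is dropped, and the order of appearance is preserved as the
#' chromosome rank used for all downstream sorting.
#'
#' @param path Path to a FASTA file.
#' @return A `reference_genome` object: a named character vector of uppercase
#'   sequences with chromosome ranks `0..K-1` implied by order.
#' @export
read_reference <- function(path) {
  set <- withCallingHandlers(
    tryCatch(
      Biostrings::readDNAStringSet(path),
      error = function(e) .rescan_fasta_error(path, conditionMessage(e))
    ),
    # the parser drops invalid letters with a warning; refuse them instead
    warning = function(w) {
      if (grepl("invalid one-letter sequence code", conditionMessage(w)))
        .rescan_fasta_error(path, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  reference_genome(seqs)
}

# Locate the offending character/line for a friendlier error than the
# Biostrings parse failure.
.rescan_fasta_error <- function(path, original) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, ">")) next
    bad <- regmatches(ln, regexpr("[^ACGTRYSWKMBDHVNacgtryswkmbdhvn]", ln))
    if (length(bad) && nzchar(bad)) {
      stop(sprintf("non-IUPAC character '%s' on line %d of %s", bad, i, path),
           call. = FALSE)
    }
  }
  stop(sprintf("failed to parse FASTA %s: %s", path, original), call. = FALSE)
}

#' Construct a reference genome from named sequences
#'
#' @param seqs Named character vector of nucleotide sequences (one per
#'   chromosome, in rank order).
#' @return A `reference_genome` object.
#' @export
reference_genome <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("every sequence must be named", call. = FALSE)
  if (anyDuplicated(names(seqs)))
    stop(sprintf("duplicate sequence name: %s",
                 names(seqs)[duplicated(names(seqs))][1]), call. = FALSE)
  if (any(!nzchar(seqs)))
    stop(sprintf("empty sequence: %s", names(seqs)[!nzchar(seqs)][1]),
         call. = FALSE)
  structure(toupper(seqs), class = "reference_genome")
}

#' @export
print.reference_genome <- function(x, ...) {
  cat(sprintf("reference_genome: %d sequence(s), %s bases total\n",
              length(x), format(sum(nchar(x)), big.mark = ",")))
  for (i in seq_along(x))
    cat(sprintf("  [%d] %s (%d bp)\n", i - 1L, names(x)[i], nchar(x[[i]])))
  invisible(x)
}

#' Chromosome lengths of a reference
#' @param ref A `reference_genome`.
#' @return Named integer vector of lengths in bases.
#' @export
reference_lengths <- function(ref) {
  stats::setNames(nchar(ref), names(ref))
}

#' Write a reference (or any named sequence set) as wrapped FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width (default 60 columns).
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
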