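#' Read a SAM file
#'
#' Parses a SAM text file into header lines and a record data.frame. Only
#' the 11 mandatory columns are interpreted; optional tags are carried
#' through verbatim so partitioning never loses information. Positions are
#' converted to the package-wide 0-based half-open convention (`pos0`).
#'
#' @param path Path to a SAM file.
#' @param sample Sample name to attach to the records. Defaults to the `SM`
#'   field of the first `@RG` header line, else the file base name.
#' @return List with `header` (character vector of `@` lines) and `records`
#'   (data.frame: qname, flag, rname, pos0, mapq, cigar, rnext, pnext, tlen,
#'   seq, qual, opt, sample).
#' @export
read_sam <- function(path, sample = NULL) {
  lines <- readLines(path, warn = FALSE)
  is_hdr <- startsWith(lines, "@")
  header <- lines[is_hdr]
  body <- lines[!is_hdr]
  if (is.null(sample)) sample <- .sample_from_header(header, path)
  if (!length(body)) {
    return(list(header = header, records = .empty_sam_records(sample)))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L))
    stop(sprintf("malformed SAM record on line %d: fewer than 11 fields",
                 which(!is_hdr)[which(nf < 11L)[1]]), call. = FALSE)
  grab <- function(i) vapply(fields, `[[`, "", i)
  opt <- vapply(fields, function(f)
    if (length(f) > 11L) paste(f[-(1:11)], collapse = "\t") else "", "")
  records <- data.frame(
    qname = grab(1L),
    flag = as.integer(grab(2L)),
    rname = grab(3L),
    pos0 = as.integer(grab(4L)) - 1L,
    mapq = as.integer(grab(5L)),
    cigar = grab(6L),
    rnext = grab(7L),
    pnext = as.integer(grab(8L)),
    tlen = as.integer(grab(9L)),
    seq = grab(10L),
    qual = grab(11L),
    opt = opt,
    sample = sample,
    stringsAsFactors = FALSE)
  list(header = header, records = records)
}

.sample_from_header <- function(header, path) {
  rg <- header[startsWith(header, "@RG")]
  if (length(rg)) {
    sm <- regmatches(rg[1], regexpr("SM:[^\t]+", rg[1]))
    if (length(sm)) return(sub("^SM:", "", sm))
  }
  sub("\\.[sb]am$", "", basename(path))
}

.empty_sam_records <- function(sample = character(0)) {
  data.frame(qname = character(0), flag = integer(0), rname = character(0),
             pos0 = integer(0), mapq = integer(0), cigar = character(0),
             rnext = character(0), pnext = integer(0), tlen = integer(0),
             seq = character(0), qual = character(0), opt = character(0),
             sample = character(0), stringsAsFactors = FALSE)
}

#' Write records as a SAM file
#'
#' @param header Character vector of header (`@`) lines.
#' @param records Record data.frame as produced by [read_sam()].
#' @param path Output path.
#' @export
write_sam <- function(header, records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  if (nrow(records)) {
    body <- paste(records$qname, records$flag, records$rname,
                  records$pos0 + 1L, records$mapq, records$cigar,
                  records$rnext, records$pnext, records$tlen,
                  records$seq, records$qual, sep = "\t")
    has_opt <- nzchar(records$opt)
    body[has_opt] <- paste(body[has_opt], records$opt[has_opt], sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Parse a CIGAR string into operations
#' @param cigar CIGAR string (e.g. `"3S20M2D5M"`).
#' @return List with integer `len` and character `op` vectors.
#' @export
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || !nzchar(cigar))
    stop("cannot parse CIGAR '*' or empty", call. = FALSE)
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar))
    stop(sprintf("malformed CIGAR: %s", cigar), call. = FALSE)
  list(len = as.integer(sub(".$", "", toks)),
       op = substring(toks, nchar(toks), nchar(toks)))
}

.REF_OPS <- c("M", "D", "N", "=", "X")
.QUERY_OPS <- c("M", "I", "S", "=", "X")

#' Reference span of aligned records
#'
#' The half-open reference interval `[start0, end0)` each record covers:
#' `pos0` plus the total length of reference-consuming CIGAR operations
#' (M, D, N, =, X). Vectorized over records.
#'
#' @param records Record data.frame (needs `pos0` and `cigar`).
#' @return data.frame with `start0`, `end0`.
#' @export
reference_span <- function(records) {
  if (!nrow(records))
    return(data.frame(start0 = integer(0), end0 = integer(0)))
  width <- cigar_ref_width(records$cigar)
  data.frame(start0 = records$pos0, end0 = records$pos0 + width)
}

#' Reference-consumed width of CIGAR strings (vectorized)
#' @param cigars Character vector of CIGAR strings.
#' @return Integer vector of widths in bases.
#' @export
cigar_ref_width <- function(cigars) {
  u <- unique(cigars)
  w <- vapply(u, function(cg) {
    ops <- parse_cigar(cg)
    sum(ops$len[ops$op %in% .REF_OPS])
  }, integer(1))
  unname(w[match(cigars, u)])
}

#' Query-consumed width of CIGAR strings (vectorized)
#' @param cigars Character vector of CIGAR strings.
#' @return Integer vector of widths in bases.
#' @export
cigar_query_width <- function(cigars) {
  u <- unique(cigars)
  w <- vapply(u, function(cg) {
    ops <- parse_cigar(cg)
    sum(ops$len[ops$op %in% .QUERY_OPS])
  }, integer(1))
  unname(w[match(cigars, u)])
}

# TRUE for records with SAM flag bit 0x4 (unmapped)
is_unmapped <- function(flag) bitwAnd(flag, 4L) != 0L

# check coordinate sort: within each rname block, pos0 non-decreasing,
# and no rname appears in two separated blocks
.check_sorted <- function(records) {
  if (nrow(records) < 2L) return(invisible(TRUE))
  r <- rle(records$rname)
  if (anyDuplicated(r$values))
    stop("input not coordinate-sorted: interleaved reference blocks",
         call. = FALSE)
  grp <- rep(seq_along(r$lengths), r$lengths)
  d <- diff(records$pos0)
  if (any(d < 0 & diff(grp) == 0))
    stop("input not coordinate-sorted: positions decrease", call. = FALSE)
  invisible(TRUE)
}
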