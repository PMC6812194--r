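#' Segment one chromosome into overlap-padded pieces
#'
#' Cuts `[0, chrom_length)` into consecutive core intervals of at most
#' `core_size` bases and attaches a flanking pad of up to `pad` bases on each
#' side, clamped to the chromosome. Core intervals tile the chromosome
#' exactly (disjoint, gapless, in order); padded intervals overlap their
#' neighbours so that every read shorter than the pad has full alignment
#' context inside at least one piece. All coordinates are 0-based half-open.
#'
#' @param chrom_length Chromosome length in bases (>= 1).
#' @param core_size Maximum core length in bases (>= 1).
#' @param pad Flank length in bases (>= 0).
#' @param merge_short_final If `TRUE`, a final core shorter than `pad` is
#'   merged into the previous piece rather than kept as a degenerate piece.
#' @return A data.frame with columns `core_start`, `core_end`,
#'   `padded_start`, `padded_end`.
#' @export
segment_chromosome <- function(chrom_length, core_size, pad,
                               merge_short_final = FALSE) {
  stopifnot(chrom_length >= 1, core_size >= 1, pad >= 0)
  L <- as.integer(chrom_length)
  starts <- seq.int(0L, L - 1L, by = as.integer(core_size))
  ends <- pmin(starts + as.integer(core_size), L)
  if (merge_short_final && length(starts) > 1L &&
      (ends[length(ends)] - starts[length(starts)]) < pad) {
    n <- length(starts)
    ends[n - 1L] <- ends[n]
    starts <- starts[-n]; ends <- ends[-n]
  }
  data.frame(
    core_start = starts,
    core_end = ends,
    padded_start = pmax(0L, starts - as.integer(pad)),
    padded_end = pmin(L, ends + as.integer(pad))
  )
}

#' Build the piece table for a reference genome
#'
#' Splits every chromosome with [segment_chromosome()] and assembles the
#' genome-wide piece table: the source of truth mapping piece-relative to
#' absolute coordinates. Piece ids are `"<chrom>:<core_start>-<core_end>"`
#' in 0-based half-open convention. When `core_size` is at least the longest
#' chromosome, splitting degenerates to one piece per chromosome.
#'
#' @param ref A `reference_genome` (or named character vector of sequences).
#' @param core_size Core length in bases.
#' @param pad Flank length in bases.
#' @param max_read_span If supplied, `pad < max_read_span` draws a warning:
#'   a pad shorter than the longest read reference-span breaks the
#'   guarantee that split calling reproduces unsplit calling at core
#'   positions.
#' @param merge_short_final Passed to [segment_chromosome()].
#' @return A `piece_table` object.
#' @export
build_piece_table <- function(ref, core_size, pad, max_read_span = NULL,
                              merge_short_final = FALSE) {
  lens <- stats::setNames(nchar(ref), names(ref))
  if (!is.null(max_read_span) && pad < max_read_span)
    warning(sprintf(
      "pad (%d) is shorter than the maximum read reference-span (%d); boundary pileups will be incomplete",
      as.integer(pad), as.integer(max_read_span)), call. = FALSE)
  per_chrom <- lapply(names(lens), function(cn) {
    seg <- segment_chromosome(lens[[cn]], core_size, pad, merge_short_final)
    seg$chrom <- cn
    seg
  })
  pieces <- do.call(rbind, per_chrom)
  pieces$piece_id <- sprintf("%s:%d-%d", pieces$chrom,
                             pieces$core_start, pieces$core_end)
  pieces <- pieces[, c("piece_id", "chrom", "core_start", "core_end",
                       "padded_start", "padded_end")]
  rownames(pieces) <- NULL
  structure(
    list(pieces = pieces,
         chrom_lengths = lens,
         chrom_rank = stats::setNames(seq_along(lens) - 1L, names(lens)),
         core_size = as.integer(core_size),
         pad = as.integer(pad)),
    class = "piece_table")
}

#' @export
print.piece_table <- function(x, ...) {
  cat(sprintf("piece_table: %d piece(s) over %d chromosome(s) (core_size=%d, pad=%d)\n",
              nrow(x$pieces), length(x$chrom_lengths), x$core_size, x$pad))
  print(utils::head(x$pieces, 10L))
  if (nrow(x$pieces) > 10L) cat(sprintf("  ... %d more\n", nrow(x$pieces) - 10L))
  invisible(x)
}

#' Look up one piece by id
#' @param table A `piece_table`.
#' @param piece_id Piece identifier string.
#' @return One-row data.frame (the piece).
#' @export
get_piece <- function(table, piece_id) {
  i <- match(piece_id, table$pieces$piece_id)
  if (is.na(i)) stop(sprintf("unknown piece_id: %s", piece_id), call. = FALSE)
  table$pieces[i, ]
}

#' Piece owning an absolute position
#'
#' Returns the unique piece whose core interval contains the 0-based
#' position: the piece authoritative for variants at that position during
#' merge deduplication.
#'
#' @param table A `piece_table`.
#' @param chrom Chromosome name.
#' @param abs_pos0 0-based position on the chromosome.
#' @return One-row data.frame (the owning piece).
#' @export
owner_piece <- function(table, chrom, abs_pos0) {
  if (!chrom %in% names(table$chrom_lengths))
    stop(sprintf("unknown chromosome: %s", chrom), call. = FALSE)
  if (abs_pos0 < 0 || abs_pos0 >= table$chrom_lengths[[chrom]])
    stop(sprintf("position %d out of range for %s", abs_pos0, chrom),
         call. = FALSE)
  p <- table$pieces[table$pieces$chrom == chrom, ]
  p[p$core_start <= abs_pos0 & abs_pos0 < p$core_end, ]
}

#' Piece-relative to absolute coordinates
#'
#' @param piece One-row piece data.frame (from [get_piece()] etc.).
#' @param rel_pos1 1-based position within the piece's padded sequence.
#' @return List with `chrom` and `abs_pos1` (1-based absolute position).
#' @export
rel_to_abs <- function(piece, rel_pos1) {
  plen <- piece$padded_end - piece$padded_start
  if (any(rel_pos1 < 1L | rel_pos1 > plen))
    stop(sprintf("relative position out of range 1..%d for piece %s",
                 plen, piece$piece_id), call. = FALSE)
  list(chrom = piece$chrom, abs_pos1 = as.integer(rel_pos1 + piece$padded_start))
}

#' Absolute to piece-relative coordinates
#'
#' Inverse of [rel_to_abs()] for positions inside the piece's padded
#' interval.
#'
#' @param piece One-row piece data.frame.
#' @param abs_pos1 1-based absolute position on the parent chromosome.
#' @return 1-based position within the piece.
#' @export
abs_to_rel <- function(piece, abs_pos1) {
  rel <- as.integer(abs_pos1 - piece$padded_start)
  plen <- piece$padded_end - piece$padded_start
  if (any(rel < 1L | rel > plen))
    stop(sprintf("absolute position outside padded interval of piece %s",
                 piece$piece_id), call. = FALSE)
  rel
}

#' Padded-interval sequence of a piece
#' @param ref A `reference_genome`.
#' @param piece One-row piece data.frame.
#' @return Nucleotide string over the padded interval.
#' @export
piece_sequence <- function(ref, piece) {
  substring(ref[[piece$chrom]], piece$padded_start + 1L, piece$padded_end)
}

#' Write per-piece FASTA files
#'
#' One 60-column wrapped FASTA per piece, header carrying the piece id.
#' Offsets live in the piece-map TSV, not in the header.
#'
#' @param ref A `reference_genome`.
#' @param table A `piece_table`.
#' @param dir Output directory (created if absent).
#' @param skip_existing If `TRUE`, piece files already on disk are left
#'   untouched (resume support).
#' @return Named character vector of file paths, one per piece id.
#' @export
write_piece_fastas <- function(ref, table, dir, skip_existing = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(table$pieces))
  for (i in seq_len(nrow(table$pieces))) {
    piece <- table$pieces[i, ]
    path <- file.path(dir, paste0(.safe_name(piece$piece_id), ".fa"))
    if (!(skip_existing && file.exists(path)))
      write_fasta(stats::setNames(piece_sequence(ref, piece), piece$piece_id),
                  path)
    paths[i] <- path
  }
  stats::setNames(paths, table$pieces$piece_id)
}

# piece ids contain ':', safe on POSIX but normalized for portability
.safe_name <- function(x) gsub("[:]", "_", x)

#' Serialize a piece table to TSV
#'
#' Header line plus one row per piece: `piece_id`, `chrom`, `core_start`,
#' `core_end`, `padded_start`, `padded_end` (0-based half-open). Chromosome
#' lengths and the (core_size, pad) configuration ride along as `#` comment
#' lines so the file round-trips losslessly.
#'
#' @param table A `piece_table`.
#' @param path Output path.
#' @export
write_piece_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#core_size=%d\tpad=%d", table$core_size, table$pad), con)
  writeLines(sprintf("#chrom\t%s\t%d", names(table$chrom_lengths),
                     unname(table$chrom_lengths)), con)
  utils::write.table(table$pieces, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Parse a piece table from TSV
#' @param path Path written by [write_piece_table()].
#' @return A `piece_table`.
#' @export
read_piece_table <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  cfg <- meta[grepl("^#core_size=", meta)]
  kv <- strsplit(sub("^#core_size=", "", cfg), "\t")[[1]]
  core_size <- as.integer(kv[1])
  pad <- as.integer(sub("^pad=", "", kv[2]))
  chrom_lines <- strsplit(sub("^#chrom\t", "", meta[startsWith(meta, "#chrom\t")]), "\t")
  chrom_lengths <- stats::setNames(
    as.integer(vapply(chrom_lines, `[`, "", 2L)),
    vapply(chrom_lines, `[`, "", 1L))
  body <- lines[!startsWith(lines, "#")]
  pieces <- utils::read.table(text = body, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  int_cols <- c("core_start", "core_end", "padded_start", "padded_end")
  pieces[int_cols] <- lapply(pieces[int_cols], as.integer)
  structure(
    list(pieces = pieces,
         chrom_lengths = chrom_lengths,
         chrom_rank = stats::setNames(seq_along(chrom_lengths) - 1L,
                                      names(chrom_lengths)),
         core_size = core_size,
         pad = pad),
    class = "piece_table")
}
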