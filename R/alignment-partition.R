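#' Assign records to genome pieces
#'
#' A record belongs to every piece whose padded interval fully contains the
#' record's reference span. Full containment (rather than mere overlap)
#' guarantees each emitted record is a legal alignment to the piece
#' sequence and is what makes per-piece pileups at core positions identical
#' to the unsplit pileup whenever the pad is at least the maximum read
#' reference-span. Records inside an overlap zone are assigned to both
#' neighbouring pieces; records spanning wider than every padded window are
#' assigned to none.
#'
#' @param records Mapped record data.frame (see [read_sam()]).
#' @param table A `piece_table`.
#' @return List of integer vectors, one per piece (same order as
#'   `table$pieces`), each holding the row indices of `records` assigned to
#'   that piece.
#' @export
assign_records <- function(records, table) {
  pieces <- table$pieces
  out <- vector("list", nrow(pieces))
  if (!nrow(records)) {
    out[] <- list(integer(0))
    return(stats::setNames(out, pieces$piece_id))
  }
  span <- reference_span(records)
  for (i in seq_len(nrow(pieces))) {
    hit <- records$rname == pieces$chrom[i] &
      span$start0 >= pieces$padded_start[i] &
      span$end0 <= pieces$padded_end[i]
    out[[i]] <- which(hit)
  }
  stats::setNames(out, pieces$piece_id)
}

#' Remap records into piece-relative coordinates
#'
#' Rewrites `rname` to the piece id and shifts `pos0` by the piece's padded
#' start. Mate fields (`rnext`/`pnext`/`tlen`) are reset to unset values
#' because mates may land in different pieces; pairing flags are left
#' intact. The original absolute coordinate is recoverable through the
#' piece table ([rel_to_abs()]).
#'
#' @param records Record data.frame whose spans lie inside the piece's
#'   padded interval.
#' @param piece One-row piece data.frame.
#' @return The remapped record data.frame.
#' @export
remap_records <- function(records, piece) {
  if (nrow(records)) {
    span <- reference_span(records)
    if (any(records$rname != piece$chrom |
            span$start0 < piece$padded_start |
            span$end0 > piece$padded_end))
      stop(sprintf("record span not contained in padded interval of %s",
                   piece$piece_id), call. = FALSE)
  }
  records$rname <- rep(piece$piece_id, nrow(records))
  records$pos0 <- records$pos0 - piece$padded_start
  records$rnext <- rep("*", nrow(records))
  records$pnext <- rep(0L, nrow(records))
  records$tlen <- rep(0L, nrow(records))
  records
}

# SAM header for one piece: single reference sequence named by piece id
.piece_sam_header <- function(piece, sample) {
  c("@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", piece$piece_id,
            piece$padded_end - piece$padded_start),
    sprintf("@RG\tID:%s\tSM:%s", sample, sample))
}

#' Partition a sorted alignment file into per-piece SAM files
#'
#' Splits one coordinate-sorted, single-sample SAM file into one SAM file
#' per genome piece, with positions remapped to piece-relative coordinates.
#' Each output carries a single-contig header (the piece) and stays
#' coordinate-sorted because remapping within a piece is a constant shift.
#'
#' @param sam_path Path to a coordinate-sorted SAM file.
#' @param table A `piece_table`.
#' @param dir Output directory.
#' @param sample Sample name; default derived from the `@RG` header or file
#'   name.
#' @param skip_existing If `TRUE` and every expected output file already
#'   exists, return immediately without re-reading the input (resume
#'   support); counts are `NA` in that case.
#' @return A `partition_report` list: `sample`, `paths` (named by piece id),
#'   `total`, `assigned`, `unmapped`, `unassignable`, `per_piece` counts.
#'   Overlap-zone records appear in up to two outputs, so per-piece counts
#'   may sum to more than `assigned`.
#' @export
partition_alignments <- function(sam_path, table, dir, sample = NULL,
                                 skip_existing = FALSE) {
  if (skip_existing && !is.null(sample)) {
    expected <- file.path(dir, sprintf("%s.%s.sam", sample,
                                       .safe_name(table$pieces$piece_id)))
    if (length(expected) && all(file.exists(expected))) {
      report <- list(
        sample = sample,
        paths = stats::setNames(expected, table$pieces$piece_id),
        total = NA_integer_, assigned = NA_integer_,
        unmapped = NA_integer_, unassignable = NA_integer_,
        per_piece = stats::setNames(rep(NA_integer_, nrow(table$pieces)),
                                    table$pieces$piece_id))
      class(report) <- "partition_report"
      return(report)
    }
  }
  aln <- read_sam(sam_path, sample = sample)
  sample <- if (nrow(aln$records)) aln$records$sample[1] else
    .sample_from_header(aln$header, sam_path)
  records <- aln$records
  unmapped <- is_unmapped(records$flag)
  mapped <- records[!unmapped, , drop = FALSE]
  if (nrow(mapped)) {
    unknown <- setdiff(unique(mapped$rname), names(table$chrom_lengths))
    if (length(unknown))
      stop(sprintf("chromosome absent from piece table: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    .check_sorted(mapped)
  }
  assign <- assign_records(mapped, table)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(table$pieces))
  for (i in seq_len(nrow(table$pieces))) {
    piece <- table$pieces[i, ]
    out <- remap_records(mapped[assign[[i]], , drop = FALSE], piece)
    path <- file.path(dir, sprintf("%s.%s.sam", sample,
                                   .safe_name(piece$piece_id)))
    write_sam(.piece_sam_header(piece, sample), out, path)
    paths[i] <- path
  }
  n_hits <- lengths(assign)
  hit_any <- logical(nrow(mapped))
  for (idx in assign) hit_any[idx] <- TRUE
  report <- list(
    sample = sample,
    paths = stats::setNames(paths, table$pieces$piece_id),
    total = nrow(records),
    assigned = sum(hit_any),
    unmapped = sum(unmapped),
    unassignable = sum(!hit_any),
    per_piece = stats::setNames(as.integer(n_hits), table$pieces$piece_id))
  class(report) <- "partition_report"
  report
}

#' @export
print.partition_report <- function(x, ...) {
  cat(sprintf(
    "partition_report [%s]: %d records; %d assigned, %d unmapped, %d unassignable; %d piece file(s)\n",
    x$sample, x$total, x$assigned, x$unmapped, x$unassignable,
    length(x$paths)))
  invisible(x)
}
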