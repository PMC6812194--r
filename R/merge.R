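#' Lift a per-piece variant set to absolute coordinates
#'
#' Rewrites the contig to the parent chromosome and shifts positions by the
#' piece's padded start. Everything else (alleles, QUAL, genotypes) passes
#' through untouched — qualities are never recomputed or averaged at merge
#' time.
#'
#' @param vs A `variant_set` whose contig is the piece id.
#' @param piece One-row piece data.frame.
#' @return The lifted `variant_set`.
#' @export
lift_piece_vcf <- function(vs, piece) {
  if (n_variants(vs)) {
    if (any(vs$chrom != piece$piece_id))
      stop(sprintf("contig mismatch: expected %s, found %s",
                   piece$piece_id,
                   paste(setdiff(unique(vs$chrom), piece$piece_id),
                         collapse = ", ")), call. = FALSE)
    plen <- piece$padded_end - piece$padded_start
    if (any(vs$pos1 < 1L | vs$pos1 > plen))
      stop(sprintf("position outside padded interval of piece %s",
                   piece$piece_id), call. = FALSE)
  }
  vs$chrom <- rep(piece$chrom, n_variants(vs))
  vs$pos1 <- vs$pos1 + piece$padded_start
  vs
}

#' Keep only variants owned by the piece's core
#'
#' After lifting, a piece may report variants in its overlap pad that a
#' neighbouring piece also reports. Each variant is kept only by the piece
#' whose core interval contains its (0-based) start position, so every
#' boundary duplicate survives exactly once pipeline-wide. Multi-base
#' records (e.g. deletions from an external caller) are owned by the piece
#' containing their start.
#'
#' @param vs A lifted `variant_set`.
#' @param piece One-row piece data.frame (the source piece).
#' @return The core-owned subset.
#' @export
filter_to_core <- function(vs, piece) {
  pos0 <- vs$pos1 - 1L
  subset_variants(vs, pos0 >= piece$core_start & pos0 < piece$core_end)
}

#' Merge per-piece VCFs into the final callset
#'
#' Reads every per-piece VCF, lifts it to absolute coordinates, drops
#' non-core (duplicate) records, concatenates, and sorts by (chromosome
#' rank in the original reference, position). A post-filter duplicate
#' (chrom, pos, ref, alt) key indicates an ownership bug and raises an
#' error, as does any sample-column mismatch between pieces.
#'
#' @param piece_vcfs Named character vector: piece id -> VCF path.
#' @param table A `piece_table`.
#' @param out_vcf Optional path; when given the merged VCF is written with
#'   one `##contig` line per original chromosome.
#' @return The merged `variant_set` (invisibly when `out_vcf` is given).
#' @export
merge_piece_vcfs <- function(piece_vcfs, table, out_vcf = NULL) {
  if (is.null(names(piece_vcfs)) && length(piece_vcfs))
    stop("piece_vcfs must be named by piece id", call. = FALSE)
  sets <- vector("list", length(piece_vcfs))
  samples <- NULL
  for (i in seq_along(piece_vcfs)) {
    pid <- names(piece_vcfs)[i]
    piece <- get_piece(table, pid)
    vs <- read_vcf(piece_vcfs[[i]])
    if (is.null(samples)) samples <- vs$samples
    else if (!identical(vs$samples, samples))
      stop(sprintf("sample columns differ between pieces (%s)", pid),
           call. = FALSE)
    sets[[i]] <- filter_to_core(lift_piece_vcf(vs, piece), piece)
  }
  merged <- do.call(rbind_variant_sets, sets)
  if (n_variants(merged)) {
    ord <- order(table$chrom_rank[merged$chrom], merged$pos1)
    merged <- subset_variants(merged, ord)
    key <- paste(merged$chrom, merged$pos1, merged$ref, merged$alt,
                 sep = "\r")
    if (anyDuplicated(key))
      stop(sprintf(
        "duplicate variant after core filtering (ownership bug): %s",
        gsub("\r", ":", key[duplicated(key)][1])), call. = FALSE)
  }
  if (!is.null(out_vcf)) {
    write_vcf(merged, out_vcf, contigs = table$chrom_lengths)
    return(invisible(merged))
  }
  merged
}
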