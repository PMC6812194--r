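#' Variant set container
#'
#' In-memory representation of VCF data lines: site columns plus per-sample
#' genotype (`GT`) and counted depth (`DP`) matrices with one row per
#' variant and one column per sample.
#'
#' @param chrom,pos1,ref,alt,qual Site columns; `pos1` is 1-based.
#' @param gt Character matrix of genotypes (`0/0`, `0/1`, `1/1`, `./.`).
#' @param dp Integer matrix of counted depths.
#' @param samples Sample names (column order of `gt`/`dp`).
#' @return A `variant_set` object.
#' @export
variant_set <- function(chrom = character(0), pos1 = integer(0),
                        ref = character(0), alt = character(0),
                        qual = numeric(0), gt = NULL, dp = NULL,
                        samples = character(0)) {
  n <- length(chrom)
  if (is.null(gt)) gt <- matrix(character(0), nrow = n, ncol = length(samples))
  if (is.null(dp)) dp <- matrix(integer(0), nrow = n, ncol = length(samples))
  gt <- matrix(as.character(gt), nrow = n, ncol = length(samples))
  dp <- matrix(as.integer(dp), nrow = n, ncol = length(samples))
  colnames(gt) <- samples
  colnames(dp) <- samples
  structure(list(chrom = as.character(chrom), pos1 = as.integer(pos1),
                 ref = as.character(ref), alt = as.character(alt),
                 qual = as.numeric(qual), gt = gt, dp = dp,
                 samples = as.character(samples)),
            class = "variant_set")
}

#' Number of variants in a set
#' @param vs A `variant_set`.
#' @return Integer count.
#' @export
n_variants <- function(vs) length(vs$pos1)

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d variant(s), %d sample(s) [%s]\n",
              n_variants(x), length(x$samples),
              paste(x$samples, collapse = ", ")))
  if (n_variants(x)) {
    df <- as.data.frame.variant_set(x)
    print(utils::head(df, 8L))
    if (nrow(df) > 8L) cat(sprintf("  ... %d more\n", nrow(df) - 8L))
  }
  invisible(x)
}

#' @export
as.data.frame.variant_set <- function(x, ...) {
  df <- data.frame(chrom = x$chrom, pos1 = x$pos1, ref = x$ref,
                   alt = x$alt, qual = x$qual, stringsAsFactors = FALSE)
  for (s in x$samples) {
    df[[paste0("gt_", s)]] <- x$gt[, s]
    df[[paste0("dp_", s)]] <- x$dp[, s]
  }
  df
}

#' Concatenate variant sets
#' @param ... `variant_set` objects with identical sample columns.
#' @return A single `variant_set`.
#' @export
rbind_variant_sets <- function(...) {
  sets <- list(...)
  sets <- sets[vapply(sets, Negate(is.null), TRUE)]
  if (!length(sets)) return(variant_set())
  samples <- sets[[1]]$samples
  for (s in sets)
    if (!identical(s$samples, samples))
      stop("sample columns differ between variant sets", call. = FALSE)
  variant_set(
    chrom = unlist(lapply(sets, `[[`, "chrom")),
    pos1 = unlist(lapply(sets, `[[`, "pos1")),
    ref = unlist(lapply(sets, `[[`, "ref")),
    alt = unlist(lapply(sets, `[[`, "alt")),
    qual = unlist(lapply(sets, `[[`, "qual")),
    gt = do.call(rbind, lapply(sets, `[[`, "gt")),
    dp = do.call(rbind, lapply(sets, `[[`, "dp")),
    samples = samples)
}

#' Subset a variant set by row
#' @param vs A `variant_set`.
#' @param i Integer or logical index.
#' @return The subset `variant_set`.
#' @export
subset_variants <- function(vs, i) {
  variant_set(chrom = vs$chrom[i], pos1 = vs$pos1[i], ref = vs$ref[i],
              alt = vs$alt[i], qual = vs$qual[i],
              gt = vs$gt[i, , drop = FALSE], dp = vs$dp[i, , drop = FALSE],
              samples = vs$samples)
}

# QUAL column formatting: integers print without decimals
.fmt_qual <- function(q) {
  out <- ifelse(is.na(q), ".",
                ifelse(q == round(q), sprintf("%d", as.integer(round(q))),
                       sprintf("%g", q)))
  out
}

#' Write a variant set as VCF 4.2
#'
#' Emits a fixed, timestamp-free header (deterministic output is part of
#' the pipeline contract), `##contig` lines in the given order, and
#' `GT:DP`-formatted sample columns. `INFO/DP` is the summed counted depth
#' across samples.
#'
#' @param vs A `variant_set`.
#' @param path Output path.
#' @param contigs Named integer vector: contig name -> length, in header
#'   order.
#' @return The path, invisibly.
#' @export
write_vcf <- function(vs, path, contigs) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=scattervc",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs),
            as.integer(contigs)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total counted depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Counted depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(vs$samples)) c("FORMAT", vs$samples)),
          collapse = "\t")), con)
  if (n_variants(vs)) {
    info <- sprintf("DP=%d", as.integer(rowSums(vs$dp)))
    sample_cols <- vapply(seq_len(n_variants(vs)), function(i)
      paste(sprintf("%s:%d", vs$gt[i, ], vs$dp[i, ]), collapse = "\t"), "")
    writeLines(paste(vs$chrom, vs$pos1, ".", vs$ref, vs$alt,
                     .fmt_qual(vs$qual), "PASS", info, "GT:DP",
                     sample_cols, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF file into a variant set
#'
#' Parses through `vcfR`. `GT` and `DP` are taken from the FORMAT fields
#' when present; files without sample columns yield empty matrices.
#'
#' @param path Path to an uncompressed or bgzipped VCF.
#' @return A `variant_set`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt_raw <- v@gt
  samples <- if (!is.null(gt_raw) && ncol(gt_raw) > 1L)
    colnames(gt_raw)[-1L] else character(0)
  n <- nrow(fix)
  if (is.null(n) || n == 0L) return(variant_set(samples = samples))
  gt <- matrix("./.", nrow = n, ncol = length(samples))
  dp <- matrix(0L, nrow = n, ncol = length(samples))
  if (length(samples)) {
    fmt <- strsplit(gt_raw[, 1L], ":", fixed = TRUE)
    for (j in seq_along(samples)) {
      vals <- strsplit(gt_raw[, j + 1L], ":", fixed = TRUE)
      for (i in seq_len(n)) {
        gi <- match("GT", fmt[[i]])
        di <- match("DP", fmt[[i]])
        if (!is.na(gi) && gi <= length(vals[[i]])) gt[i, j] <- vals[[i]][gi]
        if (!is.na(di) && di <= length(vals[[i]]))
          dp[i, j] <- suppressWarnings(as.integer(vals[[i]][di]))
      }
    }
    dp[is.na(dp)] <- 0L
  }
  variant_set(chrom = fix[, "CHROM"], pos1 = as.integer(fix[, "POS"]),
              ref = fix[, "REF"], alt = fix[, "ALT"],
              qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
              gt = gt, dp = dp, samples = samples)
}
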