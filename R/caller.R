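.BASES <- c("A", "C", "G", "T")

#' Built-in caller configuration
#'
#' Thresholds for the deterministic pileup SNV caller. `het_min` and
#' `hom_min` are allele-fraction cut-offs for heterozygous and homozygous
#' alternate genotypes; `err` is the per-base sequencing error probability
#' under the error-only null used for the Phred site quality.
#'
#' @param min_depth Minimum counted depth for a genotype call (reads).
#' @param het_min Minimum alternate-allele fraction for `0/1`.
#' @param hom_min Minimum alternate-allele fraction for `1/1`.
#' @param err Per-base error probability.
#' @param qual_cap Maximum emitted QUAL.
#' @return A `caller_config` list.
#' @export
caller_config <- function(min_depth = 4L, het_min = 0.2, hom_min = 0.8,
                          err = 0.01, qual_cap = 255L) {
  stopifnot(het_min > 0, het_min < hom_min, hom_min <= 1,
            err > 0, err < 1, min_depth >= 1, qual_cap >= 1)
  structure(list(min_depth = as.integer(min_depth), het_min = het_min,
                 hom_min = hom_min, err = err,
                 qual_cap = as.integer(qual_cap)),
            class = "caller_config")
}

#' Phred-scaled binomial tail quality
#'
#' Quality of observing at least `k` alternate bases among `d` under the
#' error-only null: `-10 log10 P(X >= k)` with `X ~ Binomial(d, err)`,
#' rounded and capped. Computed on the log scale so deep pileups do not
#' underflow. Vectorized over `k` and `d`.
#'
#' @param k Alternate-base count (0 <= k <= d).
#' @param d Counted depth (>= 1).
#' @param err Per-base error probability.
#' @param qual_cap Maximum returned value.
#' @return Integer vector of Phred qualities.
#' @export
phred_binomial_qual <- function(k, d, err, qual_cap = 255L) {
  stopifnot(all(k >= 0), all(k <= d), all(d >= 1))
  logp <- stats::pbinom(k - 1, d, err, lower.tail = FALSE, log.p = TRUE)
  as.integer(pmin(as.numeric(qual_cap), round(-10 * logp / log(10))))
}

# CIGAR walk for one record: reference positions (0-based) and the query
# indices aligned to them (M/=/X only)
.aligned_pairs <- function(pos0, cigar) {
  ops <- parse_cigar(cigar)
  rpos <- pos0
  qpos <- 1L
  ref_out <- integer(0)
  qry_out <- integer(0)
  for (j in seq_along(ops$op)) {
    len <- ops$len[j]
    op <- ops$op[j]
    if (op %in% c("M", "=", "X")) {
      ref_out <- c(ref_out, rpos + seq_len(len) - 1L)
      qry_out <- c(qry_out, qpos + seq_len(len) - 1L)
      rpos <- rpos + len
      qpos <- qpos + len
    } else if (op %in% c("D", "N")) {
      rpos <- rpos + len
    } else if (op %in% c("I", "S")) {
      qpos <- qpos + len
    }
    # H and P consume neither
  }
  list(ref = ref_out, qry = qry_out)
}

#' Build a per-sample pileup over one contig
#'
#' Stacks aligned read bases (CIGAR M/=/X only) per reference position and
#' sample. Insertions and deleted/skipped reference positions contribute
#' nothing; soft/hard clips are skipped; read `N` bases are not counted.
#' Base qualities are deliberately not used: calling works on the raw
#' multiset of aligned bases, which is what makes split and unsplit pileups
#' exactly comparable.
#'
#' @param records Record data.frame mapped to this contig (piece-relative
#'   or absolute, as long as `pos0` matches `contig_seq`).
#' @param contig_seq Nucleotide string of the contig the records map to.
#' @param samples Optional character vector fixing the sample order;
#'   defaults to sorted unique sample names in `records`.
#' @return A `pileup` object: per-sample 4 x L count matrices (rows A,C,G,T)
#'   plus the reference base index per position.
#' @export
build_pileup <- function(records, contig_seq, samples = NULL) {
  L <- nchar(contig_seq)
  if (is.null(samples))
    samples <- sort(unique(records$sample))
  counts <- lapply(samples, function(s) {
    rec <- records[records$sample == s, , drop = FALSE]
    .count_bases(rec, L)
  })
  names(counts) <- samples
  ref_idx <- match(strsplit(contig_seq, "", fixed = TRUE)[[1]], .BASES)
  structure(list(counts = counts, ref_idx = ref_idx,
                 ref_seq = contig_seq, L = L, samples = samples),
            class = "pileup")
}

.count_bases <- function(records, L) {
  if (!nrow(records)) return(matrix(0L, nrow = 4L, ncol = L))
  simple <- grepl("^\\d+M$", records$cigar)
  pos_all <- integer(0)
  base_all <- character(0)
  if (any(simple)) {
    rec <- records[simple, , drop = FALSE]
    qlen <- nchar(rec$seq)
    pos_all <- rep(rec$pos0, qlen) + sequence(qlen) - 1L
    base_all <- unlist(strsplit(rec$seq, "", fixed = TRUE), use.names = FALSE)
  }
  if (any(!simple)) {
    rec <- records[!simple, , drop = FALSE]
    for (i in seq_len(nrow(rec))) {
      ap <- .aligned_pairs(rec$pos0[i], rec$cigar[i])
      pos_all <- c(pos_all, ap$ref)
      base_all <- c(base_all,
                    substring(rec$seq[i], ap$qry, ap$qry))
    }
  }
  if (any(pos_all < 0L | pos_all >= L))
    stop("aligned base beyond contig end: upstream containment contract violated",
         call. = FALSE)
  idx <- match(base_all, .BASES)          # N and ambiguity codes drop out
  keep <- !is.na(idx)
  tab <- tabulate(pos_all[keep] * 4L + idx[keep], nbins = 4L * L)
  matrix(as.integer(tab), nrow = 4L, ncol = L)
}

#' @export
print.pileup <- function(x, ...) {
  covered <- sum(Reduce(`+`, lapply(x$counts, colSums)) > 0)
  cat(sprintf("pileup: %d bp contig, %d sample(s), %d covered position(s)\n",
              x$L, length(x$samples), covered))
  invisible(x)
}

#' Pileup columns as a data.frame
#'
#' Tidy view of a [build_pileup()] result: one row per (covered position,
#' sample) with base counts and depth. Intended for inspection and testing.
#'
#' @param pileup A `pileup` object.
#' @param contig Contig name to report in the `chrom` column.
#' @return data.frame with chrom, pos0, ref_base, sample, A, C, G, T, depth.
#' @export
pileup_columns <- function(pileup, contig = "contig") {
  depth_any <- Reduce(`+`, lapply(pileup$counts, colSums))
  pos <- which(depth_any > 0) - 1L
  out <- lapply(pileup$samples, function(s) {
    m <- pileup$counts[[s]][, pos + 1L, drop = FALSE]
    data.frame(chrom = contig, pos0 = pos,
               ref_base = .BASES[pileup$ref_idx[pos + 1L]],
               sample = s,
               A = m[1L, ], C = m[2L, ], G = m[3L, ], T = m[4L, ],
               depth = colSums(m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$pos0, out$sample), , drop = FALSE]
}

#' Call SNVs from a pileup
#'
#' Deterministic allele-fraction genotyper. Per sample, the candidate
#' allele is the non-reference base with the highest count (ties broken to
#' the lexicographically smallest base) and `f` its fraction of the counted
#' depth: genotype `1/1` when `f >= hom_min`, `0/1` when
#' `het_min <= f < hom_min`, else `0/0`; samples below `min_depth` get
#' `./.`. A site is emitted when at least one sample is `0/1` or `1/1`. The
#' site ALT is the candidate allele of the highest-quality variant sample
#' and QUAL the maximum [phred_binomial_qual()] over variant samples, so
#' output is identical under any execution order or piece layout.
#'
#' @param pileup A `pileup` object.
#' @param config A [caller_config()].
#' @param contig Contig name for emitted records.
#' @return A `variant_set` (see [variant_set()]).
#' @export
call_snvs <- function(pileup, config = caller_config(), contig = "contig") {
  L <- pileup$L
  S <- length(pileup$samples)
  if (S == 0L || L == 0L)
    return(variant_set(samples = pileup$samples))
  alt_idx <- matrix(0L, nrow = S, ncol = L)
  alt_cnt <- matrix(0L, nrow = S, ncol = L)
  depth <- matrix(0L, nrow = S, ncol = L)
  for (si in seq_len(S)) {
    m <- pileup$counts[[si]]
    depth[si, ] <- as.integer(colSums(m))
    m2 <- m
    m2[cbind(pileup$ref_idx, seq_len(L))] <- -1L   # mask the ref base
    b <- max.col(t(m2), ties.method = "first")     # lexicographic tie-break
    alt_idx[si, ] <- b
    alt_cnt[si, ] <- m[cbind(b, seq_len(L))]
  }
  f <- ifelse(depth > 0, alt_cnt / depth, 0)
  gt <- matrix("0/0", nrow = S, ncol = L)
  gt[f >= config$het_min] <- "0/1"
  gt[f >= config$hom_min] <- "1/1"
  gt[depth < config$min_depth] <- "./."
  is_var <- gt == "0/1" | gt == "1/1"
  emit <- which(colSums(is_var) > 0L)
  if (!length(emit))
    return(variant_set(samples = pileup$samples))
  qual <- matrix(-1L, nrow = S, ncol = L)
  iv <- which(is_var, arr.ind = TRUE)
  qual[iv] <- phred_binomial_qual(alt_cnt[iv], depth[iv], config$err,
                                  config$qual_cap)
  site_qual <- integer(length(emit))
  site_alt <- integer(length(emit))
  for (j in seq_along(emit)) {
    p <- emit[j]
    q <- max(qual[, p])
    site_qual[j] <- q
    best <- which(qual[, p] == q & is_var[, p])
    site_alt[j] <- min(alt_idx[best, p])           # smallest allele on ties
  }
  variant_set(
    chrom = rep(contig, length(emit)),
    pos1 = emit,
    ref = .BASES[pileup$ref_idx[emit]],
    alt = .BASES[site_alt],
    qual = site_qual,
    gt = t(gt[, emit, drop = FALSE]),
    dp = t(depth[, emit, drop = FALSE]),
    samples = pileup$samples)
}

#' Run the built-in caller over a set of contigs
#'
#' Convenience wrapper: builds a pileup and calls SNVs per contig, in the
#' given contig order, concatenating the results. Used both for whole
#' (unsplit) references and for single-piece sequences.
#'
#' @param seqs Named character vector of contig sequences.
#' @param records Record data.frame (may hold several samples).
#' @param config A [caller_config()].
#' @param samples Optional fixed sample order.
#' @return A `variant_set`.
#' @export
call_builtin <- function(seqs, records, config = caller_config(),
                         samples = NULL) {
  if (is.null(samples))
    samples <- sort(unique(records$sample))
  sets <- lapply(names(seqs), function(cn) {
    rec <- records[records$rname == cn & !is_unmapped(records$flag), ,
                   drop = FALSE]
    pu <- build_pileup(rec, seqs[[cn]], samples = samples)
    call_snvs(pu, config, contig = cn)
  })
  do.call(rbind_variant_sets, sets)
}

#' Expand and run an external caller command template
#'
#' Substitutes `{ref}`, `{bams}` (space-joined) and `{out}` into the
#' template and executes it through the shell. The first token must resolve
#' to an executable before anything runs. A non-zero exit is reported with
#' the tail of captured stderr; the produced VCF must reference only the
#' piece contig (validated at lift time).
#'
#' @param template Command template containing `{ref}`, `{bams}`, `{out}`.
#' @param piece_fasta Path to the piece FASTA.
#' @param piece_bams Character vector of per-sample piece alignment files.
#' @param out_vcf Output VCF path.
#' @return List with `status` (exit code), `out_vcf`, `stderr_tail`.
#' @export
run_external_caller <- function(template, piece_fasta, piece_bams, out_vcf) {
  for (ph in c("{ref}", "{bams}", "{out}"))
    if (!grepl(ph, template, fixed = TRUE))
      stop(sprintf("caller template lacks placeholder %s", ph), call. = FALSE)
  cmd <- template
  cmd <- gsub("{ref}", piece_fasta, cmd, fixed = TRUE)
  cmd <- gsub("{bams}", paste(piece_bams, collapse = " "), cmd, fixed = TRUE)
  cmd <- gsub("{out}", out_vcf, cmd, fixed = TRUE)
  exe <- strsplit(trimws(cmd), "\\s+")[[1]][1]
  if (!nzchar(Sys.which(exe)) && !file.exists(exe))
    stop(sprintf("external caller executable not found: %s", exe),
         call. = FALSE)
  err_file <- tempfile("caller-stderr-")
  status <- system(paste(cmd, "2>", shQuote(err_file)))
  stderr_tail <- if (file.exists(err_file))
    utils::tail(readLines(err_file, warn = FALSE), 20L) else character(0)
  unlink(err_file)
  list(status = status, out_vcf = out_vcf, stderr_tail = stderr_tail)
}
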