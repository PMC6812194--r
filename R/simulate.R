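# run code under a fixed seed without clobbering the caller's RNG stream
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a random reference genome
#'
#' Chromosomes of i.i.d. uniform A/C/G/T bases. Fully deterministic for a
#' given `(lengths, seed)` pair.
#'
#' @param lengths Integer vector of chromosome lengths (>= 1); names are
#'   used as chromosome names, default `chr1..chrK`.
#' @param seed RNG seed.
#' @return A `reference_genome`.
#' @export
simulate_reference <- function(lengths, seed) {
  stopifnot(all(lengths >= 1))
  if (is.null(names(lengths)))
    names(lengths) <- paste0("chr", seq_along(lengths))
  .with_seed(seed, {
    seqs <- vapply(lengths, function(L)
      paste(sample(.BASES, L, replace = TRUE), collapse = ""), "")
    reference_genome(seqs)
  })
}

#' Plant diploid SNVs into a reference
#'
#' Draws variant positions without replacement, at least `min_spacing`
#' bases apart (positions are spread over chromosomes proportionally to
#' length). The alternate allele is uniform over the three non-reference
#' bases. Per sample, each site is heterozygous with probability
#' `het_fraction` (the alternate allele lands on one random haplotype),
#' otherwise homozygous alternate.
#'
#' @param ref A `reference_genome`.
#' @param n_snvs Number of SNVs to plant.
#' @param het_fraction Probability a site is heterozygous in a sample.
#' @param min_spacing Minimum distance between planted sites (bases).
#' @param samples Character vector of sample names.
#' @param seed RNG seed.
#' @return List with `truth` (data.frame: chrom, pos1, ref, alt, one
#'   genotype column per sample) and `haplotypes` (per sample, per
#'   chromosome, a character vector of the two haplotype sequences).
#' @export
plant_variants <- function(ref, n_snvs, het_fraction, min_spacing,
                           samples, seed) {
  lens <- stats::setNames(nchar(ref), names(ref))
  .with_seed(seed, {
    quota <- stats::setNames(
      if (n_snvs == 0) integer(length(lens))
      else round(n_snvs * lens / sum(lens)),
      names(lens))
    # rounding drift goes to the largest chromosome
    quota[which.max(lens)] <- quota[which.max(lens)] + n_snvs - sum(quota)
    if (any(quota * min_spacing >= lens))
      stop("cannot satisfy min_spacing: too many variants for chromosome length",
           call. = FALSE)
    rows <- list()
    for (cn in names(lens)) {
      pos <- integer(0)
      tries <- 0L
      while (length(pos) < quota[[cn]]) {
        cand <- sample.int(lens[[cn]], 1L)
        if (!length(pos) || min(abs(pos - cand)) >= min_spacing)
          pos <- c(pos, cand)
        tries <- tries + 1L
        if (tries > 1000L * max(1L, quota[[cn]]))
          stop("cannot satisfy min_spacing after repeated sampling",
               call. = FALSE)
      }
      pos <- sort(pos)
      if (length(pos)) {
        refb <- substring(ref[[cn]], pos, pos)
        altb <- vapply(refb, function(b)
          sample(setdiff(.BASES, b), 1L), "", USE.NAMES = FALSE)
        rows[[cn]] <- data.frame(chrom = cn, pos1 = pos, ref = refb,
                                 alt = altb, stringsAsFactors = FALSE)
      }
    }
    truth <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(0), pos1 = integer(0),
                 ref = character(0), alt = character(0))
    rownames(truth) <- NULL
    haplotypes <- list()
    for (s in samples) {
      is_het <- stats::runif(nrow(truth)) < het_fraction
      alt_on_first <- stats::runif(nrow(truth)) < 0.5
      truth[[paste0("gt_", s)]] <- ifelse(is_het, "0/1", "1/1")
      haps <- list()
      for (cn in names(lens)) {
        h1 <- h2 <- ref[[cn]]
        sel <- which(truth$chrom == cn)
        for (i in sel) {
          p <- truth$pos1[i]
          a <- truth$alt[i]
          if (!is_het[i]) {
            substring(h1, p, p) <- a
            substring(h2, p, p) <- a
          } else if (alt_on_first[i]) {
            substring(h1, p, p) <- a
          } else {
            substring(h2, p, p) <- a
          }
        }
        haps[[cn]] <- c(h1, h2)
      }
      haplotypes[[s]] <- haps
    }
    list(truth = truth, haplotypes = haplotypes)
  })
}

#' Write a truth table as VCF
#'
#' @param truth Truth data.frame from [plant_variants()].
#' @param path Output path.
#' @param contigs Named vector of chromosome lengths.
#' @return The path, invisibly.
#' @export
write_truth_vcf <- function(truth, path, contigs) {
  samples <- sub("^gt_", "", grep("^gt_", names(truth), value = TRUE))
  vs <- variant_set(
    chrom = truth$chrom, pos1 = truth$pos1, ref = truth$ref,
    alt = truth$alt, qual = rep(100, nrow(truth)),
    gt = as.matrix(truth[, paste0("gt_", samples), drop = FALSE]),
    dp = matrix(0L, nrow(truth), length(samples)),
    samples = samples)
  write_vcf(vs, path, contigs)
}

#' Simulate uniform-coverage error-bearing reads for one sample
#'
#' Draws read start positions uniformly until the requested mean coverage
#' is reached, copies each read from one of the two haplotypes (fair
#' coin), then flips every base independently to a uniformly chosen
#' different base with probability `err_rate`. Reads are emitted as
#' already-aligned SAM records (position known by construction, all-M
#' CIGAR, fixed base quality), coordinate-sorted.
#'
#' @param haplotypes Per-chromosome list of two haplotype strings (one
#'   sample's entry from [plant_variants()]).
#' @param coverage Target mean coverage.
#' @param read_len Read length in bases.
#' @param err_rate Per-base error probability.
#' @param sample Sample name (goes into the `@RG` header and records).
#' @param seed RNG seed.
#' @return List with `header` and `records`, as from [read_sam()].
#' @export
simulate_reads <- function(haplotypes, coverage, read_len, err_rate,
                           sample, seed) {
  stopifnot(coverage > 0, read_len >= 1)
  lens <- vapply(haplotypes, function(h) nchar(h[1]), 0L)
  stopifnot(all(read_len <= lens))
  .with_seed(seed, {
    recs <- list()
    for (cn in names(haplotypes)) {
      L <- lens[[cn]]
      n <- ceiling(coverage * L / read_len)
      starts0 <- sort(sample.int(L - read_len + 1L, n, replace = TRUE)) - 1L
      coin <- sample.int(2L, n, replace = TRUE)
      idx <- outer(seq_len(read_len) - 1L, starts0, `+`) + 1L
      h1 <- strsplit(haplotypes[[cn]][1], "", fixed = TRUE)[[1]]
      h2 <- strsplit(haplotypes[[cn]][2], "", fixed = TRUE)[[1]]
      m <- h1[idx]
      dim(m) <- dim(idx)
      if (any(coin == 2L)) {
        m2 <- h2[idx]
        dim(m2) <- dim(idx)
        sel <- rep(coin == 2L, each = read_len)
        m[sel] <- m2[sel]
      }
      if (err_rate > 0) {
        mask <- stats::runif(length(m)) < err_rate
        if (any(mask)) {
          cur <- match(m[mask], .BASES)
          shift <- sample.int(3L, sum(mask), replace = TRUE)
          m[mask] <- .BASES[(cur - 1L + shift) %% 4L + 1L]
        }
      }
      reads <- do.call(paste0, asplit(m, 1L))
      recs[[cn]] <- data.frame(
        qname = sprintf("%s_%s_%06d", sample, cn, seq_len(n)),
        flag = 0L, rname = cn, pos0 = starts0, mapq = 60L,
        cigar = paste0(read_len, "M"), rnext = "*", pnext = 0L,
        tlen = 0L, seq = reads,
        qual = strrep("I", read_len), opt = "", sample = sample,
        stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, recs)
    rownames(records) <- NULL
    header <- c("@HD\tVN:1.6\tSO:coordinate",
                sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens),
                sprintf("@RG\tID:%s\tSM:%s", sample, sample))
    list(header = header, records = records)
  })
}

#' Generate a complete synthetic dataset on disk
#'
#' Reference FASTA, truth VCF, one sorted SAM per sample, and a JSON
#' manifest of every parameter and seed — everything the pipeline needs,
#' with no external downloads.
#'
#' @param dir Output directory.
#' @param lengths Chromosome lengths (named or unnamed).
#' @param n_snvs Number of planted SNVs.
#' @param het_fraction Probability a planted site is heterozygous.
#' @param coverage Mean read coverage.
#' @param read_len Read length.
#' @param err_rate Per-base error probability.
#' @param samples Sample names.
#' @param min_spacing Minimum spacing between planted sites.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return List of paths (`reference`, `truth_vcf`, `sams`, `manifest`)
#'   plus the in-memory `ref` and `truth`.
#' @export
simulate_dataset <- function(dir, lengths = c(chr1 = 100000L),
                             n_snvs = 100L, het_fraction = 0.5,
                             coverage = 30, read_len = 100L,
                             err_rate = 0.01, samples = "s1",
                             min_spacing = 2L, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  ref <- simulate_reference(lengths, seed = seed)
  planted <- plant_variants(ref, n_snvs, het_fraction, min_spacing,
                            samples, seed = (seed + 1001L) %% .Machine$integer.max)
  ref_path <- file.path(dir, "reference.fa")
  write_fasta(stats::setNames(as.character(ref), names(ref)), ref_path)
  truth_path <- file.path(dir, "truth.vcf")
  write_truth_vcf(planted$truth, truth_path, reference_lengths(ref))
  sam_paths <- character(0)
  for (i in seq_along(samples)) {
    s <- samples[i]
    aln <- simulate_reads(planted$haplotypes[[s]], coverage, read_len,
                          err_rate, sample = s,
                          seed = (seed + 2001L + i) %% .Machine$integer.max)
    p <- file.path(dir, paste0(s, ".sam"))
    write_sam(aln$header, aln$records, p)
    sam_paths[s] <- p
  }
  manifest_path <- file.path(dir, "simulation.json")
  jsonlite::write_json(
    list(lengths = as.list(stats::setNames(as.integer(lengths),
                                           names(reference_lengths(ref)))),
         n_snvs = n_snvs, het_fraction = het_fraction, coverage = coverage,
         read_len = read_len, err_rate = err_rate, samples = samples,
         min_spacing = min_spacing, seed = seed),
    manifest_path, auto_unbox = TRUE, pretty = TRUE)
  list(reference = ref_path, truth_vcf = truth_path, sams = sam_paths,
       manifest = manifest_path, ref = ref, truth = planted$truth)
}
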