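# shared fixture builders and independent oracles

# minimal mapped-record data.frame with sensible defaults
make_records <- function(pos0, cigar, seq, rname = "chr1", sample = "s1",
                         flag = 0L, qname = NULL) {
  n <- max(length(pos0), length(cigar), length(seq))
  data.frame(
    qname = if (is.null(qname)) sprintf("r%03d", seq_len(n)) else qname,
    flag = rep_len(flag, n), rname = rep_len(rname, n),
    pos0 = rep_len(as.integer(pos0), n), mapq = rep_len(60L, n),
    cigar = rep_len(cigar, n), rnext = rep_len("*", n),
    pnext = rep_len(0L, n), tlen = rep_len(0L, n),
    seq = rep_len(seq, n),
    qual = strrep("I", nchar(rep_len(seq, n))),
    opt = rep_len("", n), sample = rep_len(sample, n),
    stringsAsFactors = FALSE)
}

write_test_sam <- function(records, path, contigs) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contigs),
                      as.integer(contigs)))
  write_sam(header, records, path)
}

# variant fields with rownames stripped, for record-identity comparisons
vs_records <- function(vs) {
  df <- as.data.frame(vs)
  rownames(df) <- NULL
  df[order(df$chrom, df$pos1), , drop = FALSE]
}

# independent brute-force oracle: binomial upper tail by direct summation
qual_oracle <- function(k, d, err, cap = 255L) {
  if (k == 0) return(0L)
  p <- sum(choose(d, k:d) * err^(k:d) * (1 - err)^(d - (k:d)))
  as.integer(min(cap, round(-10 * log10(p))))
}

# independent brute-force oracle for the concordance metrics: enumerates
# all key pairs with explicit loops
metrics_oracle <- function(m, n, diff_threshold = 0.05) {
  l_keys <- character(0); s_a <- numeric(0); s_b <- numeric(0)
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(nrow(n))) {
      if (m$key[i] == n$key[j]) {
        l_keys <- c(l_keys, m$key[i])
        s_a <- c(s_a, m$score[i]); s_b <- c(s_b, n$score[j])
      }
    }
  }
  only_m <- sum(!(m$key %in% n$key))
  only_n <- sum(!(n$key %in% m$key))
  rd <- mapply(function(a, b) {
    mx <- max(a, b); if (mx == 0) 0 else abs(a - b) / mx
  }, s_a, s_b)
  rd <- as.numeric(rd)
  conc <- rd <= diff_threshold
  list(l = length(l_keys), p = only_m + only_n,
       missing = (only_m + only_n) / nrow(m),
       diff = if (length(l_keys)) mean(rd >= diff_threshold) else NA,
       corr = if (sum(conc) >= 2 && var(s_a[conc]) > 0 &&
                  var(s_b[conc]) > 0) cor(s_a[conc], s_b[conc]) else NA)
}

# random callset pair over a shared key universe, as variant_sets
random_callsets <- function(seed, max_records = 50L) {
  set.seed(seed)
  universe <- sprintf("chr%d:%d", sample(1:2, 60, TRUE),
                      sample(1:5000, 60))
  universe <- unique(universe)
  mk <- function() {
    keys <- sample(universe, sample(3:min(max_records, length(universe)), 1))
    parts <- strsplit(keys, ":", fixed = TRUE)
    variant_set(
      chrom = vapply(parts, `[[`, "", 1L),
      pos1 = as.integer(vapply(parts, `[[`, "", 2L)),
      ref = sample(c("A", "C", "G", "T"), length(keys), TRUE),
      alt = "N",  # ref/alt constant per key via chrom:pos uniqueness
      qual = round(runif(length(keys), 1, 200)),
      gt = matrix("0/1", length(keys), 1), dp = matrix(10L, length(keys), 1),
      samples = "s1")
  }
  a <- mk(); b <- mk()
  # make ref/alt deterministic per key so shared keys actually intersect
  fix_alleles <- function(v) {
    v$ref <- rep("A", n_variants(v))
    v$alt <- rep("G", n_variants(v))
    v
  }
  list(a = fix_alleles(a), b = fix_alleles(b))
}

# cached pipeline fixtures shared across test files
.fixture_cache <- new.env(parent = emptyenv())

cached_dataset <- function(key, ...) {
  if (is.null(.fixture_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("svc-fix-", key))
    .fixture_cache[[key]] <- simulate_dataset(dir, ...)
  }
  .fixture_cache[[key]]
}
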