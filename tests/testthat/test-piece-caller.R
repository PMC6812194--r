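test_that("pileup stacks aligned bases and honours CIGAR geometry", {
  rec <- make_records(pos0 = 0L, cigar = "4M", seq = "ACGT")
  pu <- build_pileup(rec, "ACGTT", samples = "s1")
  expect_equal(colSums(pu$counts$s1), c(1L, 1L, 1L, 1L, 0L))
  expect_equal(pu$counts$s1[, 1], c(A = 1L, C = 0L, G = 0L, T = 0L),
               ignore_attr = TRUE)

  # two reads disagreeing at one site
  rec2 <- make_records(pos0 = c(0L, 0L), cigar = "4M",
                       seq = c("ACGT", "AGGT"))
  pu2 <- build_pileup(rec2, "ACGTT", samples = "s1")
  expect_equal(pu2$counts$s1[c(2, 3), 2], c(1L, 1L), ignore_attr = TRUE)

  # 2M1D2M on a 5-base contig: deleted position 2 (0-based) gets nothing
  rec3 <- make_records(pos0 = 0L, cigar = "2M1D2M", seq = "ACTT")
  pu3 <- build_pileup(rec3, "ACGTT", samples = "s1")
  expect_equal(colSums(pu3$counts$s1), c(1L, 1L, 0L, 1L, 1L))

  # soft clips skipped, N bases not counted, insertions contribute nothing
  rec4 <- make_records(pos0 = 1L, cigar = "2S2M1I2M", seq = "GGACTGT")
  pu4 <- build_pileup(rec4, "AACTGTA", samples = "s1")
  expect_equal(colSums(pu4$counts$s1), c(0L, 1L, 1L, 1L, 1L, 0L, 0L))
  rec5 <- make_records(pos0 = 0L, cigar = "3M", seq = "ANT")
  pu5 <- build_pileup(rec5, "ACT", samples = "s1")
  expect_equal(colSums(pu5$counts$s1), c(1L, 0L, 1L))

  # a base beyond the contig end is an upstream contract violation
  rec6 <- make_records(pos0 = 3L, cigar = "4M", seq = "ACGT")
  expect_error(build_pileup(rec6, "ACGTT", samples = "s1"),
               "beyond contig end")
})

test_that("pileup columns report per-sample counts at covered positions", {
  rec <- rbind(make_records(pos0 = 0L, cigar = "3M", seq = "ACG",
                            sample = "s1"),
               make_records(pos0 = 1L, cigar = "3M", seq = "CGA",
                            sample = "s2"))
  pu <- build_pileup(rec, "ACGA", samples = c("s1", "s2"))
  cols <- pileup_columns(pu, contig = "c1")
  expect_equal(nrow(cols), 8L)  # 4 covered positions x 2 samples
  expect_equal(cols$depth[cols$sample == "s1"], c(1L, 1L, 1L, 0L))
  expect_equal(cols$depth[cols$sample == "s2"], c(0L, 1L, 1L, 1L))
  expect_true(all(cols$depth == cols$A + cols$C + cols$G + cols$T))
})

test_that("Phred binomial tail quality matches hand-checked values", {
  expect_equal(phred_binomial_qual(1, 1, 0.01), 20L)
  expect_equal(phred_binomial_qual(10, 10, 0.01), 200L)
  # tail sum for k=3, d=10: P ~ 1.14e-4 (verified by direct summation)
  expect_equal(qual_oracle(3, 10, 0.01), 39L)
  expect_equal(phred_binomial_qual(3, 10, 0.01), 39L)
  expect_equal(phred_binomial_qual(0, 10, 0.01), 0L)
  expect_equal(phred_binomial_qual(30, 30, 0.01, qual_cap = 255L), 255L)
})

test_that("genotype thresholds, depth gate and tie-breaks behave as specified", {
  mk_pu <- function(counts_by_sample, ref = "A") {
    # single position; counts named A/C/G/T per sample
    structure(list(
      counts = lapply(counts_by_sample, function(x)
        matrix(as.integer(x), nrow = 4)),
      ref_idx = match(ref, c("A", "C", "G", "T")),
      ref_seq = ref, L = 1L, samples = names(counts_by_sample)),
      class = "pileup")
  }
  cfg <- caller_config()

  hom <- call_snvs(mk_pu(list(s1 = c(1, 0, 9, 0))), cfg, "c1")
  expect_equal(unname(hom$gt[1, "s1"]), "1/1")
  het <- call_snvs(mk_pu(list(s1 = c(5, 0, 5, 0))), cfg, "c1")
  expect_equal(unname(het$gt[1, "s1"]), "0/1")
  low <- call_snvs(mk_pu(list(s1 = c(0, 0, 3, 0))), cfg, "c1")
  expect_equal(n_variants(low), 0L)  # ./. only, site not emitted
  refonly <- call_snvs(mk_pu(list(s1 = c(10, 0, 1, 0))), cfg, "c1")
  expect_equal(n_variants(refonly), 0L)

  # allele tie at equal counts goes to the lexicographically smallest base
  tie <- call_snvs(mk_pu(list(s1 = c(0, 5, 5, 0))), cfg, "c1")
  expect_equal(tie$alt, "C")

  # site QUAL is the max over variant samples; ./. sample keeps its depth
  multi <- call_snvs(mk_pu(list(s1 = c(0, 10, 0, 0), s2 = c(5, 5, 0, 0),
                                s3 = c(1, 1, 0, 0))), cfg, "c1")
  expect_equal(multi$gt[1, ], c(s1 = "1/1", s2 = "0/1", s3 = "./."))
  expect_equal(multi$qual,
               as.numeric(phred_binomial_qual(10, 10, cfg$err)))
  expect_equal(unname(multi$dp[1, "s3"]), 2L)

  # purity: identical inputs give identical output
  expect_identical(vs_records(call_snvs(mk_pu(list(s1 = c(5, 0, 5, 0))),
                                        cfg, "c1")),
                   vs_records(het))
})

test_that("external caller templates expand, validate and capture failure", {
  fake <- withr::local_tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh",
               'for a in "$@"; do last="$a"; done',
               'echo "args:$#" > "$last"'), fake)
  out <- withr::local_tempfile(fileext = ".vcf")
  res <- run_external_caller(paste("sh", fake, "-f {ref} {bams} -o {out}"),
                             "piece.fa", c("a.sam", "b.sam"), out)
  expect_equal(res$status, 0L)
  # -f ref a.sam b.sam -o out: space-joined expansion reached the script
  expect_equal(readLines(out)[1], "args:6")

  expect_error(run_external_caller("cmd {ref} {out}", "r", "b", "o"),
               "\\{bams\\}")
  expect_error(run_external_caller(
    "definitely-not-a-real-exe {ref} {bams} {out}", "r", "b", "o"),
    "not found")
  failing <- withr::local_tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh", "echo boom >&2", "exit 1"), failing)
  res2 <- run_external_caller(paste("sh", failing, "{ref} {bams} {out}"),
                              "r", "b", withr::local_tempfile())
  expect_true(res2$status != 0)
  expect_match(paste(res2$stderr_tail, collapse = " "), "boom")
})
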