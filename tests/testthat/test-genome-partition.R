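test_that("FASTA reading uppercases, unwraps, keeps order and trims headers", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 some description", "ACGT", "ACGT", ">b", "acgt",
               ">c", "TT"), fa)
  ref <- read_reference(fa)
  expect_s3_class(ref, "reference_genome")
  expect_identical(names(ref), c("chr1", "b", "c"))
  expect_identical(unname(as.character(ref)), c("ACGTACGT", "ACGT", "TT"))
  expect_identical(unname(reference_lengths(ref)), c(8L, 4L, 2L))
})

test_that("FASTA reading rejects duplicates, empties and non-IUPAC characters", {
  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "AC", ">a", "GG"), dup)
  expect_error(read_reference(dup), "duplicate")

  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGT", ">y", "ACQT"), bad)
  expect_error(read_reference(bad), "non-IUPAC character 'Q' on line 4")

  expect_error(reference_genome(c(a = "AC", b = "")), "empty sequence")
})

test_that("chromosome segmentation produces tiling cores with clamped pads", {
  seg <- segment_chromosome(1000, 300, 50)
  expect_equal(seg$core_start, c(0L, 300L, 600L, 900L))
  expect_equal(seg$core_end, c(300L, 600L, 900L, 1000L))
  expect_equal(seg$padded_start, c(0L, 250L, 550L, 850L))
  expect_equal(seg$padded_end, c(350L, 650L, 950L, 1000L))

  one <- segment_chromosome(250, 300, 50)
  expect_equal(nrow(one), 1L)
  expect_equal(one$core_start, 0L)
  expect_equal(one$core_end, 250L)
  expect_equal(one$padded_start, 0L)
  expect_equal(one$padded_end, 250L)

  clamp <- segment_chromosome(600, 200, 600)
  expect_equal(nrow(clamp), 3L)
  expect_true(all(clamp$padded_start == 0L))
  expect_true(all(clamp$padded_end == 600L))
})

test_that("a final core shorter than the pad can be merged into its neighbour", {
  seg <- segment_chromosome(1010, 500, 100, merge_short_final = TRUE)
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$core_end, c(500L, 1010L))
  # default keeps the short piece
  expect_equal(nrow(segment_chromosome(1010, 500, 100)), 3L)
})

test_that("piece table ids, padding and sequences follow the layout", {
  # 26-base chromosome, core 10, pad 3
  ref <- reference_genome(c(c1 = substr(strrep("ACGT", 7), 1, 26)))
  tb <- build_piece_table(ref, core_size = 10, pad = 3)
  expect_equal(tb$pieces$piece_id, c("c1:0-10", "c1:10-20", "c1:20-26"))
  expect_equal(tb$pieces$padded_start, c(0L, 7L, 17L))
  expect_equal(tb$pieces$padded_end, c(13L, 23L, 26L))

  ref2 <- reference_genome(c(a = strrep("AC", 50), b = strrep("GT", 30)))
  tb2 <- build_piece_table(ref2, core_size = 10^6, pad = 100)
  expect_equal(nrow(tb2$pieces), 2L)
  expect_equal(tb2$pieces$core_start, tb2$pieces$padded_start)
  expect_equal(tb2$pieces$core_end, tb2$pieces$padded_end)

  # "ACGTACGTAC", core 5, pad 2: second piece pads to [3, 10)
  ref3 <- reference_genome(c(c1 = "ACGTACGTAC"))
  tb3 <- build_piece_table(ref3, core_size = 5, pad = 2)
  expect_equal(piece_sequence(ref3, get_piece(tb3, "c1:5-10")), "TACGTAC")
})

test_that("an undersized pad draws a warning against the read span", {
  ref <- reference_genome(c(c1 = strrep("ACGT", 100)))
  expect_warning(build_piece_table(ref, 100, 50, max_read_span = 100),
                 "pad")
  expect_silent(build_piece_table(ref, 100, 150, max_read_span = 100))
})

test_that("relative/absolute coordinate maps are exact inverses", {
  ref <- reference_genome(c(c1 = strrep("ACGT", 250)))
  tb <- build_piece_table(ref, 300, 50)
  p2 <- get_piece(tb, "c1:300-600")  # padded [250, 650)
  expect_equal(rel_to_abs(p2, 51L)$abs_pos1, 301L)
  expect_equal(rel_to_abs(get_piece(tb, "c1:0-300"), 1L)$abs_pos1, 1L)
  expect_error(rel_to_abs(p2, 0L), "out of range")
  expect_error(rel_to_abs(p2, 401L), "out of range")
  for (rel in c(1L, 57L, 400L))
    expect_equal(abs_to_rel(p2, rel_to_abs(p2, rel)$abs_pos1), rel)
})

test_that("every position has exactly one owning piece", {
  ref <- reference_genome(c(c1 = strrep("ACGT", 250)))
  tb <- build_piece_table(ref, 300, 50)
  expect_equal(owner_piece(tb, "c1", 299L)$piece_id, "c1:0-300")
  expect_equal(owner_piece(tb, "c1", 300L)$piece_id, "c1:300-600")
  expect_equal(owner_piece(tb, "c1", 0L)$piece_id, "c1:0-300")
  expect_error(owner_piece(tb, "nope", 0L), "unknown chromosome")
  expect_error(owner_piece(tb, "c1", 1000L), "out of range")
  for (pos in sample.int(1000L, 50L) - 1L)
    expect_equal(nrow(owner_piece(tb, "c1", pos)), 1L)
})

test_that("concatenated core substrings reconstruct each chromosome", {
  set.seed(42)
  for (i in 1:5) {
    L <- sample(50:2000, 1)
    ref <- simulate_reference(c(cA = L, cB = sample(30:500, 1)),
                              seed = 100 + i)
    tb <- build_piece_table(ref, sample(10:700, 1), sample(0:100, 1))
    for (cn in names(ref)) {
      p <- tb$pieces[tb$pieces$chrom == cn, ]
      parts <- vapply(seq_len(nrow(p)), function(j)
        substring(piece_sequence(ref, p[j, ]),
                  p$core_start[j] - p$padded_start[j] + 1L,
                  p$core_end[j] - p$padded_start[j]), "")
      expect_identical(paste(parts, collapse = ""), ref[[cn]])
    }
  }
})

test_that("the piece-map TSV round-trips losslessly", {
  ref <- simulate_reference(c(chrA = 777L, chrB = 333L), seed = 3)
  tb <- build_piece_table(ref, 200, 60)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_piece_table(tb, path)
  back <- read_piece_table(path)
  expect_identical(back$pieces, tb$pieces)
  expect_identical(back$chrom_lengths, tb$chrom_lengths)
  expect_identical(back$chrom_rank, tb$chrom_rank)
  expect_identical(back$core_size, tb$core_size)
  expect_identical(back$pad, tb$pad)
})
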