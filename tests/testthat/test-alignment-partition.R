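test_that("reference span walks the CIGAR over reference-consuming ops", {
  rec <- make_records(pos0 = c(100L, 100L, 7L),
                      cigar = c("50M", "10M2D10M5I10M", "3S20M"),
                      seq = c(strrep("A", 50), strrep("A", 35),
                              strrep("A", 23)))
  span <- reference_span(rec)
  expect_equal(span$start0, c(100L, 100L, 7L))
  expect_equal(span$end0, c(150L, 132L, 27L))
  expect_error(parse_cigar("10M3Z"), "malformed CIGAR")
  expect_error(parse_cigar("*"), "CIGAR")
})

test_that("records are assigned by full-span containment in padded windows", {
  ref <- reference_genome(c(c1 = strrep("ACGT", 250)))
  tb <- build_piece_table(ref, 300, 50)  # padded [0,350),[250,650),[550,950),[850,1000)
  rec <- make_records(pos0 = c(240L, 260L, 100L), rname = "c1",
                      cigar = c("100M", "80M", "700M"),
                      seq = c(strrep("A", 100), strrep("A", 80),
                              strrep("A", 700)))
  asg <- assign_records(rec, tb)
  expect_equal(asg[["c1:0-300"]], c(1L, 2L))     # [240,340) and [260,340)
  expect_equal(asg[["c1:300-600"]], 2L)          # only [260,340) fits [250,650)
  expect_equal(asg[["c1:600-900"]], integer(0))
  # the 700-bp span exceeds every padded window
  expect_false(any(vapply(asg, function(i) 3L %in% i, TRUE)))
})

test_that("remapping shifts by the padded start and clears mate fields", {
  ref <- reference_genome(c(c1 = strrep("ACGT", 250)))
  tb <- build_piece_table(ref, 300, 50)
  p2 <- get_piece(tb, "c1:300-600")
  rec <- make_records(pos0 = c(300L, 250L), cigar = "50M", rname = "c1",
                      seq = strrep("A", 50))
  rec$rnext <- "="; rec$pnext <- 77L; rec$tlen <- 120L
  out <- remap_records(rec, p2)
  expect_equal(out$pos0, c(50L, 0L))
  expect_true(all(out$rname == "c1:300-600"))
  expect_true(all(out$rnext == "*" & out$pnext == 0L & out$tlen == 0L))
  # lift back through the coordinate map recovers the original positions
  expect_equal(rel_to_abs(p2, out$pos0 + 1L)$abs_pos1, rec$pos0 + 1L)
  bad <- make_records(pos0 = 200L, cigar = "50M", seq = strrep("A", 50),
                      rname = "c1")
  expect_error(remap_records(bad, p2), "not contained")
})

test_that("partitioning splits, remaps, keeps sort order and counts everything", {
  ref <- simulate_reference(c(c1 = 1000L), seed = 8)
  tb <- build_piece_table(ref, 300, 50)
  pos <- c(10L, 120L, 240L, 260L, 280L, 400L, 550L, 610L, 820L, 900L)
  rec <- make_records(pos0 = pos, cigar = "80M", seq = strrep("A", 80),
                      rname = "c1")
  unmapped <- make_records(pos0 = 0L, cigar = "80M", seq = strrep("A", 80),
                           flag = 4L, qname = "unm", rname = "c1")
  sam <- withr::local_tempfile(fileext = ".sam")
  write_test_sam(rbind(rec, unmapped), sam, c(c1 = 1000L))
  dir <- withr::local_tempdir()
  rep <- partition_alignments(sam, tb, dir, sample = "s1")

  expect_equal(rep$total, 11L)
  expect_equal(rep$unmapped, 1L)
  expect_equal(rep$assigned + rep$unassignable, 10L)
  expect_equal(rep$unassignable, 0L)
  # the read wholly inside the overlap zone [250,350) lands in two outputs
  expect_equal(sum(rep$per_piece), 10L + 2L)
  for (pid in names(rep$paths)) {
    out <- read_sam(rep$paths[[pid]])
    piece <- get_piece(tb, pid)
    expect_match(out$header[2], sprintf("SN:%s\tLN:%d", pid,
                                        piece$padded_end - piece$padded_start),
                 fixed = TRUE)
    expect_true(all(diff(out$records$pos0) >= 0))
    expect_true(all(out$records$rname == pid))
  }
  reads_260 <- vapply(names(rep$paths), function(pid)
    "r004" %in% read_sam(rep$paths[[pid]])$records$qname, TRUE)
  expect_equal(sum(reads_260), 2L)
})

test_that("empty input yields empty outputs and an all-zero report", {
  ref <- simulate_reference(c(c1 = 500L), seed = 1)
  tb <- build_piece_table(ref, 250, 20)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_test_sam(make_records(integer(0), character(0), character(0)),
                 sam, c(c1 = 500L))
  rep <- partition_alignments(sam, tb, withr::local_tempdir(), sample = "s1")
  expect_equal(rep$total, 0L)
  expect_equal(rep$assigned, 0L)
  expect_true(all(rep$per_piece == 0L))
  for (p in rep$paths)
    expect_equal(nrow(read_sam(p)$records), 0L)
})

test_that("unsorted input and unknown chromosomes are refused", {
  ref <- simulate_reference(c(c1 = 500L), seed = 1)
  tb <- build_piece_table(ref, 250, 20)
  rec <- make_records(pos0 = c(100L, 50L), cigar = "20M", rname = "c1",
                      seq = strrep("A", 20))
  sam <- withr::local_tempfile(fileext = ".sam")
  write_test_sam(rec, sam, c(c1 = 500L))
  expect_error(partition_alignments(sam, tb, withr::local_tempdir()),
               "not coordinate-sorted")

  rec2 <- make_records(pos0 = 10L, cigar = "20M", seq = strrep("A", 20),
                       rname = "cX")
  sam2 <- withr::local_tempfile(fileext = ".sam")
  write_test_sam(rec2, sam2, c(cX = 500L))
  expect_error(partition_alignments(sam2, tb, withr::local_tempdir()),
               "absent from piece table")
})

test_that("pileups at core positions are identical before and after splitting", {
  # the load-bearing boundary property, on a small dense fixture
  sim <- simulate_dataset(withr::local_tempdir(), lengths = c(c1 = 4000L),
                          n_snvs = 10L, coverage = 15, read_len = 60L,
                          err_rate = 0.02, seed = 21)
  ref <- read_reference(sim$reference)
  tb <- build_piece_table(ref, 1000, 120)
  whole <- read_sam(sim$sams[["s1"]], sample = "s1")
  pu_all <- build_pileup(whole$records, ref[["c1"]], samples = "s1")
  rep <- partition_alignments(sim$sams[["s1"]], tb, withr::local_tempdir(),
                              sample = "s1")
  for (pid in names(rep$paths)) {
    piece <- get_piece(tb, pid)
    part <- read_sam(rep$paths[[pid]], sample = "s1")
    pu <- build_pileup(part$records, piece_sequence(ref, piece),
                       samples = "s1")
    core_cols <- (piece$core_start:(piece$core_end - 1L)) -
      piece$padded_start + 1L
    expect_identical(pu$counts$s1[, core_cols, drop = FALSE],
                     pu_all$counts$s1[, (piece$core_start + 1L):piece$core_end,
                                      drop = FALSE])
  }
})
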