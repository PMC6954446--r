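test_that("base counting follows the CIGAR column rules", {
  g <- genome("ref", "ACGA")
  f <- tempfile(fileext = ".sam")

  # one 4M read with a mismatch at pos 4
  write_test_sam(f, g, "r1", 0L, 1L, "4M", "ACGT")
  bct <- build_base_counts(f, g)
  expect_equal(bct$counts[, "A"], c(1L, 0L, 0L, 0L))
  expect_equal(bct$counts[, "C"], c(0L, 1L, 0L, 0L))
  expect_equal(bct$counts[, "G"], c(0L, 0L, 1L, 0L))
  expect_equal(bct$counts[, "T"], c(0L, 0L, 0L, 1L))
  expect_equal(bct$coverage, rep(1L, 4))

  # zero alignments
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:ref\tLN:4"), f)
  bct <- build_base_counts(f, g)
  expect_true(all(bct$counts == 0L) && all(bct$coverage == 0L))

  # 10 identical reads with C at a reference-T position
  g2 <- genome("ref", "ACTA")
  write_test_sam(f, g2, sprintf("r%d", 1:10), rep(0L, 10), rep(1L, 10),
                 rep("4M", 10), rep("ACCA", 10))
  bct <- build_base_counts(f, g2)
  expect_equal(unname(bct$counts[3, ]), c(0L, 10L, 0L, 0L, 0L))
  expect_equal(bct$coverage[3], 10L)
})

test_that("clips, indels, Ns and non-primary records are handled", {
  g <- genome("ref", "ACGTACGT")
  f <- tempfile(fileext = ".sam")

  write_test_sam(f, g,
    qname = c("soft", "ins", "del", "hasN", "sec", "unmapped", "supp"),
    flag  = c(0L, 0L, 0L, 0L, 256L, 4L, 2048L),
    pos   = c(3L, 1L, 1L, 5L, 1L, 1L, 1L),
    cigar = c("2S3M", "2M1I2M", "2M2D2M", "3M", "4M", "4M", "4M"),
    seq   = c("TTGTA", "ACGGT", "ACAC", "ANG", "ACGT", "ACGT", "ACGT"))
  bct <- build_base_counts(f, g)

  # soft: clipped TT ignored, GTA aligned at 3..5
  # ins: inserted base not counted, AC|GT aligned at 1..4
  # del: AC at 1,2, deletion spans 3,4, AC at 5,6
  # hasN: N at pos 6 goes to the N slot and is excluded from coverage
  expect_equal(unname(bct$counts[1, "A"]), 2L)            # ins + del
  expect_equal(unname(bct$counts[6, "N"]), 1L)
  expect_equal(bct$coverage[6], 1L)               # del's C only
  expect_equal(bct$coverage[5], 3L)               # soft + del + hasN
  # secondary/unmapped/supplementary contribute nothing
  expect_equal(sum(bct$counts), 3L + 4L + 4L + 3L)
})

test_that("counting agrees with the htslib pileup oracle", {
  set.seed(101)
  g <- make_genome(300, seed = 5, id = "oracle_ref")
  tt <- truth_table(g, crosslink_sites = data.frame(
    position = uridine_positions(g)[c(5, 20)], rate = 0.1),
    base_error = 0.01)
  f <- tempfile(fileext = ".sam")
  simulate_mutprofile_reads(g, tt, "test", depth = 300, path = f,
                            read_len = 80, seed = 9, reverse_frac = 0.3)
  bct <- build_base_counts(f, g)
  expect_equal(bct$counts, oracle_pileup_counts(f, g))
  # conservation: A+C+G+T == coverage everywhere
  expect_equal(unname(rowSums(bct$counts[, 1:4])), bct$coverage)
})

test_that("malformed records are skipped with a warning, bad ref errors", {
  g <- genome("ref", "ACGTACGT")
  f <- tempfile(fileext = ".sam")
  lines <- c("@HD\tVN:1.6", "@SQ\tSN:ref\tLN:8",
             "ok\t0\tref\t1\t60\t4M\t*\t0\t0\tACGT\tFFFF",
             "bad\t0\tref\t1\t60\t5M\t*\t0\t0\tACGT\tFFFF")
  writeLines(lines, f)
  expect_warning(bct <- build_base_counts(f, g), "CIGAR inconsistent")
  expect_equal(sum(bct$counts), 4L)

  g2 <- genome("other", "ACGTACGT")
  writeLines(lines[1:3], f)
  expect_error(build_base_counts(f, g2), "not genome")
})

test_that("counts are invariant to read order and file splitting", {
  set.seed(11)
  g <- make_genome(120, seed = 2, id = "ref")
  tt <- truth_table(g, base_error = 0.02)
  f <- tempfile(fileext = ".sam")
  simulate_mutprofile_reads(g, tt, "control", depth = 50, path = f,
                            read_len = 40, seed = 3)
  lines <- readLines(f)
  hdr <- lines[startsWith(lines, "@")]
  aln <- lines[!startsWith(lines, "@")]
  base <- build_base_counts(f, g)

  shuf <- tempfile(fileext = ".sam")
  writeLines(c(hdr, sample(aln)), shuf)
  expect_equal(build_base_counts(shuf, g)$counts, base$counts)

  half <- floor(length(aln) / 2)
  f1 <- tempfile(fileext = ".sam"); writeLines(c(hdr, aln[1:half]), f1)
  f2 <- tempfile(fileext = ".sam"); writeLines(c(hdr, aln[-(1:half)]), f2)
  merged <- build_base_counts(f1, g)$counts + build_base_counts(f2, g)$counts
  expect_equal(merged, base$counts)
})

test_that("transition and mismatch profiles compute the stated rates", {
  g <- genome("ref", "TAC")
  counts <- matrix(0L, 3, 5, dimnames = list(NULL, c("A", "C", "G", "T", "N")))
  counts[1, ] <- c(0L, 30L, 0L, 9970L, 0L)    # T position, 30 C of 10000
  counts[2, ] <- c(9950L, 20L, 20L, 10L, 0L)  # A position
  counts[3, ] <- c(40L, 30L, 20L, 10L, 0L)    # C position
  bct <- vparcl:::new_base_count_table("ref", counts)

  tp <- transition_profile(bct, g, "T", "C")
  expect_equal(tp$rate[1], 0.003)
  expect_true(is.na(tp$rate[2]))  # A position not in a U>C profile

  mp <- mismatch_profile(bct, g, c("A", "C"))
  expect_equal(mp$rate[2], 0.005)
  expect_equal(mp$rate[3], 70 / 100)  # brute-force non-reference sum
  expect_true(is.na(mp$rate[1]))

  # zero coverage is absent
  counts0 <- counts; counts0[1, ] <- 0L
  tp0 <- transition_profile(vparcl:::new_base_count_table("ref", counts0), g)
  expect_true(is.na(tp0$rate[1]))
})

test_that("observed rates converge to configured rates at depth 50k", {
  g <- make_genome(400, seed = 8, id = "deep")
  u <- uridine_positions(g)
  site <- u[which.min(abs(u - 200))]
  r <- 0.004
  tt <- truth_table(g, crosslink_sites = data.frame(position = site, rate = r),
                    base_error = 0)
  f <- tempfile(fileext = ".sam")
  simulate_mutprofile_reads(g, tt, "test", depth = 50000, path = f,
                            read_len = 100, seed = 21)
  bct <- build_base_counts(f, g)
  tp <- transition_profile(bct, g)
  d <- bct$coverage[site]
  se <- sqrt(r * (1 - r) / d)
  expect_lt(abs(tp$rate[site] - r), 3 * se)
})
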