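test_that("make_genome honours length, composition and seed", {
  expect_equal(genome_length(make_genome(0)), 0)
  allT <- make_genome(50, c(0, 0, 0, 1), seed = 2)
  expect_equal(allT$seq, strrep("T", 50))
  expect_equal(count_uridines(allT), 50)
  expect_identical(make_genome(200, seed = 7)$seq, make_genome(200, seed = 7)$seq)
  expect_false(make_genome(200, seed = 7)$seq == make_genome(200, seed = 8)$seq)
})

test_that("truth tables validate site classes and rates", {
  g <- genome("g", "ATGCTTACGT")
  expect_error(truth_table(g, crosslink_sites = data.frame(position = 3, rate = 0.1)),
               "T positions")
  expect_error(truth_table(g, crosslink_sites = data.frame(position = 2, rate = 1.5)),
               "rates")
  expect_error(truth_table(g, dms_unpaired = data.frame(position = 2, rate = 0.1)),
               "A/C")
  tt <- truth_table(g, variant_sites = data.frame(position = c(2L, 3L), rate = 0.05))
  # default variant substitution is the transition partner
  expect_equal(tt$variant_sites$alt, c("C", "A"))
})

test_that("simulated output is byte-identical under a fixed seed", {
  g <- make_genome(200, seed = 3)
  tt <- truth_table(g, base_error = 0.01)
  f1 <- tempfile(fileext = ".sam"); f2 <- tempfile(fileext = ".sam")
  simulate_mutprofile_reads(g, tt, "test", depth = 100, path = f1, seed = 5,
                            read_len = 60)
  simulate_mutprofile_reads(g, tt, "test", depth = 100, path = f2, seed = 5,
                            read_len = 60)
  expect_identical(readLines(f1), readLines(f2))
  simulate_mutprofile_reads(g, tt, "test", depth = 100, path = f2, seed = 6,
                            read_len = 60)
  expect_false(identical(readLines(f1), readLines(f2)))
})

test_that("configured rates are recovered within 3 binomial SEs", {
  g <- make_genome(600, seed = 13)
  u <- uridine_positions(g)
  sites <- u[u > 100 & u < 500][1:3]
  r <- 0.02
  tt <- truth_table(g,
    crosslink_sites = data.frame(position = sites, rate = r),
    variant_sites = data.frame(position = u[u > 100 & u < 500][5], rate = 0.05),
    base_error = 0)
  ft <- tempfile(fileext = ".sam"); fc <- tempfile(fileext = ".sam")
  simulate_mutprofile_reads(g, tt, "test", depth = 20000, path = ft, seed = 41)
  simulate_mutprofile_reads(g, tt, "control", depth = 20000, path = fc, seed = 42)
  pt <- transition_profile(build_base_counts(ft, g), g)
  pc <- transition_profile(build_base_counts(fc, g), g)
  covt <- build_base_counts(ft, g)$coverage

  for (s in sites) {
    se <- sqrt(r * (1 - r) / covt[s])
    expect_lt(abs(pt$rate[s] - r), 3 * se)   # test arm carries the signal
    expect_equal(pc$rate[s], 0)              # control arm does not
  }
  # the both-arm variant appears at similar elevated rate in BOTH arms
  v <- tt$variant_sites$position
  expect_gt(pt$rate[v], 0.03)
  expect_gt(pc$rate[v], 0.03)
  sig <- fold_change(pt, pc)
  expect_lt(sig$signal[v], 2)
  expect_gt(sig$signal[v], 0.5)
})

test_that("dose multiplier scales crosslink rates", {
  g <- make_genome(400, seed = 23)
  s <- uridine_positions(g)[20]
  tt <- truth_table(g, crosslink_sites = data.frame(position = s, rate = 0.01),
                    base_error = 0)
  f <- tempfile(fileext = ".sam")
  rates <- vapply(c(1, 4), function(mult) {
    simulate_mutprofile_reads(g, tt, "test", depth = 10000, path = f,
                              seed = 31, dose_multiplier = mult)
    transition_profile(build_base_counts(f, g), g)$rate[s]
  }, numeric(1))
  expect_gt(rates[2], 2.5 * rates[1])
})

test_that("DMS arms mutate unpaired A/C only, never G/T", {
  g <- genome("dms", strrep("GATCGATCGC", 30))
  # pair up the first 100 positions against the last 100 (status only)
  pair <- integer(300)
  pair[1:100] <- 300:201
  pair[300:201] <- 1:100
  st <- vparcl:::new_structure_model("dms", pair)

  ft <- tempfile(fileext = ".sam"); fc <- tempfile(fileext = ".sam")
  simulate_dms_reads(g, st, unpaired_rate = 0.05, paired_rate = 0.002,
                     depth = 3000, path = ft, arm = "test", base_error = 0,
                     read_len = 100, seed = 61)
  simulate_dms_reads(g, st, unpaired_rate = 0.05, paired_rate = 0.002,
                     depth = 3000, path = fc, arm = "control", base_error = 0,
                     read_len = 100, seed = 62)
  mt <- mismatch_profile(build_base_counts(ft, g), g)
  mc <- mismatch_profile(build_base_counts(fc, g), g)

  gb <- genome_bases(g)
  core <- 110:290  # away from coverage ramps
  unpaired_ac <- intersect(core, which(gb %in% c("A", "C") & pair == 0L))
  paired_ac <- setdiff(which(gb %in% c("A", "C") & pair != 0L), c(1:20, 281:300))
  expect_gt(mean(mt$rate[unpaired_ac]), 0.03)
  expect_lt(mean(mt$rate[paired_ac]), 0.01)
  # DMS- control carries no signal at all
  expect_equal(sum(mc$rate[c(unpaired_ac, paired_ac)]), 0)
  # G/T positions receive nothing in either arm
  gt_pos <- intersect(core, which(gb %in% c("G", "T")))
  tp <- mismatch_profile(build_base_counts(ft, g), g, c("G", "T"))
  expect_equal(sum(tp$rate[gt_pos]), 0)
})

test_that("FASTQ emission writes constant Q37 reads of the right length", {
  g <- make_genome(150, seed = 17)
  tt <- truth_table(g, base_error = 0)
  f <- tempfile(fileext = ".fastq")
  simulate_mutprofile_reads(g, tt, "control", depth = 20, path = f,
                            read_len = 75, emit = "fastq", seed = 3)
  reads <- read_fastq(f)
  expect_true(all(vapply(reads, function(r) nchar(r$bases) == 75, logical(1))))
  expect_true(all(vapply(reads, function(r) all(r$quals == 37L), logical(1))))
  # sidecar records the parameters
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(meta$read_len, 75)
  expect_equal(meta$arm, "control")
})

test_that("read length beyond the genome errors", {
  g <- make_genome(50, seed = 1)
  tt <- truth_table(g)
  expect_error(simulate_mutprofile_reads(g, tt, "test", depth = 10,
                                         path = tempfile(), read_len = 60),
               "exceeds")
})
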