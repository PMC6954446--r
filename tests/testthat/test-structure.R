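test_that("constraint sets validate ordering and bounds", {
  cs <- constraint_set("g", c(3L, 17L), genome_length = 20L)
  expect_equal(cs$unpaired_positions, c(3L, 17L))
  expect_error(constraint_set("g", c(17L, 3L)), "ascending")
  expect_error(constraint_set("g", c(3L, 3L)), "ascending")
  expect_error(constraint_set("g", 25L, genome_length = 20L), "beyond")
  expect_silent(constraint_set("g", integer(0)))
})

test_that("constraint files use the section dialect and round-trip", {
  cs <- constraint_set("g", c(3L, 17L))
  f <- tempfile(fileext = ".con")
  write_constraint_file(cs, f)
  expect_equal(readLines(f),
               c("DS:", "-1", "SS:", "3", "17", "-1", "Mod:", "-1",
                 "Pairs:", "-1 -1", "FMN:", "-1", "Forbids:", "-1 -1"))
  back <- read_constraint_file(f, "g")
  expect_equal(back$unpaired_positions, cs$unpaired_positions)

  # empty set: all sections present, only terminators
  write_constraint_file(constraint_set("g", integer(0)), f)
  expect_equal(readLines(f),
               c("DS:", "-1", "SS:", "-1", "Mod:", "-1",
                 "Pairs:", "-1 -1", "FMN:", "-1", "Forbids:", "-1 -1"))
  expect_length(read_constraint_file(f)$unpaired_positions, 0)
})

test_that("dot-bracket parsing handles pairs, errors, and round-trips", {
  s <- parse_dotbracket("((...))")
  expect_equal(s$pair, c(7L, 6L, 0L, 0L, 0L, 2L, 1L))
  expect_equal(parse_dotbracket(".......")$pair, rep(0L, 7))
  expect_error(parse_dotbracket("((..)"), "unbalanced")
  expect_error(parse_dotbracket("(..))"), "unbalanced")
  expect_equal(to_dotbracket(s), "((...))")
})

test_that("CT parsing builds involutions and rejects inconsistencies", {
  f <- tempfile(fileext = ".ct")
  writeLines(c("7 demo",
               "1 G 0 2 7 1", "2 G 1 3 6 2", "3 A 2 4 0 3", "4 A 3 5 0 4",
               "5 A 4 6 0 5", "6 C 5 7 2 6", "7 C 6 0 1 7"), f)
  s <- parse_structure(f)
  expect_equal(s$pair, c(7L, 6L, 0L, 0L, 0L, 2L, 1L))

  writeLines(c("2 bad", "1 A 0 2 2 1", "2 A 1 0 0 2"), f)
  expect_error(parse_structure(f), "non-involutive")

  # dot-bracket file with header and sequence line, format auto-detected
  writeLines(c("> demo2", "GGAAACC", ".(...)."), f)
  s2 <- parse_structure(f)
  expect_equal(s2$pair, c(0L, 6L, 0L, 0L, 0L, 2L, 0L))
})

test_that("CT writing round-trips through parse_structure", {
  g <- genome("hp", "GGGAAACCC")
  s <- toy_fold(g)
  f <- tempfile(fileext = ".ct")
  write_ct(s, g, f)
  expect_equal(parse_structure(f)$pair, s$pair)
})

test_that("ds_fraction and refold_difference measure what they claim", {
  s <- parse_dotbracket("((...))")
  expect_equal(ds_fraction(s), 4 / 7)
  expect_equal(ds_fraction(parse_dotbracket("....")), 0)
  # perfect stem of n pairs with loop 3
  n <- 5
  stem <- parse_dotbracket(paste0(strrep("(", n), "...", strrep(")", n)))
  expect_equal(ds_fraction(stem), 2 * n / (2 * n + 3))

  a <- parse_dotbracket("((...))")
  b <- parse_dotbracket(".(...).")
  expect_equal(refold_difference(a, a), 0)
  expect_equal(refold_difference(a, b), 2 / 7)
  # paired with a different partner but still paired: unchanged status
  x <- parse_dotbracket("((...)).....")
  y <- parse_dotbracket("(.....)(...)")
  expect_equal(refold_difference(x, y),
               mean((x$pair != 0) != (y$pair != 0)))
  expect_error(refold_difference(a, x), "lengths")
  expect_true(ds_fraction(s) >= 0 && ds_fraction(s) <= 1)
})

test_that("toy_fold solves the stated examples", {
  g <- genome("hp", "GGGAAACCC")
  s <- toy_fold(g)
  expect_equal(sum(s$pair != 0) / 2, 3)
  expect_equal(to_dotbracket(s), "(((...)))")

  s1 <- toy_fold(g, constraint_set("hp", 1L))
  expect_equal(sum(s1$pair != 0) / 2, 2)
  expect_equal(s1$pair[1], 0L)

  expect_equal(toy_fold(genome("a4", "AAAA"))$pair, rep(0L, 4))
})

test_that("toy_fold matches exhaustive enumeration and respects constraints", {
  set.seed(99)
  for (rep in 1:60) {
    n <- sample(4:10, 1)
    bases <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    g <- genome("t", paste(bases, collapse = ""))
    blocked <- runif(n) < 0.2
    cs <- constraint_set("t", which(blocked))
    s <- toy_fold(g, cs)
    expect_equal(sum(s$pair != 0) / 2,
                 enum_max_pairs(bases, blocked = blocked))
    # constrained positions unpaired; involution; min loop separation
    expect_true(all(s$pair[blocked] == 0L))
    nz <- which(s$pair != 0L)
    expect_equal(s$pair[s$pair[nz]], nz)
    expect_true(all(abs(s$pair[nz] - nz) > 3))
    # deterministic traceback
    expect_identical(toy_fold(g, cs)$pair, s$pair)
    # dot-bracket round trip on nested output
    expect_equal(parse_dotbracket(to_dotbracket(s))$pair, s$pair)
  }
})

test_that("unpaired constraint selection supports both rules", {
  sig <- vparcl:::new_signal_profile("g", "mismatch:A,C",
    signal = c(rep(1, 99), 50),
    test_rate = rep(0.01, 100), control_rate = rep(0.001, 100))
  sig$passed_background <- rep(TRUE, 100)

  cs_sigma <- select_unpaired_constraints(sig, list(type = "sigma", k = 2))
  expect_equal(cs_sigma$unpaired_positions, 100L)

  cs_top <- select_unpaired_constraints(sig, list(type = "top", frac = 0.05))
  expect_length(cs_top$unpaired_positions, 5)
  expect_true(100L %in% cs_top$unpaired_positions)

  # restricted to background-passing positions
  sig$passed_background[100] <- FALSE
  expect_length(select_unpaired_constraints(sig,
    list(type = "sigma", k = 2))$unpaired_positions, 0)

  # rule selecting none is a valid empty set
  sig2 <- sig
  sig2$signal <- rep(1, 100)
  expect_length(select_unpaired_constraints(sig2,
    list(type = "sigma", k = 2))$unpaired_positions, 0)
})
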