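# Independent oracles and fixture builders used across the suite.

# Brute-force enumeration of all nested structures (no dynamic-programming
# table): every structure over [i, j] either leaves i unpaired or pairs i
# with some admissible k; the maximum pair count is taken over the full
# enumeration tree.
enum_max_pairs <- function(bases, min_loop = 3L, blocked = logical(length(bases))) {
  pairable <- function(x, y) {
    paste0(x, y) %in% c("AT", "TA", "CG", "GC", "GT", "TG")
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (!blocked[i] && !blocked[k] && pairable(bases[i], bases[k])) {
        cand <- 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j)
        if (cand > best) best <- cand
      }
    }
    best
  }
  if (length(bases) < 2L) return(0L)
  rec(1L, length(bases))
}

# Pileup oracle: the htslib pileup engine via Rsamtools, configured to count
# every base of every primary alignment. Independent of the package's
# scanBam/consensusMatrix counting path.
oracle_pileup_counts <- function(sam_path, genome) {
  bam <- suppressMessages(Rsamtools::asBam(sam_path, tempfile(),
                                           overwrite = TRUE))
  on.exit(unlink(c(bam, paste0(bam, ".bai"))))
  pp <- Rsamtools::PileupParam(
    max_depth = 1000000L, min_base_quality = 0L, min_mapq = 0L,
    min_nucleotide_depth = 1L, distinguish_strands = FALSE,
    distinguish_nucleotides = TRUE, ignore_query_Ns = FALSE,
    include_deletions = FALSE, include_insertions = FALSE)
  sbp <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  pu <- Rsamtools::pileup(bam, scanBamParam = sbp, pileupParam = pp)
  counts <- matrix(0L, nrow = genome_length(genome), ncol = 5L,
                   dimnames = list(NULL, c("A", "C", "G", "T", "N")))
  if (nrow(pu)) {
    keep <- as.character(pu$nucleotide) %in% colnames(counts)
    pu <- pu[keep, , drop = FALSE]
    idx <- cbind(pu$pos, match(as.character(pu$nucleotide), colnames(counts)))
    for (r in seq_len(nrow(pu))) counts[idx[r, 1], idx[r, 2]] <-
        counts[idx[r, 1], idx[r, 2]] + pu$count[r]
  }
  counts
}

# Brute-force two-sample K-S D: sup of |ECDF difference| evaluated on a
# dense grid spanning both samples.
oracle_ks_D <- function(x, y) {
  grid <- seq(min(c(x, y)) - 1, max(c(x, y)) + 1, length.out = 2000)
  max(abs(vapply(grid, function(g) mean(x <= g) - mean(y <= g), numeric(1))))
}

# Construct a RateProfile directly (bypassing pileup) for signal-level tests.
make_profile <- function(rate, coverage, genome_id = "g", event = "T>C",
                         eligible = !logical(length(rate))) {
  rate[coverage == 0] <- NA_real_
  vparcl:::new_rate_profile(genome_id, event, rate, coverage, eligible)
}

# Minimal SAM writer for hand-built alignment fixtures.
write_test_sam <- function(path, genome, qname, flag, pos, cigar, seq,
                           mapq = 60L) {
  lines <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", genome$id, genome_length(genome)),
             sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                     qname, flag, genome$id, pos, mapq, cigar, seq,
                     strrep("F", nchar(seq))))
  writeLines(lines, path)
  path
}
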