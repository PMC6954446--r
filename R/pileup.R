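#' @title Alignment pileup and substitution-rate profiles
#' @description Converts SAM/BAM alignments into per-position base-count
#'   tables, and derives per-position substitution-rate profiles (e.g. the
#'   U>C transition rate at genomic uridines, or the any-mismatch rate at A/C
#'   positions) from them. Only primary alignments are counted; insertions,
#'   deletions and clipped bases contribute nothing; read `N`s are tallied in
#'   their own slot and excluded from coverage.
#' @name pileup
NULL

BASES <- c("A", "C", "G", "T", "N")

new_base_count_table <- function(genome_id, counts) {
  stopifnot(is.matrix(counts), identical(colnames(counts), BASES))
  structure(list(genome_id = genome_id, counts = counts,
                 coverage = unname(rowSums(counts[, c("A", "C", "G", "T"),
                                                  drop = FALSE]))),
            class = "BaseCountTable")
}

#' @export
print.BaseCountTable <- function(x, ...) {
  cat(sprintf("BaseCountTable '%s': %d positions, median coverage %g\n",
              x$genome_id, nrow(x$counts), stats::median(x$coverage)))
  invisible(x)
}

cigar_ops <- function(cigar) {
  m <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub("[MIDNSHP=X]", "", m)),
       op = sub("[0-9]+", "", m))
}

cigar_query_length <- function(cigar) {
  ops <- cigar_ops(cigar)
  if (!length(ops$op)) return(NA_integer_)
  sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
}

# Drop SAM alignment lines whose CIGAR is inconsistent with the read length
# (sum of query-consuming ops M/I/S/=/X must equal the SEQ length).
# Query lengths are computed once per distinct CIGAR string.
validate_sam_records <- function(lines) {
  idx <- which(!startsWith(lines, "@"))
  if (!length(idx)) return(lines)
  fields <- data.table::tstrsplit(lines[idx], "\t", fixed = TRUE)
  cig <- fields[[6L]]
  seq <- fields[[10L]]
  ucig <- unique(cig)
  qlen <- vapply(ucig, cigar_query_length, integer(1))
  bad <- cig != "*" & seq != "*" &
    (is.na(qlen[match(cig, ucig)]) | qlen[match(cig, ucig)] != nchar(seq))
  if (any(bad)) {
    warning(sprintf("skipped %d SAM record(s) with CIGAR inconsistent with read length",
                    sum(bad)))
    lines <- lines[-idx[bad]]
  }
  lines
}

#' Build a per-position base-count table from alignments
#'
#' Counts, for every aligned column of CIGAR class match/mismatch, the read
#' base at the corresponding reference position. Unmapped, secondary and
#' supplementary records are excluded, as are inserted, deleted and clipped
#' bases. No per-base quality or MAPQ threshold is applied here (read-level
#' filtering belongs to preprocessing).
#'
#' @param path a SAM (`.sam`) or BAM file aligned against `genome`.
#' @param genome the reference [genome()]; its `id` must match the alignment
#'   header's `@SQ` name.
#' @return a `BaseCountTable`: `counts` is a `genome_length x 5` matrix with
#'   columns A,C,G,T,N; `coverage` is the per-position A+C+G+T sum.
#' @export
build_base_counts <- function(path, genome) {
  stopifnot(inherits(genome, "Genome"))
  is_sam <- grepl("\\.sam$", path, ignore.case = TRUE)
  if (is_sam) {
    lines <- readLines(path)
    lines2 <- validate_sam_records(lines)
    tmp_sam <- tempfile(fileext = ".sam")
    on.exit(unlink(tmp_sam), add = TRUE)
    writeLines(lines2, tmp_sam)
    bam <- suppressMessages(
      Rsamtools::asBam(tmp_sam, tempfile(), overwrite = TRUE,
                       indexDestination = FALSE))
    on.exit(unlink(bam), add = TRUE)
  } else {
    bam <- path
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!(genome$id %in% names(hdr)))
    stop(sprintf("alignment file references '%s', not genome '%s'",
                 paste(names(hdr), collapse = ","), genome$id))
  L <- genome_length(genome)
  sbp <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    what = c("pos", "cigar", "seq"))
  sb <- Rsamtools::scanBam(bam, param = sbp)[[1]]
  counts <- matrix(0L, nrow = L, ncol = 5L, dimnames = list(NULL, BASES))
  if (length(sb$pos)) {
    # fast path: ungapped full-length matches within the reference
    wid <- Biostrings::width(sb$seq)
    simple <- grepl("^[0-9]+M$", sb$cigar) & sb$pos + wid - 1L <= L
    if (any(simple)) {
      cm <- Biostrings::consensusMatrix(sb$seq[simple],
                                        shift = sb$pos[simple] - 1L,
                                        width = L)
      counts <- counts + t(cm[BASES, , drop = FALSE])
    }
    # general path: walk the CIGAR, counting M/=/X columns only
    for (k in which(!simple)) {
      ops <- cigar_ops(sb$cigar[k])
      rpos <- sb$pos[k]
      qpos <- 1L
      bases <- strsplit(as.character(sb$seq[k]), "", fixed = TRUE)[[1]]
      for (o in seq_along(ops$op)) {
        len <- ops$len[o]
        op <- ops$op[o]
        if (op %in% c("M", "=", "X")) {
          keep <- which(rpos:(rpos + len - 1L) <= L)
          if (length(keep)) {
            b <- bases[qpos + keep - 1L]
            b[!b %in% BASES] <- "N"
            tab <- table(factor(paste0(rpos + keep - 1L, ":", b)))
            ij <- strsplit(names(tab), ":", fixed = TRUE)
            counts[cbind(as.integer(vapply(ij, `[`, character(1), 1L)),
                         match(vapply(ij, `[`, character(1), 2L), BASES))] <-
              counts[cbind(as.integer(vapply(ij, `[`, character(1), 1L)),
                           match(vapply(ij, `[`, character(1), 2L), BASES))] +
              as.integer(tab)
          }
          rpos <- rpos + len
          qpos <- qpos + len
        } else if (op %in% c("D", "N")) {
          rpos <- rpos + len
        } else if (op %in% c("I", "S")) {
          qpos <- qpos + len
        }  # H, P consume nothing counted here
      }
    }
  }
  new_base_count_table(genome$id, counts)
}

#' Write a BaseCountTable as TSV
#'
#' Columns: position, ref, A, C, G, T, N, coverage.
#'
#' @param bct a `BaseCountTable`.
#' @param genome the matching [genome()] (supplies the `ref` column).
#' @param path output file.
#' @export
write_base_counts <- function(bct, genome, path) {
  stopifnot(inherits(bct, "BaseCountTable"), bct$genome_id == genome$id)
  df <- data.frame(position = seq_len(nrow(bct$counts)),
                   ref = genome_bases(genome), bct$counts,
                   coverage = bct$coverage, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

new_rate_profile <- function(genome_id, event, rate, coverage, eligible,
                             coverage_ok = NULL) {
  if (is.null(coverage_ok)) coverage_ok <- coverage > 0L
  structure(list(genome_id = genome_id, event = event, rate = rate,
                 coverage = coverage, eligible = eligible,
                 coverage_ok = coverage_ok),
            class = "RateProfile")
}

#' @export
print.RateProfile <- function(x, ...) {
  cat(sprintf("RateProfile '%s' [%s]: %d eligible positions, %d with rates\n",
              x$genome_id, x$event, sum(x$eligible),
              sum(!is.na(x$rate))))
  invisible(x)
}

#' Per-position transition rate for one substitution class
#'
#' At each position whose reference base is `ref_base`, the rate is
#' `count(alt_base) / coverage`; positions with zero coverage carry `NA`
#' (absent). The canonical crosslink readout is `ref_base = "T"`,
#' `alt_base = "C"` (the U>C transition rate at genomic uridines).
#'
#' @param bct a `BaseCountTable`.
#' @param genome the matching [genome()].
#' @param ref_base,alt_base single distinct bases in A/C/G/T.
#' @return a `RateProfile` with full-genome-length vectors; `rate` is `NA`
#'   outside eligible positions and where absent.
#' @export
transition_profile <- function(bct, genome, ref_base = "T", alt_base = "C") {
  stopifnot(inherits(bct, "BaseCountTable"), bct$genome_id == genome$id,
            ref_base != alt_base, ref_base %in% BASES[1:4],
            alt_base %in% BASES[1:4])
  eligible <- genome_bases(genome) == ref_base
  rate <- rep(NA_real_, nrow(bct$counts))
  idx <- which(eligible & bct$coverage > 0L)
  rate[idx] <- bct$counts[idx, alt_base] / bct$coverage[idx]
  new_rate_profile(genome$id, paste0(ref_base, ">", alt_base), rate,
                   bct$coverage, eligible)
}

#' Per-position any-mismatch rate over a set of reference bases
#'
#' At positions whose reference base is in `ref_bases`, the rate is
#' `(coverage - count(ref_base)) / coverage`. The DMS readout uses
#' `ref_bases = c("A", "C")` (overall mutation rate of A and C positions).
#'
#' @param bct a `BaseCountTable`.
#' @param genome the matching [genome()].
#' @param ref_bases subset of A/C/G/T.
#' @return a `RateProfile`.
#' @export
mismatch_profile <- function(bct, genome, ref_bases = c("A", "C")) {
  stopifnot(inherits(bct, "BaseCountTable"), bct$genome_id == genome$id,
            all(ref_bases %in% BASES[1:4]))
  gb <- genome_bases(genome)
  eligible <- gb %in% ref_bases
  rate <- rep(NA_real_, nrow(bct$counts))
  idx <- which(eligible & bct$coverage > 0L)
  if (length(idx)) {
    ref_count <- bct$counts[cbind(idx, match(gb[idx], BASES))]
    rate[idx] <- (bct$coverage[idx] - ref_count) / bct$coverage[idx]
  }
  new_rate_profile(genome$id,
                   paste0("mismatch:", paste(sort(ref_bases), collapse = ",")),
                   rate, bct$coverage, eligible)
}
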