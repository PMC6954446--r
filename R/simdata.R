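#' @title Synthetic genomes and reads with ground truth
#' @description Generates random genomes and paired crosslinked/control or
#'   DMS+/DMS- read sets in which designated sites carry elevated
#'   substitution rates, fixed minority variants are present in both members
#'   of a pair, and a uniform per-base sequencing error applies everywhere.
#'   Reads are emitted as FASTQ or as perfectly aligned full-length-match SAM
#'   records so pileup can be exercised without an aligner. Every stage of
#'   the pipeline is thereby testable against known truth with no downloads.
#'   Coverage is uniform (no 3'/5' bias); quality scores are constant; no
#'   indels or PCR duplicates are modelled.
#' @name simdata
NULL

#' Generate a random genome
#'
#' @param length genome length in nt.
#' @param base_composition probabilities for A, C, G, T (must sum to 1).
#' @param seed integer seed (same seed, same sequence).
#' @param id reference identifier.
#' @return a [genome()]; seed and composition are recorded as attributes.
#' @export
make_genome <- function(length, base_composition = c(0.25, 0.25, 0.25, 0.25),
                        seed = 1L, id = "synthetic_genome") {
  stopifnot(length >= 0, length(base_composition) == 4L,
            abs(sum(base_composition) - 1) < 1e-8)
  set.seed(seed)
  seq <- if (length == 0L) "" else
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                 prob = base_composition), collapse = "")
  g <- genome(id, seq)
  attr(g, "seed") <- seed
  attr(g, "base_composition") <- base_composition
  g
}

# transition partner used as the default fixed-variant substitution
TRANSITION_ALT <- c(A = "G", G = "A", C = "T", T = "C")

#' Ground-truth table for a simulated sample pair
#'
#' @param genome the [genome()] the truth refers to.
#' @param crosslink_sites data frame with `position` (U positions) and
#'   `rate`: the extra U>C rate induced in the test arm only.
#' @param variant_sites data frame with `position`, `rate` and optionally
#'   `alt`: fixed minority variants substituted at the same rate in BOTH
#'   arms (default `alt` is the transition partner of the reference base,
#'   e.g. a U>C variant at a U position).
#' @param dms_unpaired optional data frame with `position` (A/C positions)
#'   and `rate`: elevated mismatch rate at unpaired positions in the DMS+
#'   arm.
#' @param base_error uniform sequencing/RT error rate applied everywhere in
#'   every arm, parameterized per substitution class: each base mutates to
#'   each of its three alternatives at `base_error` (total error
#'   `3 * base_error`), so the control-arm background rate of any single
#'   readout class (e.g. U>C) equals `base_error`. The default 0.001
#'   matches the per-mille background transition rates typical of deep
#'   RNA-seq with reverse transcription.
#' @return an object of class `TruthTable`.
#' @export
truth_table <- function(genome, crosslink_sites = NULL, variant_sites = NULL,
                        dms_unpaired = NULL, base_error = 0.001) {
  stopifnot(inherits(genome, "Genome"), base_error >= 0, base_error <= 1)
  gb <- genome_bases(genome)
  chk <- function(df, allowed, what) {
    if (is.null(df) || !nrow(df)) return(NULL)
    stopifnot(all(c("position", "rate") %in% names(df)))
    if (any(df$rate < 0 | df$rate > 1)) stop("rates must be in [0,1]")
    if (any(df$position < 1L | df$position > genome_length(genome)))
      stop(sprintf("%s position outside genome", what))
    if (!is.null(allowed) && !all(gb[df$position] %in% allowed))
      stop(sprintf("%s must lie on %s positions", what,
                   paste(allowed, collapse = "/")))
    df
  }
  crosslink_sites <- chk(crosslink_sites, "T", "crosslink sites")
  variant_sites <- chk(variant_sites, NULL, "variant sites")
  dms_unpaired <- chk(dms_unpaired, c("A", "C"), "DMS sites")
  if (!is.null(variant_sites) && is.null(variant_sites$alt))
    variant_sites$alt <- unname(TRANSITION_ALT[gb[variant_sites$position]])
  structure(list(genome_id = genome$id, crosslink_sites = crosslink_sites,
                 variant_sites = variant_sites, dms_unpaired = dms_unpaired,
                 base_error = base_error),
            class = "TruthTable")
}

#' @export
print.TruthTable <- function(x, ...) {
  n <- function(df) if (is.null(df)) 0L else nrow(df)
  cat(sprintf("TruthTable '%s': %d crosslink, %d variant, %d DMS sites; base error %g\n",
              x$genome_id, n(x$crosslink_sites), n(x$variant_sites),
              n(x$dms_unpaired), x$base_error))
  invisible(x)
}

# Draw reads with uniform starts and apply per-base substitutions.
# site_events: data.frame(position, rate, alt) with alt = NA meaning a
# uniformly chosen non-reference base per event. Site substitutions are
# applied after uniform errors (and therefore override them).
sim_reads_core <- function(genome, site_events, base_error, depth, read_len,
                           reverse_frac = 0) {
  L <- genome_length(genome)
  if (read_len > L) stop("read_len exceeds genome length")
  gb <- genome_bases(genome)
  n_reads <- max(1L, as.integer(round(depth * L / read_len)))
  starts <- sample.int(L - read_len + 1L, n_reads, replace = TRUE)
  seqs <- substring(genome$seq, starts, starts + read_len - 1L)
  others <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                  G = c("A", "C", "T"), T = c("A", "C", "G"))
  ev_read <- integer(0); ev_off <- integer(0); ev_base <- character(0)
  if (base_error > 0) {
    # base_error is the per-substitution-class rate: each base mutates to
    # each of its three alternatives at base_error, so any single readout
    # class (e.g. the control U>C background) sits at base_error exactly
    total <- as.numeric(n_reads) * read_len
    n_err <- stats::rbinom(1L, as.integer(total), min(1, 3 * base_error))
    if (n_err > 0L) {
      idx <- sample.int(as.integer(total), n_err)
      ri <- (idx - 1L) %/% read_len + 1L
      off <- (idx - 1L) %% read_len + 1L
      ref <- gb[starts[ri] + off - 1L]
      pick <- sample.int(3L, n_err, replace = TRUE)
      ev_read <- ri; ev_off <- off
      ev_base <- others[cbind(match(ref, rownames(others)), pick)]
    }
  }
  if (!is.null(site_events) && nrow(site_events)) {
    ord <- order(starts)
    sorted_starts <- starts[ord]
    for (s in seq_len(nrow(site_events))) {
      p <- site_events$position[s]
      r <- site_events$rate[s]
      if (r <= 0) next
      lo <- findInterval(p - read_len, sorted_starts) + 1L
      hi <- findInterval(p, sorted_starts)
      m <- hi - lo + 1L
      if (m <= 0L) next
      k <- stats::rbinom(1L, m, r)
      if (k == 0L) next
      hit <- ord[if (m == 1L) rep(lo, k) else (lo:hi)[sample.int(m, k)]]
      alt <- site_events$alt[s]
      bases <- if (is.na(alt)) {
        others[cbind(rep(match(gb[p], rownames(others)), k),
                     sample.int(3L, k, replace = TRUE))]
      } else rep(alt, k)
      ev_read <- c(ev_read, hit)
      ev_off <- c(ev_off, p - starts[hit] + 1L)
      ev_base <- c(ev_base, bases)
    }
  }
  if (length(ev_read)) {
    for (e in seq_along(ev_read)) {
      i <- ev_read[e]
      substr(seqs[i], ev_off[e], ev_off[e]) <- ev_base[e]
    }
  }
  flags <- rep(0L, n_reads)
  if (reverse_frac > 0)
    flags[stats::runif(n_reads) < reverse_frac] <- 16L
  list(starts = starts, seqs = seqs, flags = flags, read_len = read_len)
}

emit_reads <- function(rd, genome, emit, path) {
  ids <- sprintf("read_%07d", seq_along(rd$starts))
  qual <- strrep("F", rd$read_len)  # constant Q37, Phred+33
  if (emit == "sam") {
    lines <- c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", genome$id, genome_length(genome)),
               sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                       ids, rd$flags, genome$id, rd$starts, rd$read_len,
                       rd$seqs, qual))
  } else {
    lines <- as.vector(rbind(paste0("@", ids), rd$seqs, "+", qual))
  }
  writeLines(lines, path)
  invisible(path)
}

sidecar <- function(path, params) {
  jsonlite::write_json(params, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
}

#' Simulate a crosslink-profiling read set (one arm of a pair)
#'
#' Reads are drawn with uniform start positions at a mean coverage of
#' `depth`. Every covered base mutates independently at the truth table's
#' `base_error`; additionally, in the `test` arm each crosslink site's U>C
#' rate (times `dose_multiplier`) is applied, and fixed minority variants
#' are applied in BOTH arms. SAM emission writes perfect full-length-match
#' records (`<read_len>M`); FASTQ emission assigns constant Q37.
#'
#' @param genome a [genome()].
#' @param truth a [truth_table()] for that genome.
#' @param arm `"test"` (4SU+/UV+ or DMS+) or `"control"` (4SU+/UV-).
#' @param depth mean coverage (> 0).
#' @param path output file.
#' @param read_len read length in nt (default 150).
#' @param emit `"sam"` or `"fastq"`.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param dose_multiplier scalar applied to crosslink rates, emulating 4SU
#'   dose/incubation-time series (default 1).
#' @param reverse_frac fraction of reads flagged reverse-strand (SEQ stays
#'   reference-oriented; default 0).
#' @return invisibly, a list with `path`, `truth` and the generation
#'   parameters (also echoed to a JSON sidecar at `<path>.json`).
#' @export
simulate_mutprofile_reads <- function(genome, truth, arm = c("test", "control"),
                                      depth, path, read_len = 150L,
                                      emit = c("sam", "fastq"), seed = 1L,
                                      dose_multiplier = 1,
                                      reverse_frac = 0) {
  arm <- match.arg(arm)
  emit <- match.arg(emit)
  stopifnot(inherits(genome, "Genome"), inherits(truth, "TruthTable"),
            truth$genome_id == genome$id, depth > 0)
  set.seed(seed)
  ev <- NULL
  if (arm == "test" && !is.null(truth$crosslink_sites))
    ev <- data.frame(position = truth$crosslink_sites$position,
                     rate = pmin(1, truth$crosslink_sites$rate * dose_multiplier),
                     alt = "C")
  if (!is.null(truth$variant_sites))
    ev <- rbind(ev, data.frame(position = truth$variant_sites$position,
                               rate = truth$variant_sites$rate,
                               alt = truth$variant_sites$alt))
  rd <- sim_reads_core(genome, ev, truth$base_error, depth, read_len,
                       reverse_frac)
  emit_reads(rd, genome, emit, path)
  params <- list(kind = "mutprofile", arm = arm, depth = depth,
                 read_len = read_len, emit = emit, seed = seed,
                 dose_multiplier = dose_multiplier,
                 reverse_frac = reverse_frac, base_error = truth$base_error,
                 genome_id = genome$id, n_reads = length(rd$starts))
  sidecar(path, params)
  invisible(list(path = path, truth = truth, params = params))
}

#' Simulate a DMS structure-probing read set (one arm of a pair)
#'
#' In the `test` (DMS+) arm, A/C positions that are unpaired in `structure`
#' mutate at `unpaired_rate` and paired A/C positions at `paired_rate`, each
#' event substituting a uniformly chosen non-reference base; G/U positions
#' receive no DMS mutations. The `control` (DMS-) arm carries `base_error`
#' only, as does every position in both arms.
#'
#' @param genome a [genome()].
#' @param structure a `StructureModel` of the same length.
#' @param unpaired_rate,paired_rate DMS mutation rates with
#'   `unpaired_rate > paired_rate >= 0`.
#' @param depth mean coverage.
#' @param path output file.
#' @param arm `"test"` or `"control"`.
#' @param base_error uniform per-base error rate (default 0.001).
#' @param read_len,emit,seed as in [simulate_mutprofile_reads()].
#' @return invisibly, list with `path`, `truth` (data frame of A/C positions
#'   with their pairing status and applied rate) and parameters.
#' @export
simulate_dms_reads <- function(genome, structure, unpaired_rate, paired_rate,
                               depth, path, arm = c("test", "control"),
                               base_error = 0.001, read_len = 150L,
                               emit = c("sam", "fastq"), seed = 1L) {
  arm <- match.arg(arm)
  emit <- match.arg(emit)
  stopifnot(inherits(genome, "Genome"), inherits(structure, "StructureModel"),
            length(structure$pair) == genome_length(genome),
            unpaired_rate > paired_rate, paired_rate >= 0)
  set.seed(seed)
  gb <- genome_bases(genome)
  ac <- which(gb %in% c("A", "C"))
  unpaired <- structure$pair[ac] == 0L
  truth <- data.frame(position = ac, unpaired = unpaired,
                      rate = ifelse(unpaired, unpaired_rate, paired_rate))
  ev <- if (arm == "test")
    data.frame(position = truth$position, rate = truth$rate, alt = NA_character_)
  else NULL
  rd <- sim_reads_core(genome, ev, base_error, depth, read_len)
  emit_reads(rd, genome, emit, path)
  params <- list(kind = "dms", arm = arm, depth = depth, read_len = read_len,
                 emit = emit, seed = seed, unpaired_rate = unpaired_rate,
                 paired_rate = paired_rate, base_error = base_error,
                 genome_id = genome$id, n_reads = length(rd$starts))
  sidecar(path, params)
  invisible(list(path = path, truth = truth, params = params))
}

#' Write a truth table's site lists as TSV
#' @param truth a [truth_table()].
#' @param path output file.
#' @export
write_truth_table <- function(truth, path) {
  stopifnot(inherits(truth, "TruthTable"))
  rows <- list()
  if (!is.null(truth$crosslink_sites))
    rows$crosslink <- data.frame(kind = "crosslink",
                                 position = truth$crosslink_sites$position,
                                 rate = truth$crosslink_sites$rate)
  if (!is.null(truth$variant_sites))
    rows$variant <- data.frame(kind = "variant",
                               position = truth$variant_sites$position,
                               rate = truth$variant_sites$rate)
  if (!is.null(truth$dms_unpaired))
    rows$dms <- data.frame(kind = "dms_unpaired",
                           position = truth$dms_unpaired$position,
                           rate = truth$dms_unpaired$rate)
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(kind = character(0),
                                    position = integer(0), rate = numeric(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
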