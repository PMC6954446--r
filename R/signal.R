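#' @title Mutational signal maps
#' @description Turns paired test/control rate profiles into fold-change
#'   signal maps (the vPAR-CL / DMS-MaPseq signal), with coverage masking,
#'   percentile background filtering against the untreated control, replicate
#'   consensus, and significance-based site selection. Fold change rather
#'   than the raw transition rate is used throughout so that fixed minority
#'   variants present in both arms cancel out.
#' @name mutsignal
NULL

#' Mask low-coverage positions of a rate profile
#'
#' Positions with coverage strictly below `min_cov` are set absent (`NA`);
#' all others are unchanged. The default of 10,000 reads reflects the depth
#' needed to resolve per-mille transition rates.
#'
#' @param profile a `RateProfile`.
#' @param min_cov minimum coverage (default 10000).
#' @return the masked `RateProfile` (`coverage_ok` updated).
#' @export
apply_coverage_mask <- function(profile, min_cov = 10000L) {
  stopifnot(inherits(profile, "RateProfile"))
  low <- profile$coverage < min_cov
  profile$rate[low] <- NA_real_
  profile$coverage_ok <- profile$coverage_ok & !low
  profile
}

new_signal_profile <- function(genome_id, event, signal, test_rate,
                               control_rate, passed_background = NULL) {
  if (is.null(passed_background)) passed_background <- !is.na(signal)
  structure(list(genome_id = genome_id, event = event, signal = signal,
                 test_rate = test_rate, control_rate = control_rate,
                 passed_background = passed_background),
            class = "SignalProfile")
}

#' @export
print.SignalProfile <- function(x, ...) {
  cat(sprintf("SignalProfile '%s' [%s]: %d positions with signal, %d passing background\n",
              x$genome_id, x$event, sum(!is.na(x$signal)),
              sum(x$passed_background & !is.na(x$signal))))
  invisible(x)
}

#' Fold-change signal between a treated sample and its matched control
#'
#' `signal = test_rate / max(control_rate, 1/control_coverage)`. The floor of
#' one read in the control keeps the fold change finite and
#' coverage-calibrated when the control observed zero events. The signal is
#' absent wherever either input is absent.
#'
#' @param test,control `RateProfile`s of the same genome and event class
#'   (e.g. 4SU+/UV+ vs 4SU+/UV-, or DMS+ vs DMS-).
#' @return a `SignalProfile` retaining `test_rate` and `control_rate` for
#'   audit; `passed_background` starts as "signal present" and is refined by
#'   [filter_background()].
#' @export
fold_change <- function(test, control) {
  stopifnot(inherits(test, "RateProfile"), inherits(control, "RateProfile"))
  if (test$genome_id != control$genome_id)
    stop("test and control profiles are for different genomes")
  if (test$event != control$event)
    stop(sprintf("event class mismatch: '%s' vs '%s'", test$event, control$event))
  floor <- ifelse(control$coverage > 0L, 1 / control$coverage, NA_real_)
  denom <- pmax(control$rate, floor)
  signal <- test$rate / denom
  new_signal_profile(test$genome_id, test$event, signal,
                     test$rate, control$rate)
}

#' Background threshold from an untreated control profile
#'
#' The nearest-rank percentile separating the highest `top_frac` of control
#' rates: the value at ascending rank `ceiling((1 - top_frac) * n)` among the
#' `n` present control rates. Treated-sample positions below this value are
#' indistinguishable from background fluctuation.
#'
#' @param control a `RateProfile` (typically coverage-masked first).
#' @param top_frac background tail fraction (default 0.05, the highest 5%).
#' @return the threshold rate (scalar).
#' @export
background_threshold <- function(control, top_frac = 0.05) {
  stopifnot(inherits(control, "RateProfile"),
            top_frac > 0, top_frac < 1)
  rates <- control$rate[!is.na(control$rate)]
  n <- length(rates)
  if (n == 0L) stop("control profile has no present positions")
  sort(rates)[ceiling((1 - top_frac) * n)]
}

#' Flag signal positions against a background threshold
#'
#' A position passes when its treated-sample rate is at or above the
#' threshold (positions "below" the threshold are removed, so the boundary is
#' kept). Signals are retained but flagged; downstream site calling uses only
#' passing positions.
#'
#' @param signal a `SignalProfile`.
#' @param threshold rate threshold from [background_threshold()] of the
#'   paired control.
#' @return the `SignalProfile` with `passed_background` updated.
#' @export
filter_background <- function(signal, threshold) {
  stopifnot(inherits(signal, "SignalProfile"), is.numeric(threshold))
  signal$passed_background <- !is.na(signal$signal) &
    !is.na(signal$test_rate) & signal$test_rate >= threshold
  signal
}

#' Replicate consensus of background-filtered signals
#'
#' Per position, the passing signal of each replicate is stored; a position
#' is `consistent` when it passed the background filter in every replicate,
#' and the mean is taken over the replicates where a passing signal is
#' present (vacant positions have no mean).
#'
#' @param signals list of two or more `SignalProfile`s of the same genome,
#'   each already flagged with its own control-derived threshold.
#' @return a `ConsensusSignal` with matrix `signals`
#'   (positions x replicates, background-passing values only),
#'   `mean_signal` (mean over passing replicates), `n_present`,
#'   `consistent`, and `mean_all`: the background-agnostic consensus (mean
#'   over all coverage-masked replicate signals), which genome-wide
#'   significance tiers are computed against so that the mean/sd reflect
#'   the whole analyzable genome rather than the background-passing subset.
#' @export
combine_replicates <- function(signals) {
  stopifnot(is.list(signals), length(signals) >= 2L)
  gid <- unique(vapply(signals, function(s) s$genome_id, character(1)))
  if (length(gid) != 1L) stop("replicates are for different genomes")
  L <- length(signals[[1]]$signal)
  raw <- vapply(signals, function(s) {
    stopifnot(length(s$signal) == L)
    s$signal
  }, numeric(L))
  mat <- vapply(signals, function(s)
    ifelse(s$passed_background, s$signal, NA_real_), numeric(L))
  n_present <- rowSums(!is.na(mat))
  mean_signal <- ifelse(n_present > 0, rowMeans(mat, na.rm = TRUE), NA_real_)
  n_raw <- rowSums(!is.na(raw))
  mean_all <- ifelse(n_raw > 0, rowMeans(raw, na.rm = TRUE), NA_real_)
  structure(list(genome_id = gid, signals = mat, mean_signal = mean_signal,
                 mean_all = mean_all, n_present = n_present,
                 consistent = n_present == length(signals)),
            class = "ConsensusSignal")
}

#' @export
print.ConsensusSignal <- function(x, ...) {
  cat(sprintf("ConsensusSignal '%s': %d replicates, %d consistent positions\n",
              x$genome_id, ncol(x$signals), sum(x$consistent)))
  invisible(x)
}

#' Positions exceeding the genome-wide mean by k standard deviations
#'
#' Mean and standard deviation are computed over all present values of the
#' supplied vector (i.e. the coverage-masked signals of one genome, before
#' background filtering); selected positions satisfy
#' `value > mean + k * sd`.
#'
#' @param values per-position numeric vector (NA = absent), e.g.
#'   `consensus$mean_signal` or a `SignalProfile`'s `signal`.
#' @param k sigma multiplier (the significance tiers are k = 1 and k = 2).
#' @return ascending integer positions.
#' @export
sigma_sites <- function(values, k = 2) {
  vals <- values[!is.na(values)]
  if (length(vals) < 2L) stop("need at least 2 present values")
  cutoff <- mean(vals) + k * stats::sd(vals)
  which(!is.na(values) & values > cutoff)
}

#' Highest-signal sites from a replicate consensus
#'
#' Selects the `n` positions with the highest mean signal, optionally
#' restricted to consistent positions; ties are broken by ascending genomic
#' position.
#'
#' @param consensus a `ConsensusSignal`.
#' @param n number of sites.
#' @param require_consistent restrict to positions passing the background
#'   filter in every replicate (default `TRUE`).
#' @return integer positions ordered by decreasing mean signal; if fewer than
#'   `n` candidates exist, all are returned with a warning.
#' @export
top_sites <- function(consensus, n, require_consistent = TRUE) {
  stopifnot(inherits(consensus, "ConsensusSignal"), n >= 1L)
  cand <- which(!is.na(consensus$mean_signal) &
                  (!require_consistent | consensus$consistent))
  if (length(cand) < n) {
    warning(sprintf("only %d candidate sites available (requested %d)",
                    length(cand), n))
    n <- length(cand)
  }
  ord <- cand[order(-consensus$mean_signal[cand], cand)]
  ord[seq_len(n)]
}

#' Pearson correlation between two replicate signal profiles
#'
#' Computed over positions where both replicates have a signal. Undefined
#' (returned as `NA`) when either vector has zero variance.
#'
#' @param a,b `SignalProfile`s of the same genome.
#' @return Pearson r, or `NA`.
#' @export
replicate_correlation <- function(a, b) {
  stopifnot(inherits(a, "SignalProfile"), inherits(b, "SignalProfile"),
            a$genome_id == b$genome_id)
  joint <- !is.na(a$signal) & !is.na(b$signal)
  if (sum(joint) < 3L) stop("need at least 3 jointly present positions")
  x <- a$signal[joint]
  y <- b$signal[joint]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Call significant consistent sites from a replicate consensus
#'
#' The default calling rule: a site must pass the background filter in
#' every replicate (consistent) and its mean signal must exceed the
#' genome-wide mean of the consensus signal by more than `k` standard
#' deviations. Both-arm minority variants have fold change near 1 and are
#' thereby excluded even though their raw rates pass the background filter.
#'
#' @param consensus a `ConsensusSignal`.
#' @param k sigma multiplier (default 1, the lowest significance tier).
#' @return ascending integer positions.
#' @export
call_sites <- function(consensus, k = 1) {
  stopifnot(inherits(consensus, "ConsensusSignal"))
  sig <- sigma_sites(consensus$mean_all, k)
  sig[consensus$consistent[sig]]
}

#' Write a signal table as TSV
#'
#' Columns: position, ref_base, test_rate, control_rate, signal,
#' passed_background.
#'
#' @param signal a `SignalProfile`.
#' @param genome the matching [genome()].
#' @param path output file.
#' @export
write_signal_table <- function(signal, genome, path) {
  stopifnot(inherits(signal, "SignalProfile"), signal$genome_id == genome$id)
  df <- data.frame(position = seq_along(signal$signal),
                   ref_base = genome_bases(genome),
                   test_rate = signal$test_rate,
                   control_rate = signal$control_rate,
                   signal = signal$signal,
                   passed_background = signal$passed_background)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
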