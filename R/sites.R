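#' @title Site-level structural and clustering analyses
#' @description Classifies called crosslink sites by secondary-structure
#'   context, tests enrichment of sites in double-stranded regions with a
#'   goodness-of-fit chi-square, and quantifies site clustering via the mean
#'   adjacent-site spacing compared against analytic and Monte-Carlo
#'   random-uridine nulls.
#' @name sites
NULL

#' Construct a site set
#'
#' @param genome_id reference identifier.
#' @param positions ascending unique 1-based positions.
#' @param signal optional per-site signal values.
#' @param sigma_level optional per-site significance tier.
#' @param genome optional [genome()]; when given, positions are validated to
#'   lie within it, and `u_only = TRUE` additionally requires U positions.
#' @param u_only require all sites to be uridine positions (crosslink sets).
#' @return an object of class `SiteSet` (a data frame with attributes).
#' @export
site_set <- function(genome_id, positions, signal = NULL, sigma_level = NULL,
                     genome = NULL, u_only = FALSE) {
  positions <- as.integer(positions)
  if (length(positions) && any(diff(positions) <= 0L))
    stop("site positions must be strictly ascending and unique")
  if (!is.null(genome)) {
    if (length(positions) && any(positions < 1L | positions > genome_length(genome)))
      stop("site position outside genome")
    if (u_only && length(positions) &&
        !all(genome_bases(genome)[positions] == "T"))
      stop("all sites must be uridine (T) positions")
  }
  df <- data.frame(position = positions)
  if (!is.null(signal)) df$signal <- signal
  if (!is.null(sigma_level)) df$sigma_level <- sigma_level
  structure(df, genome_id = genome_id, class = c("SiteSet", "data.frame"))
}

#' Structural context of each site
#'
#' Labels each site `ds` when it is base-paired in the structure,
#' `ss_adjacent` when unpaired but within `adjacency` nucleotides of a
#' paired position (window clipped at the genome ends), and `ss` otherwise.
#' With `adjacency = 0`, `ss_adjacent` collapses into `ss`.
#'
#' @param sites a [site_set()].
#' @param structure a `StructureModel` of the same genome.
#' @param adjacency neighbourhood radius in nt (default 1).
#' @return character vector of labels, one per site.
#' @export
classify_site_context <- function(sites, structure, adjacency = 1L) {
  stopifnot(inherits(sites, "SiteSet"), inherits(structure, "StructureModel"))
  n <- length(structure$pair)
  pos <- sites$position
  if (length(pos) && any(pos < 1L | pos > n))
    stop("site position outside structure")
  vapply(pos, function(p) {
    if (structure$pair[p] != 0L) return("ds")
    lo <- max(1L, p - adjacency)
    hi <- min(n, p + adjacency)
    if (any(structure$pair[lo:hi] != 0L)) "ss_adjacent" else "ss"
  }, character(1))
}

#' Chi-square enrichment of sites in double-stranded regions
#'
#' One-degree-of-freedom goodness-of-fit chi-square (no continuity
#' correction) of the observed (ds, non-ds) site split against the expected
#' split under the genome-wide double-stranded fraction.
#'
#' @param n_ds number of sites in double-stranded regions.
#' @param n_total total number of sites.
#' @param expected_ds_frac genome-wide double-stranded fraction, in (0, 1).
#' @return list with `statistic` (chi-square) and `p.value` (upper tail of
#'   chi-square with 1 df). Warns when an expected cell is below 1.
#' @export
ds_enrichment_chisq <- function(n_ds, n_total, expected_ds_frac) {
  stopifnot(n_ds >= 0, n_total >= n_ds,
            expected_ds_frac > 0, expected_ds_frac < 1)
  expected <- n_total * c(expected_ds_frac, 1 - expected_ds_frac)
  if (any(expected < 1)) warning("expected cell count below 1")
  observed <- c(n_ds, n_total - n_ds)
  chi2 <- sum((observed - expected)^2 / expected)
  list(statistic = chi2,
       p.value = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Mean distance between adjacent sites
#'
#' The average of consecutive-position differences over the sorted sites; no
#' wraparound at the genome ends.
#'
#' @param sites a [site_set()] or an integer position vector with >= 2
#'   entries.
#' @return mean spacing in nucleotides.
#' @export
adjacent_spacing <- function(sites) {
  pos <- if (inherits(sites, "SiteSet")) sites$position else as.integer(sites)
  if (length(pos) < 2L) stop("need at least 2 sites")
  mean(diff(sort(pos)))
}

#' Null expectation for the adjacent-site spacing
#'
#' `analytic` mode returns `genome_len / n_sites`, the expected spacing of
#' `n_sites` random positions on a genome of `genome_len` nucleotides.
#' `monte_carlo` mode draws `n_sites` positions without replacement from the
#' supplied uridine positions `reps` times and averages the observed
#' adjacent spacing; it requires `uridine_positions` and is seeded for
#' reproducibility.
#'
#' @param genome_len genome length in nt.
#' @param n_sites number of sites (>= 1; >= 2 for `monte_carlo`).
#' @param mode `"analytic"` or `"monte_carlo"`.
#' @param uridine_positions candidate positions for the Monte-Carlo draw.
#' @param reps Monte-Carlo replicates (default 1000).
#' @param seed optional integer seed.
#' @return expected mean spacing in nucleotides.
#' @export
null_spacing <- function(genome_len, n_sites,
                         mode = c("analytic", "monte_carlo"),
                         uridine_positions = NULL, reps = 1000L,
                         seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_sites >= 1L, genome_len >= 1)
  if (mode == "analytic") return(genome_len / n_sites)
  if (is.null(uridine_positions))
    stop("monte_carlo mode requires uridine_positions")
  if (n_sites < 2L) stop("monte_carlo mode needs n_sites >= 2")
  if (n_sites > length(uridine_positions))
    stop("n_sites exceeds the number of candidate uridine positions")
  if (!is.null(seed)) set.seed(seed)
  mean(vapply(seq_len(reps), function(r)
    adjacent_spacing(sample(uridine_positions, n_sites)), numeric(1)))
}

#' Write a site set as TSV
#' @param sites a [site_set()].
#' @param path output file.
#' @export
write_site_table <- function(sites, path) {
  stopifnot(inherits(sites, "SiteSet"))
  utils::write.table(as.data.frame(sites), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a site set as BED
#'
#' BED intervals are 0-based half-open, so chromStart is the 1-based site
#' position minus one.
#'
#' @param sites a [site_set()].
#' @param path output file.
#' @export
write_site_bed <- function(sites, path) {
  stopifnot(inherits(sites, "SiteSet"))
  gid <- attr(sites, "genome_id")
  score <- if (!is.null(sites$signal)) sites$signal else rep(0, nrow(sites))
  df <- data.frame(chrom = rep(gid, nrow(sites)),
                   chromStart = sites$position - 1L,
                   chromEnd = sites$position,
                   name = paste0("U", sites$position),
                   score = score)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
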