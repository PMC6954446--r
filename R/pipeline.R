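#' @title End-to-end pipeline runner
#' @description Orchestrates the stages (optional simulation, pileup,
#'   signal maps, replicate consensus, site calling, clustering and
#'   structure metrics) from a single declarative configuration, writing TSV
#'   tables and a JSON run report in which every reported number is
#'   traceable to a table the run produced. Fixed seeds make re-runs
#'   byte-identical.
#' @name pipeline
NULL

pipeline_defaults <- function() {
  list(min_cov = 10000L, top_frac = 0.05, sigma_levels = c(1, 2),
       calling_sigma = 1, constraint_rule = list(type = "sigma", k = 2),
       engine = list(temperature = 310.15, max_loop = 30),
       null_reps = 1000L, seed = 1L)
}

#' Validate a pipeline run configuration
#'
#' Fills in defaults (`min_cov` 10000, `top_frac` 0.05, sigma levels 1 and 2,
#' folding-engine provenance parameters 310.15 K and maximum loop 30) and
#' checks that every test sample in the manifest has a matched control with
#' the same replicate label; configuration errors are raised before any
#' compute.
#'
#' @param config list, or path to a JSON file with the same fields:
#'   `genome` (FASTA path), `samples` (data frame / records with `file`,
#'   `arm` in test/control, `replicate`), `out_dir`, optional `simulate`
#'   block, optional `structures` (`unconstrained`/`constrained` CT or
#'   dot-bracket paths), plus any defaults to override.
#' @return the completed configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  cfg <- utils::modifyList(pipeline_defaults(), config)
  if (is.null(cfg$out_dir)) stop("config$out_dir is required")
  if (is.null(cfg$simulate)) {
    if (is.null(cfg$genome)) stop("config$genome is required")
    if (is.null(cfg$samples)) stop("config$samples manifest is required")
    m <- as.data.frame(cfg$samples)
    if (!all(c("file", "arm", "replicate") %in% names(m)))
      stop("samples manifest needs columns file, arm, replicate")
    if (!all(m$arm %in% c("test", "control")))
      stop("sample arm must be 'test' or 'control'")
    tests <- m$replicate[m$arm == "test"]
    ctrls <- m$replicate[m$arm == "control"]
    missing <- setdiff(tests, ctrls)
    if (length(missing))
      stop(sprintf("test replicate(s) without matched control: %s",
                   paste(missing, collapse = ", ")))
    if (!length(tests)) stop("manifest contains no test samples")
    cfg$samples <- m
  }
  cfg
}

simulate_stage <- function(cfg) {
  sim <- utils::modifyList(
    list(genome_length = 3000L, n_crosslink_sites = 20L,
         crosslink_rate = 0.02, base_error = 0.001, depth = 20000,
         replicates = 3L, read_len = 150L, n_variant_sites = 2L,
         variant_positions = NULL, variant_rate = 0.05), cfg$simulate)
  g <- make_genome(sim$genome_length, seed = cfg$seed)
  set.seed(cfg$seed + 1L)
  # truth sites live in the reliably covered core: uniform read starts give
  # ramped coverage over the first/last read_len positions, which the 10k
  # mask removes (the real analyses likewise exclude the genome ends)
  upos <- uridine_positions(g)
  core <- upos[upos > sim$read_len &
                 upos <= sim$genome_length - sim$read_len]
  picks <- sample(core, sim$n_crosslink_sites + sim$n_variant_sites)
  cl <- sort(picks[seq_len(sim$n_crosslink_sites)])
  variants <- NULL
  if (is.null(sim$variant_positions) && sim$n_variant_sites > 0L)
    sim$variant_positions <-
      sort(picks[sim$n_crosslink_sites + seq_len(sim$n_variant_sites)])
  if (!is.null(sim$variant_positions))
    variants <- data.frame(position = sim$variant_positions,
                           rate = sim$variant_rate)
  crosslinks <- if (length(cl))
    data.frame(position = cl, rate = sim$crosslink_rate) else NULL
  truth <- truth_table(g, crosslink_sites = crosslinks,
    variant_sites = variants, base_error = sim$base_error)
  write_genome_fasta(g, file.path(cfg$out_dir, "genome.fasta"))
  write_truth_table(truth, file.path(cfg$out_dir, "truth.tsv"))
  files <- character(0); arms <- character(0); reps <- integer(0)
  for (r in seq_len(sim$replicates)) {
    for (arm in c("test", "control")) {
      f <- file.path(cfg$out_dir, sprintf("%s_rep%d.sam", arm, r))
      simulate_mutprofile_reads(g, truth, arm = arm, depth = sim$depth,
                                path = f, read_len = sim$read_len,
                                emit = "sam",
                                seed = cfg$seed + 10L * r + (arm == "test"))
      files <- c(files, f); arms <- c(arms, arm); reps <- c(reps, r)
    }
  }
  list(genome = g, truth = truth,
       samples = data.frame(file = files, arm = arms, replicate = reps))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> pileup -> signal maps -> background
#' filtering -> replicate consensus -> site calling -> clustering statistics
#' (-> structure metrics when structure files are supplied), writing per-
#' sample base-count and signal TSVs plus `report.json` under
#' `config$out_dir`.
#'
#' @param config see [validate_config()].
#' @return invisibly, the run report (also written as JSON): per-replicate
#'   background thresholds, the coverage mask, counts of consistent and
#'   sigma-tier sites, pairwise replicate correlations, spacing statistics
#'   with analytic and Monte-Carlo nulls, and (with structures) ds
#'   fractions, refolding difference and the ds-enrichment chi-square.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_seen <- character(0)
  note <- function(w) warnings_seen <<- c(warnings_seen, w)

  truth <- NULL
  if (!is.null(cfg$simulate)) {
    sim <- simulate_stage(cfg)
    g <- sim$genome
    truth <- sim$truth
    samples <- sim$samples
  } else {
    g <- read_genome_fasta(cfg$genome)[[1]]
    samples <- cfg$samples
  }

  # pileup + coverage-masked transition profiles per sample
  profiles <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    bct <- withCallingHandlers(
      build_base_counts(samples$file[i], g),
      warning = function(w) { note(conditionMessage(w))
        invokeRestart("muffleWarning") })
    write_base_counts(bct, g,
      file.path(cfg$out_dir, sprintf("counts_%s_rep%s.tsv",
                                     samples$arm[i], samples$replicate[i])))
    profiles[[i]] <- apply_coverage_mask(
      transition_profile(bct, g, "T", "C"), cfg$min_cov)
  }

  # per-replicate fold change against the matched control's threshold
  reps <- sort(unique(samples$replicate[samples$arm == "test"]))
  signals <- list()
  thresholds <- numeric(0)
  for (r in reps) {
    it <- which(samples$arm == "test" & samples$replicate == r)[1]
    ic <- which(samples$arm == "control" & samples$replicate == r)[1]
    thr <- background_threshold(profiles[[ic]], cfg$top_frac)
    sig <- filter_background(fold_change(profiles[[it]], profiles[[ic]]), thr)
    write_signal_table(sig, g,
      file.path(cfg$out_dir, sprintf("signal_rep%s.tsv", r)))
    signals[[as.character(r)]] <- sig
    thresholds[as.character(r)] <- thr
  }

  correlations <- list()
  if (length(signals) >= 2L) {
    for (a in seq_along(signals)) for (b in seq_along(signals)) {
      if (a < b)
        correlations[[sprintf("rep%s_vs_rep%s", names(signals)[a],
                              names(signals)[b])]] <-
          replicate_correlation(signals[[a]], signals[[b]])
    }
  }

  report <- list(
    version = 1L,
    parameters = list(min_cov = cfg$min_cov, top_frac = cfg$top_frac,
                      sigma_levels = cfg$sigma_levels,
                      constraint_rule = cfg$constraint_rule,
                      folding_engine = cfg$engine, seed = cfg$seed),
    genome = list(id = g$id, length = genome_length(g),
                  n_uridines = count_uridines(g)),
    background_thresholds = as.list(thresholds),
    replicate_correlations = correlations)

  if (length(signals) >= 2L) {
    consensus <- combine_replicates(unname(signals))
    sigma_counts <- list()
    spacing <- list()
    called <- list()
    for (k in cfg$sigma_levels) {
      sk <- sigma_sites(consensus$mean_all, k)
      sigma_counts[[sprintf("gt%gsigma", k)]] <- length(sk)
      called[[sprintf("gt%gsigma", k)]] <- sk
      if (length(sk) >= 2L) {
        spacing[[sprintf("gt%gsigma", k)]] <- list(
          n_sites = length(sk),
          observed = adjacent_spacing(sk),
          null_analytic = null_spacing(genome_length(g), length(sk)),
          null_monte_carlo = null_spacing(genome_length(g), length(sk),
            mode = "monte_carlo", uridine_positions = uridine_positions(g),
            reps = cfg$null_reps, seed = cfg$seed))
      }
    }
    consistent <- which(consensus$consistent)
    called_consistent <- call_sites(consensus, k = cfg$calling_sigma)
    report$site_counts <- c(list(consistent = length(consistent)),
                            sigma_counts,
                            list(called = length(called_consistent)))
    report$spacing <- spacing
    if (length(called_consistent)) {
      ss <- site_set(g$id, called_consistent,
                     signal = consensus$mean_signal[called_consistent],
                     genome = g)
      write_site_table(ss, file.path(cfg$out_dir, "called_sites.tsv"))
      write_site_bed(ss, file.path(cfg$out_dir, "called_sites.bed"))
    }
    if (!is.null(truth)) {
      truth_pos <- truth$crosslink_sites$position
      tp <- sum(called_consistent %in% truth_pos)
      report$truth_evaluation <- list(
        n_truth = length(truth_pos), n_called = length(called_consistent),
        recall = if (length(truth_pos)) tp / length(truth_pos) else NA,
        precision = if (length(called_consistent))
          tp / length(called_consistent) else NA)
    }

    # structure metrics against externally folded models, when provided
    if (!is.null(cfg$structures)) {
      sa <- parse_structure(cfg$structures$unconstrained)
      sb <- parse_structure(cfg$structures$constrained)
      dsf <- ds_fraction(sb)
      enrich <- NULL
      if (length(called_consistent)) {
        ss <- site_set(g$id, called_consistent)
        ctx <- classify_site_context(ss, sb)
        enrich <- withCallingHandlers(
          ds_enrichment_chisq(sum(ctx == "ds"), length(ctx), dsf),
          warning = function(w) { note(conditionMessage(w))
            invokeRestart("muffleWarning") })
        enrich <- c(list(n_ds = sum(ctx == "ds"), n_total = length(ctx)),
                    enrich)
      } else note("no called sites; ds enrichment skipped")
      report$structure <- list(
        ds_fraction_unconstrained = ds_fraction(sa),
        ds_fraction_constrained = dsf,
        refold_difference = refold_difference(sa, sb),
        ds_enrichment = enrich)
    }
  }

  report$warnings <- warnings_seen
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(report)
}
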