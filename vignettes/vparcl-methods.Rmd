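---
title: "Calling RNA-capsid crosslink sites and in-virion RNA structure from mutational profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling RNA-capsid crosslink sites and in-virion RNA structure from mutational profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement model

vPAR-CL (viral photoactivatable-ribonucleoside-enhanced crosslinking) reads
out RNA-capsid contacts inside purified virus particles: 4-thiouridine
incorporated into the encapsidated genome crosslinks to adjacent capsid
protein under 365 nm UV, and each crosslinked uridine leaves a
characteristic U>C transition in the sequenced library. DMS-MaPseq reads
out single-strandedness: dimethyl sulfate methylates unpaired A and C
bases, and a processive reverse transcriptase converts the methyl marks
into mismatches. Both assays therefore reduce to the same computational
object: a per-position substitution rate

$$ r_i = \frac{\text{non-reference (or specific alternative) reads at } i}
           {\text{coverage at } i} $$

measured in a treated sample and a matched untreated control, and compared
as a **fold change** $s_i = t_i / \max(c_i, 1/n_i)$, where $t_i$ and $c_i$
are the treated and control rates and $n_i$ is the control coverage. The
signal is the fold change, never the raw rate: a genuine low-frequency
sequence variant in the virus population (e.g. a fixed U>C minority
variant) elevates the raw rate identically in both arms and cancels in the
ratio, while a crosslink- or methylation-specific event elevates only the
treated arm.

## Pipeline stages and the parameters that matter

1. **Read preprocessing** (`preprocess_reads`): adapter trimming (exact
   match of `AGATCGGAAGAGC` plus terminal partial matches of at least 3
   bases; post-trim minimum length 40 nt), removal of the first 6 bases
   (random-primed bases from library construction), and discarding of
   reads with more than 4% of bases below Phred 20. The boundary is kept:
   exactly 4% passes. The chain is idempotent after one pass.
2. **Pileup** (`build_base_counts`): per-position counts of observed
   A/C/G/T/N over aligned match/mismatch columns; only primary alignments
   count; insertions, deletions, and clipped bases contribute nothing;
   read `N`s are tallied separately and excluded from coverage. No MAPQ or
   per-base quality threshold is applied at this stage — read-level
   filtering has already happened.
3. **Rate profiles** (`transition_profile`, `mismatch_profile`): U>C
   transition rates at genomic uridines (crosslink arm) or any-mismatch
   rates at A/C positions (DMS arm).
4. **Coverage mask** (`apply_coverage_mask`, default 10,000 reads):
   per-mille rate differences cannot be resolved below roughly 10k
   coverage, so lower-coverage positions are set absent. The mask is
   strict (`< 10000` removed).
5. **Fold change and background** (`fold_change`, `background_threshold`,
   `filter_background`): the background threshold is the nearest-rank
   upper 5th percentile of the present control rates — the value at
   ascending rank $\lceil 0.95\,n \rceil$. Treated positions whose rate is
   *below* it are flagged as indistinguishable from background; the
   boundary passes. Each replicate pair uses its own control-derived
   threshold. When the control observed zero events the denominator is
   floored at one read ($1/n_i$), keeping fold changes finite and
   coverage-calibrated.
6. **Replicate consensus and calling** (`combine_replicates`,
   `sigma_sites`, `call_sites`): a position is *consistent* when it passed
   the background filter in every replicate; the consensus signal is the
   mean over replicates with a passing signal. Significance tiers are
   genome-wide: a $>k\sigma$ site exceeds the mean of all present
   consensus signals by more than $k$ standard deviations (computed on
   coverage-masked signals *before* background filtering, which maximizes
   the sample for the mean/sd). The default calling rule is **consistent
   and $>1\sigma$**: consistency provides the replication stringency,
   while the $\sigma$ floor on the fold change is what excludes both-arm
   variants, whose raw rates pass every background filter but whose
   signal stays near 1. The $>2\sigma$ tier is reported as the "most
   significant" subset.
7. **Structure bridge** (`select_unpaired_constraints`,
   `write_constraint_file`, `parse_structure`, `ds_fraction`,
   `refold_difference`): the strongest single-strandedness signals become
   unpaired constraints for an external thermodynamic folding engine,
   interfaced purely through files (FASTA + CON out, CT or dot-bracket
   in). Two selection rules are provided because strong signals are
   described both ways in practice — $>2\sigma$ and top 5% — and they can
   disagree on real data; the rule used is recorded per run. The folding
   engine's provenance parameters (temperature 310.15 K, maximum loop 30)
   are carried in the configuration but thermodynamics is never
   re-implemented. Each RNA segment is folded separately; inter-segment
   pairing is out of scope.
8. **Site-level statistics** (`classify_site_context`,
   `ds_enrichment_chisq`, `adjacent_spacing`, `null_spacing`): sites are
   classified as `ds` (paired), `ss_adjacent` (unpaired within 1 nt of a
   paired position, window clipped at the ends) or `ss`. Enrichment of
   sites in double-stranded regions uses a 1-df goodness-of-fit
   chi-square without continuity correction — for example, 8 of 15 sites
   double-stranded against an expected fraction 0.60 gives 0.278 (0.3 at
   one decimal). Clustering is the mean adjacent-site distance, compared
   against an analytic null $L/n$ (45 sites on 1,400 nt: 31.11 nt) and a
   seeded Monte-Carlo null that samples $n$ positions without replacement
   from the actual uridine positions. No wraparound at the genome ends is
   assumed.

## The synthetic-data generator: what it emulates and what it does not

`make_genome`, `truth_table`, `simulate_mutprofile_reads` and
`simulate_dms_reads` generate paired test/control read sets with known
ground truth:

* uniform read starts at a configurable mean depth (default worlds use
  150-nt single-end reads at 20,000x, the regime the 10k mask assumes);
* a uniform sequencing/RT error applied everywhere in every arm.
  `base_error` is parameterized **per substitution class**: each base
  mutates to each of its three alternatives at `base_error`, so the
  control-arm background of any single readout class (e.g. U>C) equals
  `base_error` directly. The default 0.001 places the control background
  at 0.1%, the per-mille regime that deep RNA-seq with reverse
  transcription exhibits and that the background-threshold machinery is
  designed around;
* crosslink sites with an extra U>C rate in the test arm only (default
  world: 20 sites at 0.02); a dose multiplier emulates 4SU
  dose/incubation series as a scalar on the crosslink rates;
* fixed minority variants substituted at the same rate in *both* arms
  (default two sites at 0.05, transition substitution), which must never
  be called;
* for the DMS arm, elevated mismatch rates at unpaired A/C versus paired
  A/C positions; G/U positions never receive DMS events.

Truth sites are drawn from uridines at least one read length away from the
genome ends: uniform read starts give linearly ramped coverage there,
which the 10k mask removes — the real analyses likewise restrict to the
reliably covered core of each segment.

The generator does **not** model 3'/5' coverage bias, realistic quality
strings (constant Q37), indel errors, PCR duplicates, or the unexplained
global rate depression that UV-only controls can exhibit. A green
recovery test therefore establishes that the pipeline's statistics do what
they claim under a clean sampling model — not that the laboratory assay
is noise-free.

`toy_fold` is a deterministic maximum-base-pairing (Nussinov-style)
folder: Watson-Crick plus GU wobble pairs, nested structures only, minimum
hairpin loop of 3, honouring unpaired constraints, with a traceback that
scans from the 5' end and pairs each position with its smallest admissible
partner whenever an optimal structure allows. It exists so the
constraint-to-fold-to-metrics path is testable without the external
engine; it is not a thermodynamic prediction.

## Numerical choices and degenerate inputs

* Percentiles are nearest-rank, ascending, with no interpolation. With
  distinct rates this retains $\lceil 0.05\,n\rceil$ control positions at
  or above the threshold whenever $0.95\,n$ is not an integer; at exact
  multiples (e.g. $n = 100$) the nearest-rank value sits one rank lower
  and retains one extra position.
* Zero-variance t-test inputs: equal means give $t = 0,\ p = 1$; unequal
  means give infinite $t,\ p = 0$. Pearson correlation of a zero-variance
  vector is undefined and reported as absent.
* K-S p-values use the asymptotic Kolmogorov series with effective sample
  size $nm/(n+m)$.
* Chi-square enrichment warns when an expected cell falls below 1.
* Ties in top-site selection break by ascending genomic position.
* Coordinates are 1-based and fully closed throughout (SAM convention);
  BED export subtracts 1 for chromStart. Genomes are held in the DNA
  alphabet; folding treats T as U transparently.
* All stochastic steps (simulation, Monte-Carlo nulls) take explicit
  integer seeds; fixed seeds reproduce outputs byte-for-byte.

## Known limitations

* The real thermodynamic folding engine is external; only its file
  formats are supported here, and `toy_fold` maximizes pair count rather
  than free energy.
* No multiple-testing correction is applied; reported per-site p-values
  are uncorrected, matching raw $P < 0.05$ usage.
* Replicate correlation is plain Pearson over jointly present signals;
  fold-change ratios of small counts are heavy-tailed, so correlations
  computed this way are sensitive to a few extreme positions.
* The UV-only control's global rate depression is noted, not corrected
  for.

## A worked example

```{r, eval = FALSE}
library(vparcl)

d <- tempfile()
report <- run_pipeline(list(
  out_dir = d, seed = 1,
  simulate = list(genome_length = 3000, n_crosslink_sites = 20,
                  crosslink_rate = 0.02, base_error = 0.001,
                  depth = 20000, replicates = 3)))
report$truth_evaluation
report$site_counts
```

The same run is exercised (and its recovery asserted) by the package's
acceptance tests; see `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`.
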