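---
title: "Methods: differential methylation and DMR discovery with methdmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation and DMR discovery with methdmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdmr)
library(dplyr)
```

## Scope and model

`methdmr` analyses two-group Infinium HM450K-style DNA methylation cohorts
starting from a **normalized beta-value matrix** (per-probe methylation
fractions in [0, 1], one column per sample) with a parallel detection
p-value matrix, a probe manifest, and a sample sheet. Upstream
intensity-level processing (IDAT parsing, interplate normalization,
background subtraction) is out of scope: the pipeline assumes those steps
already happened. Downstream, it produces per-probe differential calls,
differentially methylated regions (DMRs), hotspot regions, genomic and
chromatin annotation, and candidate gene lists that integrate a reference
expression table.

The statistical model is the standard empirical-Bayes moderated t-test for
small-sample array studies. For probe $g$ with case/control means
$\bar\beta_{g1}, \bar\beta_{g0}$, pooled residual variance $s_g^2$ on
$d_g = n_{g1} + n_{g0} - 2$ degrees of freedom, the prior
$s_g^2 \sim s_0^2 \, d_0 / \chi^2_{d_0}$ is fitted by matching the first
two moments of $\log s_g^2$ to the marginal scaled-F distribution
(digamma/trigamma inversion), giving the posterior variance
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ and

$$ \tilde t_g = \frac{\bar\beta_{g1} - \bar\beta_{g0}}
   {\tilde s_g \sqrt{1/n_{g1} + 1/n_{g0}}}, \qquad
   \tilde t_g \sim t_{d_0 + d_g} \ \text{under } H_0 . $$

Two-sided p-values are BH-adjusted, and a probe is *called* differentially
methylated only under the dual gate **FDR < 0.05 and |Δβ| > 0.15** (both
strict). The Δβ gate is what makes the procedure conservative in practice:
at realistic array noise, few null probes ever reach a 0.15 beta
difference regardless of their p-value.

Assumptions worth stating plainly:

* within-group beta-values are treated as approximately normal with a
  common within-group variance per probe — adequate in the bulk of the
  (0, 1) range, least accurate near the boundaries;
* probes are tested independently (no spatial smoothing; regional
  structure is recovered afterwards by the window caller);
* moderation is done **on beta-values by default** because the call
  threshold is expressed in beta units. An M-value (logit) option exists
  (`use_m_values = TRUE`) for users who prefer variance-stabilized
  moderation; the delta gate stays on the beta scale either way.

## Quality control

Two rules, applied in this order by `mask_failed_values()` and
`filter_probes()`:

1. **value-level** — a beta-value whose detection p-value exceeds 0.01 is
   set to missing (that measurement never rose reliably above background);
2. **probe-level** — a probe is dropped when its post-masking missing
   fraction is *strictly greater* than 5% of the cohort, when it is
   SNP-flagged (common variant in the probe's last 5 bp or at the CpG
   site, precomputed in the manifest), or when it lies on chrX/chrY
   (mixed-sex cohorts).

The "detection p-value > 0.01" criterion appears both per value and per
probe in HM450K practice; we collapse the probe-level clause into the
missingness rule, since after per-sample masking a probe-level detection
criterion is only expressible through its missing fraction. Missingness is
computed jointly over all samples passed in (the whole cohort); analysts
who prefer per-cell-type missingness can simply filter each cell type's
columns separately. Filtering is idempotent, preserves manifest order, and
returns a removal ledger (`qc_ledger()`), with earlier rules taking
precedence so ledger counts sum exactly to the number of probes removed.

## The DMR caller

`find_windows()` scans called probes in manifest order and emits every
maximal run of ≥ 2 probes that share a direction and in which each
**adjacent pair** of member probes lies ≤ 1 kb apart. Three interpretation
choices define the caller:

* **The 1 kb rule constrains adjacent probes, not the total span.** Merged
  regions may (and do) exceed 1 kb — a hard span cap would contradict
  multi-kilobase merged DMRs, which regularly arise from chains of
  windows.
* **"Consecutive" is evaluated on the retained (post-QC) probe order.** An
  intervening retained probe that is *not* called breaks a run; probes
  removed by QC are invisible and do not. This is the literal reading of
  consecutive probes among those actually analysed.
* **Runs never cross chromosomes**, and hyper/hypo runs never mix.

`merge_windows()` merges same-direction windows that overlap, share
probes, or are book-ended within 1 kb of each other, recording for each
DMR the union of member probes, the mean member-probe Δβ, and `max_run`:
the longest *uninterrupted* run of called probes (windows joined only by a
book-end gap had a non-called probe or a super-threshold gap between them,
so their runs do not concatenate). `find_hotspots()` keeps DMRs with
`max_run ≥ 5` — regions dense enough in affected probes to serve as
candidate disease signatures. `intersect_dmr_sets()` declares a DMR
"common" between two cohorts (e.g., immature vs mature cell fractions)
when it overlaps a same-direction DMR of the other set by ≥ 1 bp.

Because a window formulation based on probe runs is one of several
readings of a "1 kb window" rule, raw *window* counts are not a stable
quantity across implementations; the merged DMR set is the comparison
surface this package standardises on.

## Annotation

Probes, windows, or DMRs are mapped onto genomic features with
`assign_feature()`: `promoter` (any overlap with TSS ± 1 kb, which wins
over gene body), `gene_body`, else `intergenic`, plus independent CpG
island and enhancer flags. All interval work inside the package is 1-based
inclusive; BED input/output is 0-based half-open and converted only in
`read_bed()`/`write_bed()`.

Promoter CpG-density classes follow the Weber-style criteria on 500-bp
windows sliding in 5-bp steps (plus a tail window so the 3' end is always
covered): **HCP** when any window reaches CpG observed/expected ≥ 0.75
*and* GC ≥ 0.55; **LCP** when no window reaches o/e ≥ 0.48; **ICP**
otherwise. Within a window, o/e = (#CpG × L)/(#C × #G) with overlapping
dinucleotide counts; N bases are excluded from all counts and from the
effective length. These statistics are reverse-complement symmetric, so
the class is strand-invariant.

Chromatin state is a pure peak-overlap classification
(`classify_chromatin_state()`): bivalent (H3K4me3 ∩ H3K27me3), a
single-mark state, or none. `category_distribution()` tabulates a focal
probe set against its background (e.g., chromatin states of probes in
hypermethylated CGI-associated DMRs against all array probes), returning
percentage vectors that always sum to 100. A DMR counts as CGI-associated
as soon as any member probe is CGI-flagged; no minimum overlap fraction is
imposed, since none is established for this rule.

## Expression integration

`classify_candidates()` crosses promoter-DMR overlap with reference
expression: genes expressed in the healthy reference (rpkm > 1) whose
promoter overlaps a **hyper**methylated DMR are *candidate repressed*;
genes repressed there (rpkm < 1) whose promoter overlaps a
**hypo**methylated DMR are *candidate expressed*. Genes exactly at the
threshold stay unclassified; a gene with several qualifying promoters is
counted once; ≥ 1 bp of promoter-DMR overlap suffices.
`cell_type_specific_candidates()` keeps a candidate only when *none* of
its supporting promoters overlaps a **same-direction** DMR in the other
cell type — specificity is judged at the promoter level and
direction-specifically, not by whole-DMR identity, because the biological
claim is about the promoter's methylation state in that cell subset.

`wgbs_concordance()` quantifies platform agreement as the squared Pearson
correlation between array beta-values and WGBS methylation fractions over
position-matched CpGs with ≥ 5-read coverage. `relative_expression()`
implements the efficiency-corrected qPCR ratio
$E_t^{-Ct_t} / \mathrm{geomean}_i(E_i^{-Ct_i})$ used to validate candidate
genes.

## The synthetic-data generator

The generator exists so that every pipeline stage can be exercised, and
its operating characteristics measured, without downloading cohort data.
`simulate_manifest()` lays out probes with log-normal spacing (median
500 bp, log-sd 1.2 — array probes cluster tightly in islands and spread
out elsewhere), short CGI runs covering ~31% of probes, ~5.5% SNP-flagged
probes and ~2.5% sex-chromosome probes (the approximate HM450K rates:
roughly 27k of 485k probes carry common-SNP flags, and X+Y carry ~11.6k).
`simulate_beta_cohort()` draws baselines from a near-0 / intermediate /
near-1 mixture (0.40/0.15/0.45 — the familiar bimodal array profile),
shifts case-group means by exactly the configured Δβ at implanted regions
(baselines there are drawn away from the boundary so the shift never
clips), adds noise **on the logit scale** scaled so its beta-scale SD
matches `noise_sd` (values stay strictly inside (0, 1), with no boundary
pile-up from hard clipping), and marks independent Bernoulli detection
failures with detection p > 0.01. Implanted regions are placed on runs of
consecutive probes whose internal gaps satisfy the region's `max_gap`, at
least one probe apart from each other; `undetectable = TRUE` forces at
least one internal gap > 1 kb, creating truth regions a 1 kb-gap caller
must split or drop — useful for specificity checks. Everything is a pure
function of the configuration and seed.

Default cohort size is 5 vs 5 samples (a typical sorted-cell HD cohort);
`noise_sd` defaults to 0.05 as a realistic array replicate SD — no
published per-probe variance exists for this setting, so this default is a
modelling choice, and the benchmark experiments in the acceptance checks
set it explicitly (0.02).

What the generator does *not* emulate — and therefore what passing
benchmarks cannot show about real data: Infinium type-I/type-II chemistry
bias, spatially correlated noise, batch/plate effects, cell-composition
drift between groups, and biologically clustered (rather than
uniformly-random) SNP and failure patterns. Recovery numbers from this
generator characterise the algorithm, not the platform.

## Numerical choices and degenerate inputs

* Trigamma inversion uses a Newton iteration started at $0.5 + 1/x$,
  converging to ~10 digits in a handful of steps; when the observed
  variance of $\log s^2$ does not exceed the chi-square contribution the
  prior degrees of freedom are reported as `Inf`.
* If every residual variance is identical (a measure-zero event under the
  model), `s0_sq` is reported as that common value rather than the
  bias-corrected moment estimate.
* A zero posterior variance with a nonzero effect cannot produce p = 0;
  such probes get the smallest representable positive p-value with a
  warning.
* `d0 = 0` reduces the moderated test exactly to the ordinary pooled
  t-test, which is both a limit-case guarantee and the hook for oracle
  testing.
* Probes with fewer than two usable values in either group are excluded
  as untestable and counted, never silently dropped.
* BH adjustment is the standard step-up rule; the test suite checks it
  against explicit enumeration.

## Benchmark scales

The property checks in the test suite run at fixed, deliberately modest
problem sizes chosen to give stable verdicts on one CPU: pooled-t
equivalence on 1,000 random probes (≤ 10⁻¹⁰ relative error), BH-FDR
against enumeration on 10,000 p-values, prior recovery on 10,000 probes
simulated from a scaled-F prior (d0 = 4, s0² = 0.01; tolerances ±25% and
±10%), DMR recovery and permutation-null experiments on 4,000-probe,
5 vs 5 cohorts with twenty implanted Δβ = 0.3 regions at noise_sd = 0.02
(10 seeds / 20 permutations), and the window caller against exhaustive
enumeration on the complete direction × gap grid up to 5 probes plus
4,000 seeded random configurations of 6–8 probes. `scripts/acceptance.R`
re-runs the same experiments from scratch and writes the measured
quantities as JSON.

## A small worked run

```{r example, message = FALSE}
cfg <- sim_config(
  n_probes = 2000, noise_sd = 0.02,
  dmr_spec = bind_rows(dmr_target("hyper", 5, 0.3),
                       dmr_target("hypo", 4, 0.3)),
  seed = 42
)
manifest <- simulate_manifest(cfg)
cohort <- simulate_beta_cohort(manifest, cfg)

dm <- cohort$beta |>
  mask_failed_values(cohort$detp) |>
  filter_probes(manifest) |>
  diff_methylation(cohort$samples, contrast = c("CML", "HD"),
                   manifest = manifest)
glance(dm)

res <- call_dmrs(dm, manifest)
res$dmrs
evaluate_dmr_recovery(res$dmrs, cohort$truth)
```

## Known limitations

* No paired designs, covariates, surrogate-variable correction, or
  cell-composition deconvolution; the design matrix is strictly
  two-group.
* No smoothing-based DMR methods and no DMR-wise significance values: a
  DMR is a deterministic consequence of the per-probe calls.
* The window caller's probe-run formulation makes raw window counts
  implementation-specific (see above); compare DMR sets, not window
  tallies.
* Promoter CpG-density classification needs promoter sequence; when only
  coordinates are available the class is simply not assigned.
* The qPCR helper implements the normalization arithmetic only; melt-curve
  QC and efficiency estimation are upstream of it.
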