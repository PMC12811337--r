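---
title: "Filtering proximity-labeling proteomes against promiscuous-ligase controls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filtering proximity-labeling proteomes against promiscuous-ligase controls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

In a proximity-labeling experiment a bait protein is fused to a promiscuous
biotin ligase (e.g. TurboID). The ligase biotinylates surface lysines of
proteins within roughly 10–30 nm of the bait — the bait itself (*cis*
labeling) and its neighbors (*trans* labeling). Biotinylated protein is
captured on streptavidin beads, digested, and quantified by
data-independent-acquisition mass spectrometry, yielding a protein × run
intensity table.

Two kinds of false positives contaminate such a table:

1. **Sticky background** — non-biotinylated protein that adheres to the
   beads. It is partly random, so it is addressed by statistics against a
   *no-ligase negative control* (a wild-type strain, here called N2).
2. **Promiscuous targets** — proteins biotinylated by *any* ligase
   regardless of bait identity, typically abundant proteins with accessible
   lysines. Their enrichment is reproducible, so no amount of replication
   removes them. They are addressed with a second control: a *freely
   diffusing ligase fusion* (a non-targeted ligase expressed in the same
   tissue), whose own enrichment profile against N2 defines a reference of
   non-bait-specific targets.

`proxifilt` implements the complete post-acquisition workflow around these
two controls: enrichment statistics, quality metrics, the control-target
reference, a two-stage filter, replicate-concordance analyses, a fully
synthetic study generator with ground truth, and a pipeline driver.

## Data model

The central container is `pl_matrix`: a numeric protein × run matrix with a
sample sheet (`run_id`, `strain_label`, `experiment_id`, `replicate_index`,
`role`) attached. Two conventions matter throughout:

* **Not-detected is `NA`, never 0.** Stored intensities are strictly
  positive. Group means are taken over the replicates in which a protein
  was detected: intensities 13, ND, ND across three replicates average
  to 13, not 13/3.
* Experiments are compared only within themselves: each bait contrast uses
  the negative-control runs of its own experiment (`run_pipeline` derives
  these automatically).

`read_quant_table()` maps empty cells, `NA`/`ND`/`Filtered` tokens and — by
default — numeric 0 to not-detected. `write_quant_table()` is its lossless
inverse (full `%.17g` precision, absences as empty cells).

## Enrichment statistics

For one bait sample versus its negative control, `compute_enrichment()`
produces per protein:

* group means over detected replicates, the linear fold change and its
  log2;
* a Welch (unequal-variance) *t*-test on log2 intensities, requiring at
  least `min_reps = 2` detected replicates per side, followed by
  Benjamini–Hochberg adjustment across all tested proteins of the
  contrast. If both groups are constant and equal the test is undefined
  and we report p = 1 (no evidence of difference) rather than an error.
* a **detection category**: `bait_only` (all bait replicates, no control
  replicate), `control_only` (the mirror image), `both`, `partial`,
  `neither`. These categories partition the proteins.
* for `bait_only` proteins, no ratio exists, so a **conservative
  fold-change estimate** is computed against a detection floor: the mean of
  the `k = 10` lowest control group-means among proteins detected in every
  control run. Using the *mean of the k lowest* rather than the single
  minimum makes the floor robust to one aberrant low value; using a floor
  at all deliberately *understates* the fold change of a protein the
  control never saw. Estimated fold changes are flagged
  (`fc_is_estimate`), carry no p-value, and are excluded from up/down
  counts.

## Quality metrics

`qc_report()` assembles one row per (strain, experiment):

* **Up %** = 100 · up/(up + down), where *up* means fold change ≥ 2 **and**
  adjusted p ≤ 0.05 (both bounds inclusive: FC 2.0 at p 0.05 counts, FC
  1.95 does not), *down* the mirror image at FC ≤ 0.5. A clean experiment
  enriches far more proteins than it depletes.
* **TurboID %** = 100 · bait-only/(bait-only + control-only). Exclusive
  detections on the control side signal sticky contamination.
* **Carboxylase %** — four endogenously biotinylated carboxylases (PYC-1,
  PCCA-1, MCCC-1, POD-2) dominate any clean streptavidin pulldown; their
  share of total detected intensity (pooled over the runs of the sample,
  which is robust to per-run dropout) tracks enrichment quality.
* **Epidermal %** — the fraction of final candidates present in a
  tissue-expression reference set, when one is supplied.

`replicate_overlap()`, `replicate_r2()` and `metric_correlation()` cover
detection Venn regions among technical replicates, pairwise log2-intensity
R² over co-detected proteins (ordinary least squares; undefined below 3
shared proteins), and simple regressions between metrics across
experiments.

## The control reference and the two-stage filter

`build_control_reference()` merges the contrasts of the non-targeted ligase
strain versus N2 from two (or more) control experiments into a per-protein
reference with three bucket types:

* `enriched_both` — significant with FC ≥ 2, and detected in all ligase
  replicates, in *every* contrast. Its `control_fc` is the arithmetic mean
  of the per-contrast *linear* fold changes (two experiments at 120- and
  144-fold average to 132-fold; averaging on the linear scale matches how
  such values are reported).
* `enriched_single_<exp>` — significant with FC ≥ 2 and full ligase
  detection in one contrast while absent from the negative controls of
  every other contrast; the single available fold change is used. Full
  ligase detection is demanded in the significant contrast itself (a
  partially detected protein is not admitted), but a protein wholly absent
  from the other experiment still qualifies.
* `control_only` — detected in every ligase replicate of every contrast
  and in no negative-control replicate anywhere; no fold change exists.

**Filter-1** (per bait contrast) retains proteins with FC ≥ 2, adjusted
p ≤ 0.05 and detection in *all* bait replicates — plus all `bait_only`
proteins, which include baits and partners the control never detects.

**Annotation** colors every Filter-1 protein by its control fold change:
red (> 10), orange (> 5–10), yellow (2–5), gray (`control_only`), white
(< 2 or absent from the reference), green (members of the bait's own
complex, supplied as a reference set; a complex member that also appears in
the control reference triggers a warning). Boundary values 10 and 5 fall
into the lower-severity bucket.

**Filter-2** removes every protein with control fold change above 5 (red
and orange) and every yellow-band protein whose bait-to-control
fold-change ratio is below 1.5. Gray proteins are retained but stay
flagged — no fold change exists for them, so removal would be
unjustified — as are green and white. Internally Filter-2 operates on the
numeric control fold change rather than on frozen color labels, which makes
retention monotone in both thresholds; the default cutoffs reproduce the
color-based description exactly. Filter-2 output is always a subset of
Filter-1 output.

## The synthetic study generator

`simulate_study(sim_config(...))` produces an intensity matrix, sample
sheet, and ground truth in exactly the shapes the pipeline consumes. The
generative model, on the log2 scale:

* Each protein has an intrinsic abundance ~ N(`baseline_log2_mean` = 16,
  `baseline_log2_sd` = 2).
* **Only the carboxylases are captured at full strength in every sample**
  (endogenous biotinylation), multiplied by `carboxylase_multiplier` = 100.
* Every other protein enters a pulldown at a **contamination-scaled sticky
  level**: intrinsic abundance + log2(`contamination_fraction` = 0.25).
  On top of that, each bait strain adds log2 cis enrichment to its bait
  and log2 trans enrichment to its partners, and a reproducible
  promiscuous set (`n_promiscuous` = 40, fold changes log-uniform on
  `promiscuous_fc_range` = [2, 132]) is enriched in every ligase-bearing
  strain including the non-targeted control. Promiscuous targets are
  clamped to at least average intrinsic abundance — they are abundant
  proteins by nature — which keeps them measurable in the negative
  control under default conditions.
* Enriched levels are floored two log2 units above the detection limit
  (`detection_floor_log2` = 12) so planted signal is observable by
  construction; values below the floor are recorded as not detected.
* Noise: per-measurement log-normal (`noise_sd_log2` = 0.2); a
  **stickiness shift** per (background protein, strain, experiment) with
  sd = `sticky_noise_sd_log2` × contamination fraction, constant across the
  technical replicates of one pulldown — this is what lets a dirty sample
  show spurious, replicate-consistent enrichment in either direction; and
  per-experiment batch shifts (`batch_sd_log2` = 1) on a random
  `batch_fraction` = 15% of proteins, recorded in the truth object.

This structure reproduces the qualitative behavior the quality metrics are
designed to detect. In a clean study genuine targets are invisible in the
negative control, so TurboID % is high; rising contamination makes them
control-visible and adds control-exclusive sticky detections, so Up %,
TurboID % and Carboxylase % all decline monotonically in expectation.
Lowering a bait's `expression` multiplier weakens cis and trans effects
without raising the observability floor, so detected partner counts fall —
the signature of a poorly expressed bait. `evaluate_recovery()` scores any
retained set against the truth (partner sensitivity, promiscuous and
background false-discovery proportions); with strong planted effects
(trans FC ≥ 8, promiscuous FC > 5, noise sd ≤ 0.2) the full pipeline
reaches sensitivity 1.0 with zero promiscuous leakage.

The generator deliberately stops at protein-level intensities: no
peptide/spectrum simulation, no chromatography, and no
missing-not-at-random mechanism beyond the intensity floor.

## The pipeline

```r
library(proxifilt)
st <- simulate_study(sim_config(seed = 42))
cfg <- pipeline_config(list(
  out_dir = "results",
  carboxylase_set = c("PYC-1", "PCCA-1", "MCCC-1", "POD-2"),
  baits = list(
    "BAIT-1::TurboID" = list(bait = "BAIT-1", partners = c("PART-1", "PART-2")),
    "BAIT-2::TurboID" = list(bait = "BAIT-2", partners = c("PART-1", "PART-3")))))
res <- run_pipeline(cfg, matrix = st$matrix)
res$summary
```

`run_pipeline()` derives every bait and control contrast automatically from
the sample sheet roles, builds the control reference, applies both filters,
writes one annotated CSV per contrast plus the QC summary, control
reference, occurrence tables and a JSON manifest whose row counts match the
files exactly, and returns everything invisibly as a `pl_study`. Reruns on
identical inputs are byte-identical. Without any non-specific control runs
it refuses to apply Filter-2 and asks for `filter1_only = TRUE`. A thin
command-line wrapper with `simulate` and `run` verbs ships in
`inst/cli/proxifilt.R`.

Cross-experiment concordance tools: `occurrence_frequency()` (how many
biological replicates each candidate recurs in), `batch_overlap()`
(detection regions across strain–experiment sets, with the fraction of
region members called *up*, using each protein's maximum across its
experiments), `cross_bait_overlap()` (Venn regions across bait candidate
sets, optionally with color composition), `term_set_jaccard()`.

## Numerical choices and limitations

* Welch test with BH adjustment via `stats::p.adjust`; undefined tests
  (zero variance, equal groups) report p = 1.
* The fold-change floor estimator is deliberately conservative and returns
  an error, not a guess, when fewer than `k` proteins are fully detected
  in the control.
* Control fold changes are averaged on the linear scale; enrichment tests
  run on the log2 scale.
* Protein identifiers are matched case-insensitively after whitespace
  trimming everywhere.
* The two-experiment control-reference design generalizes to k ≥ 3
  contrasts ("both" = all, "single" = exactly one); that extension is
  documented behavior, not validated against any published k ≥ 3 study.
* Quality metrics are descriptive, not calibrated probabilities; the
  simulator supports ordinal statements (cleaner vs dirtier), not absolute
  predictions for any particular instrument.

Typical problem sizes: thousands of proteins, a handful of strains, two to
eight experiments, three technical replicates — everything here runs in
seconds on one CPU at those scales.
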