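---
title: "Methods: per-sample pathway over-representation for paired treatment cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-sample pathway over-representation for paired treatment cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

skinora targets a common design in dermatology transcriptomics: a small
cohort of patients measured on expression microarrays before and after a
topical treatment, often in two arms (e.g. a corticosteroid versus a
calcineurin inhibitor), analysed against a curated, organ-specific pathway
knowledge base. Two features distinguish this setting from generic
enrichment tooling:

* **Per-sample analysis.** With ~10 patients, averaging fold changes
  across patients hides responder heterogeneity. skinora calls
  differentially expressed genes (DEGs) and runs the enrichment test
  *independently for each treated sample* against its own patient's
  baseline, then summarises each pathway by the number of samples in which
  it is enriched.
* **A closed gene universe.** The enrichment population is the knowledge
  base's own gene universe (the union of its pathway gene sets), not the
  array platform. This matches how curated skin-pathway platforms define
  the test and keeps results comparable across platforms.

## Preprocessing model

Input is a probe × sample intensity matrix plus a parallel
Present/Marginal/Absent (P/M/A) detection-call matrix, a probe→gene map
and a design table pairing each treated sample with its baseline within a
patient and arm. Arms are always processed separately; no cross-arm
statistic exists anywhere in the pipeline.

1. **Median scaling** (`median_normalize()`): each sample is divided by
   its own median intensity on the linear scale, so every sample's median
   is exactly 1 afterwards. The operation is idempotent. Log transforms
   happen only downstream, in the fold-change step — 50th-percentile
   scaling is defined on intensities, not logs.
2. **Detection filtering** (`filter_by_detection()`): a probe is kept if
   its P/M call rate is at least the threshold (default 0.70, boundary
   inclusive: 7 of 10 passes) in *every* analysis group — i.e. both the
   baseline and the treated group of the arm under analysis. The phrase
   "per analysis group" admits a weaker reading (at least one group); we
   default to the conservative every-group rule because a gene whose
   baseline is mostly Absent has no trustworthy denominator for a fold
   change, and expose `group_rule = "any"` for the other reading.
   Marginal calls count exactly like Present calls.
3. **Probe collapse** (`collapse_probes()`): each gene receives the median
   of its surviving probes, per sample. Medians of even counts are the
   arithmetic mean of the two central values throughout the package.
   Probes with no gene mapping are dropped (and counted in the log);
   a probe mapping to two genes is an error rather than a silent
   duplication.

## Fold changes and DEG calling

For each treated sample the log2 fold change of gene *g* is

```
log2(x_treated(g) + eps) - log2(x_baseline(g) + eps),    eps = 1e-6
```

against the *same patient's* baseline (`fold_change(mode = "per_sample")`).
We read the before/after design as paired: each patient is their own
control, which is both the stronger design and the only reading that
yields one fold-change column per treated sample. A pooled alternative
(`baseline = "pooled"`, each treated sample against the median of all the
arm's baselines) is available for designs without within-patient pairing.
The aggregate mode (`mode = "aggregate"`) takes the median over treated
samples against the median over baselines — one column, the form used when
an external tool needs a single input list.

The pseudo-value `eps` on the linear scale guards `log2(0)`; gene/column
pairs at zero in *both* conditions carry no information and are excluded
with a logged count rather than reported as 0.

DEG calling is purely threshold-based (`call_degs()`): up-regulated means
log2FC ≥ +cutoff, down-regulated means log2FC ≤ −cutoff, boundaries
included on both sides, default cutoff 1.0 (two-fold). No gene-level
statistical test or multiple-testing correction is involved — with n = 10
and a fold-change-threshold definition of differential expression, the
statistics live at the pathway level.

## The enrichment test

For a DEG set and a pathway, genes inside the knowledge-base universe are
cross-classified into the 2×2 table

|              | in pathway | not in pathway |
|--------------|-----------:|---------------:|
| DEG          | a          | b              |
| not DEG      | c          | d              |

with `n = a + b + c + d` equal to the universe size. Up- and
down-regulated genes are pooled: the test asks whether the pathway is
*perturbed*, in either direction. The probability of the observed table
with all margins fixed is the hypergeometric point probability

```
P(a) = (a+b)! (c+d)! (a+c)! (b+d)! / (a! b! c! d! n!)
```

and the reported p-value is the one-sided over-representation tail
`p = sum_{k >= a} P(k)`. One-sided is the right default because the
question is enrichment — a pathway holding *fewer* DEGs than chance is not
of interest and should not be called; `alternative = "two.sided"`
implements the standard minimum-likelihood two-sided rule for users who
want it. A pathway is *enriched* when `p < alpha` strictly (default
α = 0.05), and the cross-sample summary counts, per pathway, the samples
in which it is enriched.

Two deliberate policy choices, both switchable:

* **Universe** (`universe`): default is the full knowledge-base universe,
  following the test's definition of `d` and `n` as knowledge-base gene
  counts. `universe = "kb_measured"` intersects the universe with the
  measured genes, which is the better choice when the platform covers only
  part of the knowledge base (unmeasured genes can never be DEGs, so
  keeping them deflates p-values slightly; with a platform designed around
  the knowledge base the difference is small).
* **Adjustment** (`adjust`): raw p-values by default, matching the
  α = 0.05-on-raw-p convention of the platforms this emulates;
  `adjust = "BH"` applies Benjamini–Hochberg within each column for
  modern use.

### Numerical implementation

The tail is summed in log space from `lchoose()` terms. The hypergeometric
pmf is unimodal, so the largest term sits at the (clamped) mode
`floor((D+1)(K+1)/(n+2))`; that term is factored out before exponentiating,
which keeps the sum accurate near machine precision even when the p-value
underflows naive arithmetic. The implementation is vectorised over tables
(the per-sample analysis computes all pathway × sample p-values in one
call). Tests compare it against an exact rational-arithmetic enumeration
oracle (integer binomial-coefficient suffix sums, correctly rounded to
double only at the end) over *every* contingency table with n ≤ 60 —
635,375 tables — at 1e-10 relative tolerance, and against
`stats::fisher.test` / `stats::phyper` on random larger tables. Result
rows are ordered by (p ascending, pathway name ascending) so reruns are
byte-identical.

## Cutoff sensitivity analysis

`sensitivity_analysis()` re-runs DEG calling and enrichment at cutoffs
0.5, 1.0 and 1.5 log2 units (the default cutoff and one half fold-change
either side). Because DEG sets are nested in the cutoff — a gene passing
1.5 necessarily passes 1.0 and 0.5 — a pathway driven by a strong signal
is expected to be recovered at every cutoff, and the report tabulates per
pathway in how many cutoffs it was enriched in at least one sample. This
set-level nesting is the mechanism that makes threshold-robust conclusions
possible; note it does not force enriched-pathway sets themselves to nest,
since the *background* DEG count also changes with the cutoff.

## Expression overlays

`overlay()` projects fold changes onto a pathway: every pathway gene, per
column, gets one of four states — `up` / `down` at the DEG cutoff,
`unchanged` between, `not_measured` if absent from the fold-change table.
We discretise at the DEG cutoff rather than using a continuous colour map
because downstream interpretation is phrased in up/down terms; the
continuous log2FC is retained as a node attribute so viewers can recolour.
Exports are a node TSV, an edge TSV and a GraphML file (per-column
`state_*` and `log2fc_*` node attributes, `sign` edge attributes) readable
by Cytoscape-class viewers; rendering itself is out of scope. Up/down
states agree exactly with `call_degs()` membership, which the tests assert
across modules.

## The synthetic cohort generator

`simulate_cohort()` exists so the entire pipeline is testable, and its
statistical behaviour measurable, without any external download. The
generative model is deliberately the simplest one consistent with a
fold-change-threshold analysis:

* Gene baseline log2 levels per (gene, patient, arm):
  `Normal(baseline_log2_mean = 6, baseline_log2_sd = 1)`.
* Baseline and treated samples add independent
  `Normal(0, noise_sd = 0.3)` log2 measurement noise, so an unperturbed
  gene's log2 fold change is `Normal(0, sqrt(2) * 0.3 ≈ 0.42)` and the
  null DEG rate at cutoff 1 is its tail mass, ≈ 1.8% (slightly more after
  probe jitter and collapse) — a realistic order for processed microarray
  data at a two-fold threshold.
* Planted effects: selected pathways shift a fraction of their genes
  (default studies use 80% of a 30-gene pathway) by Δ log2 units in the
  treated samples of responder patients. Ground truth (responders,
  affected genes, per-gene shifts) is returned alongside the data.
* Probes: 1–3 per gene, jittered `Normal(0, 0.1)` around the gene value.
* Detection calls: Absent with rate 0.05, Marginal with rate 0.05 among
  detected, drawn independently of intensity. Independence is a
  simplification that keeps the detection-filter tests orthogonal to the
  intensity model; real Absent calls correlate with low intensity.
* The knowledge base partitions all genes into pathways (sizes drawn from
  `pathway_size_range`), so the universe equals the simulated gene set by
  default — 2000 genes in the standard configurations, matching the scale
  of a curated skin knowledge base.

Defaults are sized to the motivating study: 10 patients, two arms, paired
baseline/treated samples. Everything is driven by a single seed;
identical seeds give byte-identical cohorts.

What the generator does **not** emulate: array-chemistry artifacts
(probe-affinity bias beyond a symmetric jitter, background, saturation),
batch or spatial effects, gene–gene correlation beyond the planted
pathway structure, and intensity-linked detection calls. Passing
calibration and power checks on these cohorts therefore demonstrates the
pipeline's statistical correctness under its stated model, not robustness
to every failure mode of real arrays.

## Calibration and power, and the problem sizes used

`estimate_type1()` runs the full pipeline (simulate → normalise → filter →
collapse → fold change → DEG → enrich) on null cohorts and reports the
fraction of (pathway, sample, replicate) tests with p < α. Because the
test is exact and discrete, this fraction sits well below the nominal
level (typically ≈ 0.02 at α = 0.05 in the standard configuration) — the
familiar conservatism of exact tests on small counts.

`estimate_power()` scores, per planted pathway and replicate, whether the
pathway was enriched in at least `responder_fraction × n_patients − 1`
samples, and whether it was the top-ranked pathway by median p across
samples. At the reference setting (Δ = 2.0, 80% of a 30-gene pathway,
2000-gene universe, noise_sd 0.3, 10 patients) recovery and top-ranking
are essentially certain: the expected table has a ≈ 24 of 30 pathway genes
as DEGs against a ≈ 2% background rate.

The shipped test suite and the acceptance script use 200 null replicates
and 100 planted replicates at the 2000-gene, 10-patient scale, and the
exhaustive n ≤ 60 grid for the exactness check; these sizes give
Monte-Carlo standard errors well under the decision margins while keeping
a full run in the low minutes on one CPU.

## Degenerate inputs and edge policies

* Empty GMT → a valid knowledge base with an empty universe; enrichment
  refuses it with a clear error.
* A sample with all-zero intensities cannot be median-scaled → error
  naming the sample.
* An empty DEG set is legal: every pathway gets p = 1 and nothing is
  enriched (the enriched flag is strictly `p < alpha`, so α = 0 can never
  flag, and p = 1 rows are never flagged even at α = 1).
* Ties in result ordering are broken by pathway name; all writers emit
  deterministic bytes, and the pipeline manifest records md5 hashes so
  reruns are verifiably identical.
* Unknown interaction relations map to sign `unspecified` with a warning;
  edges whose endpoints are outside their pathway's gene set are rejected
  at load and reported by `kb_validate()`.

## Known limitations

* The shipped `demo_kb()` is an indicative, synthetic stand-in assembled
  from genes repeatedly implicated in atopic-dermatitis treatment
  response; it is not a curated knowledge base and should not be used for
  real inference. Any user GMT (plus optional signed edge file) drops in.
* Gene identity is plain upper-cased symbols; no alias or ID mapping.
* The enrichment model ignores pathway topology (edges drive overlays
  only) and gene–gene correlation, which genuinely inflates enrichment
  significance when pathway genes are co-regulated — a known property of
  all count-based over-representation tests.
* `reproduce_geo()` infers arm/condition/patient from sample titles with
  conservative regular expressions and fails loudly when inference is
  ambiguous; deposited series vary, so passing an explicit design table is
  the reliable path.
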