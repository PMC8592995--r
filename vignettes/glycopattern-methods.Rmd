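---
title: "Methods: dose-response pattern analysis for glycoproteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-response pattern analysis for glycoproteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycopattern)
```

## The analysis problem

Androgen-receptor-positive prostate cancer cells respond to androgen in a
biphasic way: physiologic doses (0.1–1 nM of the synthetic androgen R1881)
stimulate proliferation, while a supraphysiologic dose (SPA, 10 nM)
paradoxically inhibits it. A label-free glycoproteomic profiling experiment
quantifies lectin-enriched (glycosylated) proteins in LNCaP cells exposed to
a vehicle baseline plus the three doses, and asks which glycoproteins track
the proliferation response — and which of those, when profiled again in
clinical prostate tissue (normal adjacent tissue, benign hyperplasia,
localized and metastatic cancer), behave like disease biomarkers.

`glycopattern` implements that analysis as a reusable, testable pipeline:
spike-in normalization, ternary direction-pattern classification, cluster
overrepresentation analysis, supervised hierarchical clustering of tissue
cohorts and candidate-biomarker triage, plus a synthetic-data generator so
that every stage can be exercised end-to-end without access to raw mass
spectrometry data.

## Quantification and normalization

Input is a protein-by-sample intensity matrix (`quant_table`) with `NA` for
proteins not observed in a sample. Upstream of it, `filter_psms()` applies
the search engine's post-search acceptance thresholds (forward–reverse
score ≥ 1.2, rank 1–2 score ≥ 2, score ≥ 3, scored-peak-intensity ≥ 30%).
All four comparisons are inclusive: the engine's "threshold of x"
convention keeps a record sitting exactly at x. `aggregate_psms()` rolls
PSM intensities up to proteins by summation (mean/median selectable);
summation conserves total intensity per sample, which the tests assert.

Samples are corrected for unequal loading by an externally spiked standard
(BSA): each sample is multiplied by the ratio of the reference sample's
total spike intensity to its own, after which the spike rows are removed
(`normalize_to_spike()`). The reference defaults to the first sample; any
common reference generalizes pairwise tumor-over-normal ratios to an
arbitrary number of samples. The operation is invariant under global
rescaling and idempotent once spike totals are equal; missing values pass
through untouched — no imputation happens anywhere in the statistics.

Protein-level spike totals are used (rather than per-peptide totals), since
the quantification table is the protein-level object the pipeline works on.

## The ternary pattern frame

Each treated dose is coded relative to the vehicle baseline as up (`u`),
down (`d`) or same (`s`): `u` when intensity ratio ≥ `fold_threshold`,
`d` when ≤ 1/`fold_threshold`, `s` otherwise. With three treated doses this
yields 3³ = 27 theoretical patterns; `pattern_index()` encodes them in base
3 (d = 0, s = 1, u = 2, first dose most significant), so the flat pattern
`sss` has index 13. The default `fold_threshold` is 1.5 — a conventional
"changed" cutoff for label-free intensity data; it is deliberately
configurable because the choice is a judgment call, and the boundary is
inclusive toward "changed".

A pattern is *SPA-associated* when its SPA digit differs from the digit at
**both** proliferative doses: the SPA response then stands apart from the
proliferation-stimulating responses and aligns with the non-proliferative
baseline state. This is the only natural reading of the selection idea that
yields exactly 12 of the 27 patterns (the weaker reading "SPA digit =
same" selects only 4 patterns and is rejected). The count 12 is forced by
the rule: 3 choices of SPA digit × 2 × 2 choices for the two other digits.

Missing treated intensities default to dropping the protein from coding
(`missing_policy = "drop-protein"`); `"treat-as-down"` is available for
presence/absence-style analyses where disappearance at a dose is the
signal. A missing or non-positive baseline cannot be ratio-coded and drops
the protein under either permissive policy.

## K-means clustering and cluster-to-pattern matching

Profiles are standardized before clustering: `log10(x + 1)`, then centered
and scaled to unit variance per protein (`standardize_profiles()`);
constant profiles map to zero rows. Standardizing the log profile makes
K-means compare response *shapes* rather than abundances. Whether raw, log
or standardized intensities should be clustered is an open choice in this
kind of analysis; standardized log10 is used because the 27 theoretical
shapes are mutually distinguishable there (no two distinct ternary step
patterns are positive-affine images of each other).

`kmeans_profiles()` runs Lloyd's algorithm (via `stats::kmeans`) from
k-means++ seedings, takes the best of `n_init = 10` restarts by inertia,
and derives all randomness from one integer seed, leaving the caller's RNG
untouched. The default `k = 27` gives one empirical cluster per theoretical
pattern. `match_clusters_to_patterns()` then direction-codes each cluster's
representative profile — the per-dose **median raw intensity** of its
members, not the standardized centroid, so fold thresholds keep their
units. The mapping is many-to-one (several empirical clusters can land on
one theoretical pattern), and empty clusters are reported with a warning
flag rather than dropped.

## Overrepresentation analysis

`ora()` tests annotation terms (read from standard GMT via
`fgsea::gmtPathways`) for overrepresentation of a query set within a
universe, using the upper-tail hypergeometric probability
$P(X \ge k)$ with $N$ = universe size, $K$ = in-universe term size,
$n$ = query size, $k$ = overlap. The universe is the set of quantified
proteins of the experiment at hand, not the whole annotation vocabulary —
the background a practitioner would use for a per-condition enrichment.
Terms with fewer than `min_term_size = 3` in-universe members are excluded
as degenerate. `bh_fdr()` provides Benjamini–Hochberg q-values
(`stats::p.adjust`). For heatmap export, `neglog_p_matrix()` reports
$-\log_{10} p$ (base 10, stated in the output header) for cells with
$p < \alpha$ strictly, 0 otherwise, keeping only terms significant
somewhere.

Note the statistic is discrete: at `k = 0` the upper tail is exactly 1, and
under the null the attained level at α = 0.05 is slightly conservative.
With KEGG-typical set sizes (tens to a couple of hundred members) and a
query around a third of the universe, the exact attained level is ≈ 0.04,
which is what the null-calibration suite observes.

## Tissue cohorts, clustering and biomarker triage

For display, `log_cap_transform()` maps intensities onto the 0–5
clustergram scale: missing (undetectable) is 0, present values are
log10-transformed, shifted so the dimmest detected intensity sits at the
bottom of the scale, and saturated at 5. The exact rescaling a particular
visualization tool applies before capping is not recoverable, so the
transform is simply documented and monotone — all the downstream logic
requires. The display convention (missing → 0) deliberately differs from
the statistics: `group_contrast()` excludes missing values from group
means instead of imputing zeros, to avoid inflating fold changes.

`hierarchical_cluster()` performs supervised clustering as practiced for
such cohorts: sample columns fixed, protein rows clustered with Pearson
correlation distance ($1 - r$, pairwise-complete) and complete linkage
(`stats::hclust`). Pairs with fewer than two complete positions or zero
variance are an error naming the pair, never a silent zero. Dendrograms
export as Newick (`ape`) and as a flat merge table.

`candidate_biomarkers()` formalizes the visual triage of clustergrams as an
explicit rule: a protein passes when its cell-line dose pattern is
non-flat (androgen-regulated), its pooled PCa+mPCa vs BPH log10 fold
change is ≥ `min_log10_fc` (default 0.5, i.e. ≥ ~3-fold), and — when
paired data are required — the median paired tumor−NAT log10 difference is
positive. Candidates are ranked by the tumor-vs-BPH contrast. The
archetypal positive control is a glycoprotein (ENTPD5-like) that is
biphasic in the cell line — rising through physiologic doses, peaking at
1 nM and falling below baseline at 10 nM (`uud`) — and elevated in tumor
tissue.

## The synthetic-data generator

`simulate_dose_response()` emulates the statistical structure the analysis
assumes, with defaults set to the study conditions it stands in for:

* ~3,341 proteins with log10-normal base abundance (mean 7, sd 1), so
  intensities span roughly 1e4–3e9 — log-normality is the standard
  label-free intensity model when only a min–max range is known;
* one planted ternary pattern per protein (uniform over the 27 by
  default), each `u`/`d` step worth `effect_log10 = 1` decade;
* noise specified on the **log-ratio-to-vehicle scale**: the vehicle
  column carries the protein's base abundance and every treated dose adds
  `Normal(0, noise_log10_sd = 0.2)` to its log ratio. Specifying
  fold-change noise this way keeps the per-digit miscall probability
  directly interpretable: a digit is miscalled when ratio noise crosses
  half the effect, i.e. with probability $\approx 2\Phi(-2.5) \approx 1\%$
  at the defaults with `fold_threshold = 10^{effect/2}`;
* per-condition missingness, completely at random by default, with rates
  whose expected presence counts reproduce a realistic per-condition
  quantification profile (≈ 1540/1558/1668/1586 of the union);
  intensity-dependent missingness is available behind a flag since real
  label-free missingness is abundance-biased;
* a BSA-like spike row with *identical* intensity in every sample before
  any distortion; optional per-sample loading multipliers distort whole
  columns (spike included) so that normalization can be tested to undo
  them exactly.

The spike is represented as designated rows of the same table — that is how
spiked standards actually surface in search output. Replicate columns are
off by default (one column per condition, as a minimal design implies), but
`n_replicates` generates them with independent noise when needed.

`simulate_gene_sets()` plants enrichment by sampling designated terms with
odds multiplied by `enrichment_factor` for members of one pattern class
(default: the most frequent SPA-associated class); at factor 1 enriched and
null terms are indistinguishable, which the calibration tests exploit.
Default set sizes are 20–200 members, typical of curated pathway
collections and large enough that the discrete hypergeometric test is only
mildly conservative.

`simulate_tissue_cohort()` generates a cohort over NAT/BPH/PCa/mPCa groups
(default shape 8/10/13/6, a realistic clinical accrual) with planted marker
classes: tumor-up (elevated by `effect_log10` in PCa and mPCa), BPH-up,
null, and exactly one androgen-biphasic-tumor-up archetype whose paired
cell-line profile is `uud`. NAT samples are paired with PCa samples where
counts allow. All generators are bit-reproducible from their seed.

## What the simulations do and do not show

The generator reproduces the *statistical* structure the pipeline assumes:
log-normal intensities, ternary dose responses of a fixed effect size,
MCAR missingness, exchangeable noise. Real data violate all of these to
some degree — intensity-dependent missingness, correlated peptide-level
noise, shared-peptide ambiguity, batch structure and biological covariance
between proteins are not modeled (nor are spectra, retention times or
identification errors beyond the PSM score filter). Passing the recovery
suites therefore demonstrates correctness of the implementation under its
stated model, not expected sensitivity on any particular real dataset.

## Numerical and design choices

* Tolerances: exact combinatorial quantities (pattern counts, enumeration,
  linkage heights against a brute-force oracle) are asserted to 1e-12;
  stochastic recovery rates use the bounds their sampling distributions
  imply (3σ binomial/multinomial bands).
* Problem sizes in the test and acceptance runs: dose-response recovery
  uses 2,000 proteins × 5 seeds (pooled per-protein recovery and
  cluster-level matching); ORA calibration uses 1,000 null terms over a
  2,000-protein universe; cohort recovery uses 400 proteins (40 tumor-up +
  40 BPH-up markers + 1 archetype) × 20 seeds at 10 samples per group.
  These sizes give the recovery estimators standard errors well below the
  margins being asserted while keeping the suites quick.
* "Clusters whose members share a planted pattern" is measured as clusters
  whose modal planted pattern covers ≥ 90% of members; with 2,000 noisy
  profiles in 27 clusters, strictly 100%-pure clusters essentially never
  occur, so the strict reading would be vacuous.
* K-means ties and restarts are fully determined by the seed; an
  empty-cluster failure of a Lloyd fit triggers a fresh seeded
  re-initialization.
* Degenerate inputs are errors, not warnings: zero/missing spike totals
  (named sample), undefined Pearson distances (named pair), queries
  outside the ORA universe (named offenders), p-values outside (0, 1].

## A worked end-to-end run

```{r example, eval = FALSE}
cfg <- simulation_config(n_proteins = 1000, seed = 42)
study <- simulate_dose_response(cfg)
norm <- normalize_to_spike(study$quant, study$spike_rows)

pt <- pattern_table(norm, study$design,
                    direction_params(fold_threshold = 10^0.5))
table(pt$spa_associated)

z <- standardize_profiles(norm, study$design)
km <- kmeans_profiles(z, k = 27, seed = 42)
match_clusters_to_patterns(km, norm, study$design,
                           direction_params(fold_threshold = 10^0.5))
```

`run_full_pipeline()` sequences the same stages over files (normalize →
patterns → enrich → cohort), writes every output with a header recording
the package version, configuration hash and seed, and emits a manifest;
rerunning an identical configuration reproduces byte-identical tables. The
package is driven from R; the exported functions plus this pipeline
orchestrator are its interface.

## Known limitations

* Protein inference and shared peptides are out of scope; the PSM table's
  protein assignments are taken as given.
* No decoy-based FDR estimation for identifications; only the score-based
  post-search filter is modeled.
* The candidate-biomarker rule is a thresholded formalization of what is,
  in practice, a visual triage of clustergrams; its defaults are sensible
  but the thresholds carry no inferential guarantee.
* The 0–5 display transform is one monotone choice among several a
  visualization tool might make.
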