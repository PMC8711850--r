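---
title: "Methods: CNV landscape characterization and ecotype divergence scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNV landscape characterization and ecotype divergence scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvscape)
```

`cnvscape` is a downstream-analysis toolkit for multi-sample structural
variant catalogs of the kind produced by short-read SV pipelines
(LUMPY + svtyper and relatives): a VCF with `SVTYPE` and `END` in INFO and a
diploid `GT` per sample. It targets population studies of copy number
variation (CNV) — deletions and duplications ≥ 1 kb segregating among
sequenced individuals of a wild or domestic species — and answers four
questions about such a catalog:

1. What does the catalog look like (counts, lengths, per-individual burden,
   carrier frequencies, genome coverage)?
2. Are CNVs spread uniformly over the assembly, or clustered?
3. Where are the hotspots, and which gene models do CNVs hit?
4. Which loci differentiate two predefined groups of individuals
   (e.g. ecotypes), and how unusual is that differentiation?

This vignette records the model behind each step, the tunable parameters
with their units and defaults, the numerical conventions, and what the
synthetic-data generator does and does not emulate.

## Data model and conventions

All intervals are **0-based half-open** internally. Conversions happen only
at format boundaries: VCF and GFF3 (1-based inclusive) on read/write, BED
(0-based half-open) passes through unchanged. A VCF row with `POS = 1001`,
`END = 2000` becomes the internal interval `[1000, 2000)` of length 1000.

Genotypes are **alternate-allele dosages** in {0, 1, 2}, with `./.` mapped
to missing. svtyper emits biallelic genotypes, so the dosage is a carrier
signal, not an absolute copy number; no copy-number reconstruction is
attempted. A **carrier** is a sample with dosage ≥ 1, and the **carrier
frequency** of a locus is carriers / non-missing samples. Frequencies in
this package are carrier frequencies throughout — with biallelic SV
genotypes this is the robust quantity, and the published per-locus average
(≈ 0.355 in the motivating dataset) is consistent with either reading.

The `genome_index` fixes scaffold order and provides offsets for the
**concatenated coordinate** system (scaffolds laid end to end), which is
what the genome-wide spatial statistics operate on.

## Catalog filtering and summaries

`filter_cnvs(table, min_length = 1000, min_carriers = 2)` retains loci at
least `min_length` bp long (CNVs are conventionally ≥ 1 kb) carried by at
least `min_carriers` individuals. Variants seen in a single genome (or in
none, i.e. reference-only calls) are excluded: they are enriched for
artefacts and for de novo somatic events that say nothing about segregating
variation. The filter is idempotent and order-insensitive.

`summarize_catalog` aggregates DEL/DUP counts, mean length, per-sample
burdens, mean carrier frequency, the length of the *union* of all CNV
intervals (overlaps counted once) as a fraction of the assembly, and the
number of scaffolds with ≥ 1 CNV. `length_comparison` is a Welch
unequal-variance t test with Welch–Satterthwaite degrees of freedom —
deletion and duplication length distributions are heavy-tailed and of very
different sizes, so the pooled-variance Student test would be
inappropriate. The sign convention is `t > 0` when the first group's mean
is larger; call it with duplications first to test whether deletions are
the smaller class.

## Spatial non-randomness: the KS test

The randomness question is framed as a two-sample problem: do CNV positions
look like draws from the same distribution as non-CNV positions?
`spatial_randomness_test`:

* maps each CNV to its **midpoint** in concatenated coordinates;
* samples, uniformly **without replacement**, an equal number of bases from
  the complement of the CNV union (the "non-CNV positions"); the sample is
  seeded and the whole test is deterministic given `(table, seed)`;
* computes the two-sample Kolmogorov–Smirnov statistic
  `D = sup_t |F̂_x(t) − F̂_y(t)|` over the pooled sample points, with the p
  value from the asymptotic Kolmogorov distribution at
  `sqrt(n_eff) · D`, `n_eff = n_x n_y / (n_x + n_y)`.

Sampling the complement (rather than enumerating every non-CNV base) is an
operational choice: the per-base two-sample test is equivalent in the limit
and intractable verbatim on a multi-Gb genome. Midpoint assignment avoids
length-weighting: a 2 Mb CNV contributes one position, not two million.

The asymptotic p value is accurate for the catalog sizes this package
targets (hundreds of positions per side); `ks_two_sample` is exposed
directly if a permutation null is preferred.

## Hotspot detection

`window_counts(table, genome, window = 2e6, step = 1000)` tiles each
scaffold from 0 with 2 Mb windows every 1 kb (final windows truncated at
the scaffold end) and counts, per window, the CNVs whose **midpoints** fall
in `[start, end)`. Any-overlap counting would multi-count Mb-scale CNVs
across thousands of overlapping windows and make the statistic
length-dominated; midpoints keep it a count of events.

`detect_hotspots(track, quantile = 0.975, table)` thresholds at the
genome-wide empirical quantile of all window counts (R's type-7
linear-interpolation quantile; the quantile is computed over the single
genome-wide distribution, not per scaffold). Windows **strictly above** the
threshold are extreme — a strict comparison makes the degenerate all-equal
track yield zero hotspots — and runs of overlapping-or-abutting extreme
windows merge into hotspots (with `step < window`, consecutive extreme
windows always overlap, so hotspots are contiguous runs). Each hotspot
reports its union interval, the number of member windows, and the number of
distinct CNVs with midpoints inside it.

Two consequences of the merged-window geometry are worth knowing. First, a
hotspot interval overreaches the underlying CNV cluster by up to one window
width on each side. Second, when a large fraction of all windows sits
inside genuine clusters, the 97.5% quantile climbs into the cluster counts
themselves and fragments detection; the scan is designed for the regime
where hotspots occupy ≪ 2.5% of windows.

## Gene overlap

`overlap_cnv_genes` intersects CNVs with gene models (GFF3 `gene` rows; the
annotation in the motivating study is gene-model-level coding sequence).
An overlap requires ≥ `min_overlap_bp` shared bases (default 1 — the most
permissive reading of "overlapped"); strand is ignored because CNVs are
unstranded dosage events; half-open abutment is not an overlap. Aggregates
are computed over **all** CNVs, so zero-overlap CNVs pull the per-type
means down — means like "0.20 coding sequences per deletion, from 0 to 5"
include the zeros. Because one gene can be hit by several CNVs, the
distinct-gene cardinality and the pair count are reported separately.

## The DAPC divergence scan

The group-divergence scan is a from-scratch **discriminant analysis of
principal components**:

1. `encode_dosage` builds the samples × loci dosage matrix (missing values
   mean-imputed per locus; zero-variance loci dropped; samples without a
   group label excluded — e.g. an ecotype represented by one individual
   cannot be discriminated).
2. `fit_pca` centers (optionally scales) and decomposes by SVD. Centering
   without scaling is the default, matching standard DAPC practice for
   genotype data that shares a unit.
3. The number of retained PCs is the smallest reaching a cumulative
   explained-variance target (default 0.875), capped at `n_samples − 2` so
   the within-group covariance remains well-conditioned. The target echoes
   the motivating analysis (15 PCs, 87.4%), but the retained *count* is
   data-specific, never a constant. An explicit `n_pcs` overrides the rule.
4. With exactly two groups the discriminant subspace is one-dimensional and
   has the closed form `w ∝ W⁻¹(μ₁ − μ₂)` on the retained PC scores, where
   `W` is the pooled within-group covariance and μ the group centroids. A
   ridge of `1e-8 · trace(W)` guards against singularity. The closed form
   is exact here, so no generalized eigensolver is used.
5. Each locus gets a **composite loading** (PC rotation × discriminant
   coefficients); squared loadings normalized to sum to 1 are the
   **contributions** ("loading scores"). `select_divergent(model, q)` takes
   the `ceiling(q · n_loci)` largest — at `q = 0.025` a 1,698-locus catalog
   yields exactly 43 selected loci, which is the only rounding rule
   consistent with that published count. Ties at the threshold break by
   locus order with a warning.

Signed loadings and per-sample discriminant scores are exposed alongside;
swapping group labels flips score signs but leaves contributions unchanged.

`permutation_null` refits the model under label permutations (group sizes
preserved, seeded) and records each null fit's maximum contribution. The
motivating analysis applied no significance test to its selection; the null
is provided so users can judge whether their top contribution exceeds label
noise.

**Limitation (measured, not hypothetical):** contributions are squared
composite loadings, not per-locus standardized statistics. With small
groups (n = 10 per ecotype) and hundreds of background loci, two or three
background loci with lucky sampling fluctuations typically enter a
top-2.5% selection. In calibration runs on synthetic data with 10 planted
loci among 500 (carrier-frequency contrast 0.6, selection size 12), the
scan recovers ≥ 9/10 planted loci in ~85% of seeds — good, but a per-locus
Welch-t ranking is measurably sharper (~97%) in this regime. The DAPC scan
is kept because it is the field's established multivariate procedure and
captures joint structure a univariate test cannot; treat the selection as
candidates, not significance calls.

## The synthetic-data generator

`sim_params()` + `simulate_genome` / `simulate_gene_models` /
`simulate_cnv_catalog` / `make_fixture_bundle` produce a fully truth-known
world: genome index, non-overlapping gene models with adaptation-flavoured
annotation strings, and a genotyped CNV catalog with planted hotspot
intervals and planted divergent loci. Every artifact is a pure function of
`(params, seed)`; bundles regenerate byte-identically.

Defaults state a 20-genome, two-ecotype study at desk scale and were fixed
once, before any acceptance measurement they feed:

| parameter | default | rationale |
|---|---|---|
| genome | 8 scaffolds, 1.6 Gbp | 500 loci / 1.6 Gbp ≈ the published density (1,698 / 2.59 Gbp); a large-scaffold ladder mimics an L90-dominated assembly |
| samples | 10 + 10 (`sedentary`/`migratory`) | the study's two discriminated ecotypes |
| `n_loci` | 500 | desk-scale catalog |
| `del_fraction` | 0.863 | 1,466 / 1,698 |
| length law | log-normal, median 50 kb, σ = 1.66, truncated ≥ 1 kb | mean ≈ 200 kb, matching the published average length |
| hotspots | 4 × 8 Mb, placement weight 0.5 | wide enough for a 2 Mb-window scan to recover at Jaccard ≥ 0.5; weight 0.5 gives the clustered regime the recovery tests presume |
| carrier-frequency law | Beta(2, 3.63), truncated ≥ 0.05 | mean 0.355 per the published average; truncation encodes "only variants segregating in ≥ 2 genomes enter the catalog" |
| `n_divergent`, `delta_freq` | 10, 0.6 | calibration choices for parameter-recovery testing (the study publishes no per-ecotype spectra) |
| `missing_rate` | 0.02 | typical svtyper missingness |

Genotypes follow Hardy–Weinberg on a biallelic presence allele: a carrier
frequency `f` implies allele frequency `a = 1 − sqrt(1 − f)` and dosage
`Binomial(2, a)`. Two conditionings make the truth labels mean what they
say: every locus is redrawn until it has ≥ 2 observed carriers (so
generated catalogs pass `filter_cnvs` unchanged), and each planted
divergent locus is redrawn until its **observed** between-group
carrier-frequency difference is ≥ `delta_freq`. Without the second
conditioning, binomial sampling at n = 10 leaves the realized difference
below the nominal one about half the time, and "planted" would not describe
the emitted data — a regime in which even an oracle ranking loci by their
realized frequency difference cannot reliably find the planted set.

What the generator does **not** emulate: SV-caller error processes beyond
genotype missingness (no breakpoint jitter, no genotyping error), linkage
between loci (genotypes are independent across loci), population structure
beyond the two-group mean shift, reference bias, or read-level data. A
green recovery test therefore establishes that the statistics behave
correctly on data with the stated marginal structure — not that any caller
output is trustworthy.

## Numerical choices and degenerate inputs

* Quantiles: R type 7 (linear interpolation), documented wherever used.
* KS p value: 100-term alternating Kolmogorov series, clamped into (0, 1];
  `D = 0` gives `p = 1` exactly.
* Welch test refuses groups with < 2 values or zero total variance.
* Empty filtered catalogs summarize to zero counts with `NaN` frequency.
* All-equal window tracks produce no hotspots (strict threshold).
* Mean imputation happens before the zero-variance drop, so a locus missing
  in every sample is dropped, not imputed to a constant.
* Seeds: every stochastic step takes an explicit integer seed (< 2³¹) and
  restores the caller's RNG state (`with_seed`), so library calls never
  perturb user randomness.

## Known limitations

* The KS p value is asymptotic; for very small catalogs (tens of loci) a
  permutation approach on `ks_two_sample` is preferable.
* Hotspot intervals overreach their CNV clusters by up to one window width
  per side, and the scan assumes hotspots occupy ≪ 2.5% of windows.
* The DAPC scan supports exactly two groups; multi-group discrimination and
  cross-validated PC selection are out of scope.
* GO-term enrichment of overlapped genes requires an external annotation
  database and is deliberately not implemented; annotation strings are
  carried through for reporting only.
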