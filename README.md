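# cnvscape

Downstream analysis of multi-sample copy number variant (CNV) catalogs
from short-read population sequencing.

SV pipelines in the LUMPY/svtyper family emit a joint VCF of deletions and
duplications (`SVTYPE`/`END` in INFO, a diploid `GT` per sample). For
population studies — particularly in wild species, where CNVs are a rich
but under-used source of adaptive variation — the scientific questions
start *after* that VCF exists: how big is the segregating CNV catalog, is
it spatially clustered into hotspots, which genes does it hit, and which
loci differentiate predefined groups of individuals such as ecotypes?
`cnvscape` answers those questions with a tested, deterministic pipeline,
and ships a truth-known synthetic-data generator so every stage can be
validated without touching real data.

## What it computes

* **Catalog filtering and summaries** — keep loci ≥ `min_length` (1 kb)
  carried by ≥ `min_carriers` (2) individuals; report DEL/DUP counts, mean
  length, per-sample burden, carrier frequencies, union coverage of the
  assembly, and a Welch *t* comparison of deletion vs duplication lengths.
* **Spatial randomness** — a genome-wide two-sample Kolmogorov–Smirnov test
  between CNV midpoints and a seeded uniform sample of non-CNV positions:
  `D = sup_t |F̂_CNV(t) − F̂_bg(t)|`, p from the asymptotic Kolmogorov
  distribution at `sqrt(n_eff) D`.
* **Hotspots** — CNV counts in 2 Mb windows paced every 1 kb; windows
  strictly above the genome-wide 97.5% count quantile merge into hotspot
  intervals with member-CNV counts.
* **Gene overlap** — interval intersection of CNVs with GFF3 gene models
  (≥ 1 shared bp, strand-blind, half-open arithmetic), with per-type means
  that include zero-overlap CNVs.
* **Ecotype divergence (DAPC)** — PCA of the dosage matrix, a closed-form
  two-group discriminant `w ∝ W⁻¹(μ₁ − μ₂)` on the retained PC scores,
  per-locus contributions (squared composite loadings summing to 1), and
  selection of the `ceiling(q · n_loci)` top contributors (`q = 0.025`),
  plus a label-permutation null.
* **Synthetic data** — seeded genomes, gene models and genotyped catalogs
  with planted hotspots and planted divergent loci (Hardy–Weinberg
  genotypes from carrier frequencies), for end-to-end validation.

## Worked example

```r
library(cnvscape)

p      <- sim_params(seed = 1)            # 10+10 samples, 500 loci, 1.6 Gbp
genome <- simulate_genome(p)
sim    <- simulate_cnv_catalog(genome, p)

catalog <- filter_cnvs(sim$table)         # >= 1 kb, >= 2 carriers
summarize_catalog(catalog, genome)
#> CNV catalog summary
#>   loci:               500 (425 DEL, 75 DUP)
#>   mean length:        220559.1 bp
#>   per-sample count:   mean 184.10, range 165-201
#>   mean carrier freq:  0.376
#>   genome coverage:    79759047 bp (5.0%)
#>   scaffolds with CNV: 8

ks <- spatial_randomness_test(catalog, genome, seed = 1)
#> KS D = 0.154, p = 1.42e-05                  (clustered, as planted)

hs <- detect_hotspots(window_counts(catalog, genome), table = catalog)
#> 5 hotspots holding 279 CNVs (mean 55.80, max 72 per hotspot)

genes <- simulate_gene_models(genome, 1000, seed = 2)
overlap_cnv_genes(catalog, genes, genome = genome)
#> CNV x gene overlap: 60 of 500 CNVs (12.0%) overlap 60 distinct gene(s) [88 pairs]

model <- fit_dapc(encode_dosage(catalog))
#> <dapc_model> 16 PCs retained (89.0% of variance), groups migratory vs sedentary,
#>   500 loci; top contribution 0.0356

hits <- select_divergent(model)           # ceiling(0.025 * 500) = 13 loci
sum(sim$truth$divergent_locus_ids %in% hits$locus_ids)
#> 10 of 10 planted divergent loci recovered
```

Reading the numbers: the deletion share (425/500 = 0.85) and mean length
(~220 kb) follow the generator's published-anchored defaults; the tiny KS
p confirms the planted clustering; the five detected hotspot intervals
cover the four planted 8 Mb hotspots (window merging can split or flank
them); and all ten loci planted with a 0.6 carrier-frequency contrast
between ecotypes land in the 13-locus upper tail of the DAPC loading
contributions.

The same pipeline runs on real files via the CLI:

```sh
Rscript -e 'cnvscape::cli_main()' simulate     --out-dir fixtures --seed 7
Rscript -e 'cnvscape::cli_main()' characterize \
    --vcf fixtures/cnvs.vcf --genome fixtures/genome.fai \
    --gff3 fixtures/genes.gff3 --groups fixtures/groups.tsv --out-dir out
Rscript -e 'cnvscape::cli_main()' dapc \
    --vcf fixtures/cnvs.vcf --genome fixtures/genome.fai \
    --groups fixtures/groups.tsv --out-dir out --n-perm 99
Rscript -e 'cnvscape::cli_main()' report --out-dir out
```

Outputs are TSV/BED/JSON; logs go to stderr; every stochastic step is
seeded and the seeds are echoed into the JSON summaries.

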