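Package: cnvscape
Title: Copy Number Variant Landscape Characterization and Ecotype
    Divergence Scans
Version: 0.1.0
Authors@R:
    person("cnvscape", "developers", email = "cnvscape@example.org",
           role = c("aut", "cre"))
Description: Tools for the downstream analysis of multi-sample structural
    variant catalogs from short-read population sequencing (LUMPY/svtyper
    style VCFs). Filters deletion/duplication calls into a copy number
    variant (CNV) catalog, computes genome-architecture summaries
    (per-sample burdens, carrier frequencies, genome coverage), tests
    spatial non-randomness with a two-sample Kolmogorov-Smirnov statistic,
    detects CNV hotspots with a sliding-window upper-tail scan, intersects
    CNVs with gene models, and identifies group-divergent loci with a
    discriminant analysis of principal components (DAPC) implemented from
    first principles. A seeded synthetic-data generator produces
    truth-known fixtures (genome index, gene models, genotyped CNV
    catalogs with planted hotspots and divergent loci) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    optparse,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
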