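# gcfkit

Conservation analysis of fungal biosynthetic gene cluster (BGC) families.

Filamentous fungi — the Hypocreales especially — encode far more secondary
metabolites than have ever been characterized. Comparative questions about
that hidden chemistry (which clusters are conserved across genera? are any
families exclusive to insect-pathogenic lineages? do family sizes follow a
power law or a lognormal? are a family's genes switched on during
infection?) all run through the same pipeline: group BGCs into **gene
cluster families (GCFs)** by domain-architecture similarity, then analyse
the families. `gcfkit` implements that pipeline for computational
mycologists and natural-product genome miners, with a synthetic-data
generator carrying known ground truth so every stage is testable end to
end.

## What it computes

For two same-class BGCs with ordered domain copies, similarity is a
weighted mix of three architecture components,

```
s(a,b) = w_J * Jaccard + w_A * adjacency + w_D * DSS,      d = 1 - s,
```

(domain presence, domain order via adjacent pairs, and greedy-matched
copy-sequence similarity; weights default to 0.2 / 0.05 / 0.75). Families
at cutoff `c` are connected components of the graph with edges where
`d <= c`, swept over cutoffs 0.1–0.9 with a knee rule to pick the working
cutoff. Family sizes are fitted by discrete maximum likelihood —

```
power law    p(k) = k^(-alpha) / zeta(alpha, xmin)
lognormal    p(k) ∝ dlnorm(k; mu, sigma)     (renormalized over k >= xmin)
exponential  p(k) ∝ exp(-lambda k)
```

— and compared with Vuong's likelihood-ratio test plus bootstrap
stability intervals. Families are classified as singleton /
genus-specific / multi-genus (chi-square, df = 2), screened for
exclusivity to entomopathogenic genera, and BGC genes are scored for
infection induction from RNA-seq counts (median-of-ratios size factors, a
log2 variance-flattening transform, infection-minus-control means).

## Worked example

```r
library(gcfkit)

sim <- simulate_dataset(sim_config(seed = 7))   # planted families + orphans
summarize_by_class(sim$records)
#> BGC class summary: 215 BGCs
#>            NRPS            PKSI        PKSOTHER PKS-NRP_HYBRIDS         TERPENE
#>              89              39              13              31              24
#>           RIPPS          OTHERS
#>               0              19
#> largest class: NRPS  smallest class: PKSOTHER
#> genomes: 47  mean BGCs per genome: 4.57

edges <- pairwise_distances(sim$records)        # within-class distances
sw    <- sweep_cutoffs(edges, sim$records)      # 0.1 ... 0.9 grid
cut   <- select_cutoff(sw, "knee")              # -> 0.4 on this dataset
asg   <- attr(sw, "assignments")[[as.character(cut)]]
asg
#> GCF assignment at cutoff 0.40: 215 BGCs in 83 families (53 singletons)

spec <- classify_specificity(asg, sim$records)
spec
#> GCF taxonomic specificity ( 83 families ):
#>   singleton           53  (63.9%)
#>   genus_specific      14  (16.9%)
#>   multi_genus         16  (19.3%)
specificity_chi_square(spec)$chi2               # 34.9 on df = 2

compare_models(asg$sizes$size)$tests
#>     model_a     model_b  statistic     p_value           favored
#>    powerlaw   lognormal -0.8947835 0.370902817 indistinguishable
#>    powerlaw exponential  2.1012772 0.035616638          powerlaw
#>   lognormal exponential  2.7147662 0.006632257         lognormal
```

The class summary mirrors the configured class abundances; most BGCs sit
in singleton or genus-specific families (hence the large chi-square
against a uniform null), and at ~200 families the power-law and lognormal
size models are statistically indistinguishable while both beat the
exponential — exactly the behaviour expected of heavy-tailed family sizes
at modest sample size.

Expression scoring on a planted induction signal:

```r
meta <- data.frame(sample_id = sprintf("s%02d", 1:12),
                   condition = rep(c("infection", "saprophytic_control"), each = 6))
cnt  <- simulate_counts_matrix(1000, meta, induced_genes = sprintf("gene%04d", 1:10),
                               log2fc = 2, dispersion = 0.05, seed = 94)
sc   <- bgc_induction_scores(vst_like_transform(cnt), meta,
                             bgc_gene_set("GCF_1", sprintf("gene%04d", 1:10),
                                          backbone = "gene0001"))
sc$per_bgc   # 1.937 — the planted log2 fold change of 2, recovered
```

A command-line front end over the same functions ships in
`inst/cli/gcfkit.R`:

```sh
Rscript inst/cli/gcfkit.R report --seed 7 --out-dir out/
```

writes the inventory, distance edges, sweep table, clustering,
specificity, exclusivity, and induction-score TSVs plus a JSON run
manifest.

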