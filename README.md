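# comorbnet

Cross-disease molecular linkage analysis with weighted interaction
networks.

## What problem this solves

When two diseases co-occur clinically — say an inflammatory condition
that is aggravated by a metabolic one — a natural first question is
which genes and pathways the two share. A common study design answers
it asymmetrically: disease A is represented by one or more two-group
transcriptome datasets (affected vs. control), disease B by a curated
catalog of disease-associated genes. `comorbnet` implements the full
downstream analysis of that design as a tested, reusable R pipeline:

1. **Differential expression** (`fit_gene_stats`, `screen_degs`,
   `union_degs`): per-gene two-sample *t* tests with optional
   empirical-Bayes variance moderation. The moderated statistic shrinks
   each gene's variance toward a prior estimated by the method of
   moments on the log sample variances,
   `s²_post = (d₀·s₀² + d_g·s²_g) / (d₀ + d_g)`, and is referred to
   `d₀ + d_g` degrees of freedom. Genes with *p* < 0.05 and
   |log₂FC| ≥ 1 are screened as DEGs; datasets are analysed separately
   and their DEG sets unioned.
2. **Over-representation analysis** (`ora_test`, `enrich_catalog`,
   `shared_significant_terms`): exact hypergeometric upper-tail tests
   of a gene set against GMT term catalogs, Benjamini–Hochberg
   adjustment, and detection of terms significant in *both* diseases.
3. **Network construction and hubs** (`read_string_edges`,
   `induce_network`, `top_hubs`, `hub_subnetwork`): weighted PPI
   networks from STRING-dialect edge tables (combined association
   score, CAS ∈ [0,1]), per-disease induced subnetworks, and the top-20
   hub genes by degree.
4. **Leader genes** (`comscore`, `kmeans_1d`, `tukey_kramer`,
   `leader_class`): each node's *comscore* (weighted degree, the sum of
   incident CAS) is partitioned into five classes by **exact**
   one-dimensional K-means (dynamic programming, no random
   initialisation), followed by one-way ANOVA and Tukey–Kramer
   pairwise comparisons at *p* < 0.01 with a compact letter display.
   Leader genes are the members of the highest-mean class when it is
   significantly separated from every lower class.
5. **Cross-talk and modules** (`merge_networks`, `cross_talk_genes`,
   `mcode_complexes`, `annotate_module`): the two networks are merged
   (max-CAS rule), cross-talk genes are the exact intersection of the
   DEG union with the disease-B catalog, and dense modules are found by
   a from-scratch Molecular Complex Detection (MCODE-style) clustering:
   vertices are weighted by `k × density` of the highest k-core of
   their closed neighborhood, complexes grow from heavy seeds within a
   vertex-weight-percentage tolerance, and each module's members are
   annotated as common / disease-A-only / disease-B-only.

A synthetic-data module (`simulate_expression`, `simulate_ppi`,
`simulate_catalogs`, `default_fixture`) generates every input with
planted ground truth, so the whole pipeline is testable end-to-end
without any database download.

## Worked example

```r
library(comorbnet)

fx <- default_fixture(seed = 1)          # synthetic two-disease study
paths <- write_fixture(fx, "inputs")
cfg <- pipeline_config(
  expression    = paths$expression,      # two datasets, 2000 genes, 6 vs 6
  groups        = paths$groups,
  disease_genes = paths$disease_genes,   # 300-gene curated catalog
  edges         = paths$edges,           # ~5,300-edge weighted interactome
  catalog       = c(terms = paths$catalog),
  out_dir       = "results_run")
bundle <- run_pipeline(cfg)

length(bundle$deg_union)       # 268   genes pass the DEG screen (union)
unlist(bundle$shared_terms)    # "TERM001"  the one shared enriched term
length(bundle$cross_talk)      # 92    cross-talk genes (DEGs in catalog B)
bundle$topology
#    network nodes edges degree_min degree_median degree_max isolated
#   diseaseA   268   362          0             1         21      108
#   diseaseB   300   282          0             0         18      153
#     merged   476   479          0             1         21      209
length(bundle$leaders$A)       # 18    leader genes (top comscore class)
length(bundle$modules)         # 3     top dense modules, origin-annotated
```

Against the generator's planted truth this run recovers 100% of the
planted differential genes at a 1.1% false-discovery proportion, finds
the planted shared term as the unique shared significant term, returns
the planted 92-gene cross-talk set exactly, and recovers every planted
dense module (Jaccard ≥ 0.9); the 18 leader genes are exactly the
planted top-comscore module. Every stage writes its tables (TSV),
gene lists (TXT) and networks (GraphML) under `out_dir`, and reruns
are byte-identical.

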