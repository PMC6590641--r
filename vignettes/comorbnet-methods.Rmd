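---
title: "Methods: cross-disease linkage analysis in comorbnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-disease linkage analysis in comorbnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbnet)
```

# The study design

`comorbnet` analyses a deliberately asymmetric two-disease design.
Disease A enters as one or more two-group expression datasets on the
log2 scale; disease B enters as a curated list of disease-associated
gene symbols, the form in which gene–disease catalogs distribute their
knowledge. The pipeline looks for molecular links between the two
diseases at four levels: shared enriched terms, shared network hubs,
shared leader genes, and cross-talk genes embedded in dense interaction
modules. All gene identity is by upper-cased symbol, because public
resources mix casings (IL-6, IL6, il6).

# Differential expression

Each dataset is analysed separately with a per-gene equal-variance
two-sample *t* test on the log2 values, so the effect estimate is the
log2 fold change (case minus control mean). With
`moderation = TRUE` (the default) the per-gene variances are shrunk
before testing. The model is the standard empirical-Bayes hierarchy:
gene variances are draws from a scaled inverse-chi-square prior with
scale $s_0^2$ and degrees of freedom $d_0$, so the posterior variance is

$$ s^2_{post} = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}, $$

and the moderated $t = \mathrm{logFC} / (s_{post}\sqrt{1/n_1 + 1/n_2})$
is referred to $d_0 + d_g$ degrees of freedom. The hyper-parameters are
estimated by the method of moments on the log sample variances: with
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$,

$$ \psi'(d_0/2) = \mathrm{var}(e) - \psi'(d_g/2), \qquad
   \log s_0^2 = \bar e + \psi(d_0/2) - \log(d_0/2), $$

where $\psi$ and $\psi'$ are the digamma and trigamma functions. The
trigamma inversion is a Newton iteration with relative tolerance
1e-10; when the moment estimate of $\mathrm{var}(e)$ does not exceed
$\psi'(d_g/2)$ the prior is taken as infinitely informative
($d_0 = \infty$, all genes share $s_0^2$). At the other extreme,
$d_0 = 0$ recovers the ordinary *t* exactly — the test suite asserts
this limit, and checks the whole computation against an independently
coded transcription of the formulas (and against `limma`) on a fixed
6-gene, 4-vs-4 matrix.

Degenerate genes are handled explicitly: zero pooled variance with zero
fold change is reported as $p = 1$ (no evidence), zero pooled variance
with a nonzero fold change under the unmoderated test as $p = 0$, with
a log message.

The DEG screen keeps genes with $p < 0.05$ (strict) and
$|\mathrm{logFC}| \ge 1$ (inclusive). No multiple-testing adjustment is
applied at this stage — the screen is the conventional raw-p one, and
the |logFC| requirement is what controls the false calls in practice.
DEG sets from multiple datasets are combined by identity-only union; a
gene significant in opposite directions in two datasets is kept once
and the conflict is logged, not resolved.

# Over-representation analysis

`ora_test` is the exact hypergeometric upper tail
$P(X \ge \mathrm{overlap})$ with universe size $N$, term size $K$
within the universe, and study size $n$ within the universe.
Adjustment is Benjamini–Hochberg (the field default; exposed as
`bh_adjust`), and a term is significant at $q < 0.05$ by default. Terms
with fewer than `min_term = 3` genes in the universe are not tested —
smaller terms cannot be meaningfully enriched and only spend
multiple-testing budget. Enrichment tables are sorted by ascending
$p$ with term-id tie-breaks, so catalog order never matters.

The background universe is a genuine design choice the data do not
make for you. The package defaults to the measured universe (all genes
on the expression platform) for both sides, and offers
`disease_universe = "catalog"` (all catalog genes plus the disease
list) for the disease-list side, where no platform exists. Shared
terms are the intersection of the two significant term-id sets — note
that an empty intersection is a perfectly ordinary outcome for one
catalog and a singleton for another.

# Networks, hubs, comscore and leader genes

Edge tables use the STRING dialect (`protein1 protein2
combined_score`), with integer scores on 0–1000 divided by 1000 on
read. The default confidence floor is `score_min = 0.4`, the
conventional "medium confidence" cut; duplicates keep the maximum
score and self-loops are dropped with a logged count. Disease networks
are induced on the DEG union and the disease list respectively;
members without any retained interaction stay as isolated nodes so
that node counts are well-defined, and the isolated count is reported
separately in the topology summary.

Hubs are the top `top_n_hubs = 20` nodes by unweighted degree; the
weighted degree (comscore) and then the symbol break ties, making the
ranking total and reproducible.

The **comscore** of a node is the sum of the combined association
scores of its incident edges — a confidence-weighted connectivity. The
leader-gene procedure partitions the comscores of each disease network
into `k = 5` classes. Instead of randomized Lloyd iterations the
package computes the *globally optimal* one-dimensional K-means by
dynamic programming over the sorted scores ($O(k n^2)$ with prefix
sums): in one dimension the optimum is a contiguous partition of the
sorted values, so it is exactly computable and byte-reproducible.
Classes are labelled in ascending order of class mean. Two properties
are asserted in the tests: the partition's SSE equals the exhaustive
minimum over all contiguous partitions (for small instances), and
scaling every CAS by a constant leaves the assignment unchanged.

The classes are then compared by one-way ANOVA ($F = MSB/MSW$) and
Tukey–Kramer pairwise tests at `alpha = 0.01`,

$$ q_{ij} = \frac{|\bar x_i - \bar x_j|}
   {\sqrt{(MSW/2)(1/n_i + 1/n_j)}}, $$

referred to the studentized-range distribution with $k$ groups and
$N - k$ degrees of freedom; with equal class sizes this reduces to the
classic Tukey HSD. The compact letter display is built from the
maximal cliques of the non-significance graph (exact for the small
class counts used here), so classes share a letter exactly when they
are not significantly different. **Leader genes** are the members of
the highest-mean class, provided that class is significantly separated
from every lower class — it carries a unique letter. If the top two
classes are indistinguishable the leader set is empty, with a warning,
rather than silently taking an unsupported class.

One caveat is inherited from the procedure itself: the ANOVA is
computed on the same scores that were used to form the classes, so it
is circular by construction and describes separation, not confirmatory
inference. The package reproduces the conventional analysis and
documents the circularity instead of "correcting" it.

# Merging, cross-talk genes and module detection

The merged network is the node and edge union of the two disease
networks, a shared edge keeping the maximum CAS (which makes merging
commutative and idempotent — both are asserted as invariants). Each
node's origin (A-only, B-only, both) is recorded. Cross-talk genes are
the exact intersection of the DEG union with the disease-B catalog.

Module detection re-implements the Molecular Complex Detection scheme
from its published definition, on topology alone — edge weights do not
enter, since density is the object of interest. Every vertex is
weighted by $k \times \mathrm{density}$ of the highest k-core of its
closed neighborhood, where the k-core is found by minimum-degree
peeling. Complexes grow breadth-first from still-unused seeds in
descending weight order (ties broken by symbol), admitting neighbors
whose weight is at least $(1 - \mathrm{vwp})$ of the seed weight, with
the canonical defaults `vwp = 0.2`, haircut on, fluff off. Haircut
iteratively removes members with fewer than two within-complex
interactions; when it removes the original seed, the complex is
re-seeded with its heaviest remaining member so the "seed is a member"
invariant always holds. Complexes score density × size and the top
`top_k_modules = 3` are annotated and exported by default, mirroring
the usual practice of reporting a handful of top modules; the setting
is exposed because published analyses rarely state how many complexes
they kept.

A structural note on bridged complexes: if two dense complexes are
joined by a *direct* edge, members of either side pass any
vertex-weight threshold, so seeded expansion necessarily returns them
as one complex — that is the algorithm's defined behavior, not a bug.
Separation is only expected when complexes connect through low-weight
linker nodes, and that is how the recovery tests are constructed.

# The synthetic-data module

The generators produce every input the pipeline consumes, each a pure
function of its parameters and seed:

* `simulate_expression` — baseline levels uniform on log2 8 ± 4,
  per-gene noise standard deviations drawn from a scaled
  inverse-chi-square spread (`sigma^2 * d0 / chisq(d0)`, default
  `d0 = 8`), so the moderated test's variance model is actually
  satisfied; planted genes are shifted by `effect_lfc` with
  alternating sign, so the absolute-value screen is exercised both
  ways.
* `simulate_ppi` — a planted-partition graph: within-module edge
  probability `p_in`, background probability `p_out`, CAS uniform on
  `[cas_low, cas_high]` for background edges and on
  `[max(cas_low, 0.7), cas_high]` for module edges, so planted modules
  carry a high-confidence signal the comscore stages can recover.
  Scores are quantised to three decimals, which makes the 0–1000
  STRING dialect lossless on a write–read round trip.
* `simulate_catalogs` — a disease list containing an exact planted
  overlap with the differential genes, and a GMT catalog whose first
  term draws about a third of its members from the
  differential-and-disease overlap, a third from differential-only and
  a third from disease-only genes — enriched in both studies by
  construction.

`default_fixture` combines these into the default study: 2,000 genes,
two datasets of 6 vs 6 samples with 6% and 8% planted differential
genes at |log2FC| 2 and noise scale 0.3, a 300-gene disease catalog
containing 92 planted differential genes, a background interactome at
`p_out = 0.0025` (about 5,000 edges), and a 50-term catalog. The
sample sizes, effect size and noise scale are typical of the small
tissue-biopsy microarray comparisons this design is used for; 92 is
the planted cross-disease overlap the catalog generator is asked for.

Four modules are planted as nested density strata: an 18-gene clique
inside the differential-and-disease overlap (the leader module),
13- and 8-gene cliques among differential-only genes, and a 10-gene
`p_in = 0.95` module among disease-only genes. The strata design is a
calibration, settled by pilot simulation before the acceptance tests
were frozen: with a single planted module, the optimal 1-D K-means
regularly splits the module's comscore cluster across the top two
classes (a few members pick up extra background edges and separate),
which defeats the purpose of a planted leader signal. Planting
intermediate-density strata gives the intermediate comscore classes
real structure to absorb, and the top class then captures the full
planted module across all piloted seeds. The distractor strata live
among differential-only genes so that no two planted modules can
co-occur in one induced network and be bridged by a background edge
(see the structural note above).

What the generator does *not* emulate: probe-level microarray
artifacts, normalization and batch effects, annotation ambiguity,
correlated genes, scale-free degree distributions, or
database-version drift in catalogs and interactomes. Passing the
planted-truth tests therefore demonstrates that the algorithms recover
what they are defined to recover under their own model assumptions —
it says nothing about the biological validity of any particular real
dataset's output.

# Numerical and reproducibility choices

* All generators take explicit seeds; the pipeline writes
  deterministically ordered, canonically formatted files, so reruns
  are byte-identical (asserted in the tests).
* Edge canonicalisation (`from < to`, sorted rows) makes network
  equality and file round trips exact; CAS is held to three decimals.
* K-means ties among equal scores follow stable sort order; seed ties
  in MCODE and letter-ordering ties in the Tukey display are broken
  lexicographically.
* The acceptance checks run at deliberately small problem sizes — the
  full default fixture (2,000 genes), 500 random graphs of at most 8
  nodes for the vertex-weight oracle, 200 instances of at most 12
  points for the K-means oracle — sizes at which the exhaustive
  oracles are exact and fast.

# Interfaces

The package's surface is its exported functions; `pipeline_config()`
plus `run_pipeline()` orchestrate the whole analysis and write every
intermediate (TSV/TXT/GMT/GraphML plus a key=value MANIFEST) to the
output directory, which is the package's equivalent of a command-line
driver: each stage is equally callable on its own, which is what an
analyst actually wants from an R toolkit. `scripts/acceptance.R` is a
thin Rscript over the installed package that regenerates the default
fixture and reports the recovery quantities as JSON.

# Known limitations

* The leader-class rule is strict: if the top two comscore classes are
  not separated at `alpha`, the leader set is empty by design.
* Hub ranking uses unweighted degree; comscore only breaks ties. On
  networks with near-uniform degree the ranking is mostly alphabetical
  and should be read accordingly.
* MCODE complexes are disjoint (pre-fluff); overlapping-complex
  variants are out of scope, as are other community-detection
  families.
* The enrichment stage tests each catalog independently; no
  term-hierarchy (GO graph) awareness.
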