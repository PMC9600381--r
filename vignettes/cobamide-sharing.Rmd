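---
title: "Inferring cobamide sharing from metagenomic functional profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cobamide sharing from metagenomic functional profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cobashare)
```

## The problem

Cobamides — the vitamin B12 family of cofactors — are required by most
bacteria but synthesized *de novo* by few. In a community like the skin
microbiome this asymmetry predicts nutrient sharing: a small set of
producers supplies a much larger set of cobamide-dependent users, and that
dependency should leave a trace in community structure. `cobashare` turns
raw profile-HMM and covariance-model search results against shotgun
metagenomes into the quantities that test this prediction: who can make
cobamides, who needs them, how producers and users co-occur in association
networks, and how producer abundance relates to community diversity.

This vignette documents the model and the methodological choices, their
defaults and units, what the synthetic-data generator does and does not
emulate, and the numerical conventions.

## Read profiling

Metagenomic reads are six-frame translated (standard genetic code, stops as
`*`, fuzzy codons as `X`, partial trailing codons dropped) and searched
against profile HMMs for cobamide biosynthesis, transport and dependence
genes. The pipeline then applies, in order:

1. **E-value cutoff** — hits with independent E-value above `evalue_max`
   (default 1e-6) are discarded. The same cutoff applies to the Infernal
   riboswitch search.
2. **Best-hit deduplication** — a read aligning to multiple HMMs keeps the
   hit with the lowest E-value; E-value ties are broken by the highest bit
   score. Residual ties are broken by the lexicographically smallest model
   name: the criterion "lowest E and/or highest bit score" does not decide
   exact double ties, and a deterministic tie-break keeps reruns
   bit-identical.
3. **Coverage-based presence** — a gene counts as present in a sample only
   when the union of its hit envelopes (in HMM coordinates, 1-based
   inclusive on input) covers at least `min_coverage` (default 0.20,
   boundary inclusive) of the model length. Coverage is pooled across taxa
   within the sample: the criterion is about whether the *gene* is
   represented in the sample at sufficient breadth, before asking who
   carries it. Gating happens before taxonomic aggregation for the same
   reason.
4. **Normalization** — per (sample, gene, taxon): `norm_length` =
   raw hits / HMM length, for within-sample comparisons across genes of
   different lengths; `norm_length_depth` = `norm_length` / total post-QC
   reads × `depth_scale`, for cross-sample comparisons. `depth_scale`
   defaults to 1e6, i.e. hits per HMM-length-unit per million reads —
   "sequencing depth" fixes only the quantity, not the scale, and
   per-million is the conventional choice.
5. **Rare-pair filtering** — a (gene, taxon) pairing survives only when it
   appears (≥ 1 retained read) in at least `min_samples` (5) samples
   spanning at least `min_datasets` (2) studies. "Appears" means one
   retained read: the weakest reading, which makes the filter a pure
   support test. The filter is idempotent.

Reads without a species-level classification are aggregated under the
reserved taxon `"unclassified"`, which is excluded from producer calls and
from false-positive accounting (it is neither a true nor a false
assignment).

**Producer calls.** A taxon is called a *de novo* producer when it retains
reads for at least `producer_min_markers` (5) distinct genes of the
marker panel. The panel defaults to 10 markers: the 11-marker biosynthesis
panel minus `bluB`, because documented producers of nonbenzimidazolyl
cobamides lack `bluB`, and requiring it would misclassify them. Both the
panel and the threshold are configurable; the shipped identity of the
panel (six corrin-ring genes, four nucleotide-loop genes) is this
package's documented default, not a community standard.

**Mock-community accounting.** `mock_false_positive_rate()` is the
fraction of classified hits assigned to taxa not placed in the mock
community. Under a planted Bernoulli false-assignment rate the estimate is
binomial, so validation accepts deviations up to three binomial standard
errors.

## Genome classification

The pathway model divides de novo biosynthesis into ordered subsections —
tetrapyrrole precursor synthesis, corrin ring synthesis (parallel aerobic
`cob` and anaerobic `cbi` series), nucleotide loop synthesis and lower
ligand synthesis. Aerobic/anaerobic orthologue pairs (e.g. cobJ/cbiH,
cobQ/cbiP) satisfy a requirement through either member; corrin-ring
completeness is the better of the two routes after that mapping.

Category rules (all configurable via `category_rules()`):

* **producer** — corrin-ring completeness ≥ 0.5 *and* nucleotide-loop
  completeness ≥ 0.5;
* **salvager** — otherwise, ≥ 3 of the 4 salvage gene slots (cobQ/cbiP,
  cobD/cbiB, cobP/cobU, cobS) present;
* **nonproducer** — otherwise.

The exact scoring thresholds used in published category assignments live in
external supplemental material; the 0.5/0.5/3 defaults reproduce the
category semantics (full or near-full ring + loop for producers,
loop-only for salvagers) without inventing unstated specifics as fixed
truths, and every classification returns the rule that fired as a decision
trace. `bluB` is stored as a lower-ligand capability flag and never
required for producer status. `cbiZ` (cobamide remodeling) is excluded from
scoring. Dependence is the presence of at least one of seven
cobamide-dependent enzyme families (B12-dependent RNR, metH,
methylmalonyl-CoA mutase, ethanolamine ammonia lyase, glycerol/diol
dehydratase, d-ornithine 4,5-aminomutase, epoxyqueuosine reductase),
represented by the symbols nrdJ, metH, mutA, eutB, pduC, oraE, queG.

Genome-level group contrasts (e.g. genome length between host- and
environment-associated species) use a two-sided Mann–Whitney U test, exact
for small tie-free groups and normally approximated with tie correction
otherwise.

## Association networks

Counts are compositional, so inference runs on centered log-ratio
transformed data: per sample, add `pseudocount` (default 1), close to
proportions, take logs and center. With pseudocount 0 the transform is
invariant to per-sample scaling, which is the point of using it.

**Neighborhood selection.** Each species' CLR abundance is regressed on all
others with an L1 penalty (solved by glmnet) along a path of
`n_lambda` = 20 penalties log-spaced from λ_max — the largest absolute
off-diagonal correlation of the CLR columns, above which every
neighborhood is empty — down to λ_max × `lambda_min_ratio` (0.01).
Directed selections are symmetrized with the OR rule by default; an edge's
weight is the mean of the two directed coefficients and its sign the sign
of that mean. Exact zeros after symmetrization (opposite-signed directed
coefficients of equal magnitude) carry no interpretable sign and are
dropped.

**StARS.** `stars_subsamples` = 50 subsamples without replacement of size
min(⌊10√n⌋, ⌊0.8 n⌋) are refit over the full-data path; the per-penalty
instability is the mean over node pairs of 2ξ(1−ξ) with ξ the edge
selection frequency. The chosen penalty is the densest whose monotonized
instability stays ≤ 0.05. These are the reference defaults of the
stability-selection literature; the source analyses state only
"neighborhood selection mode", so all of them are exposed in
`network_params()`. When no penalty meets the threshold the sparsest is
returned with a warning rather than an error, since that is always a
defensible conservative answer.

**Species filter.** Applied on the pooled samples of all studies —
one shared roster (> 0.015% mean relative abundance and ≥ 55% prevalence),
then networks are inferred per study so the consensus compares like with
like.

**Consensus.** An edge enters the consensus when it appears with identical
sign in ≥ `consensus_min_support` (2) per-study networks; its weight is
the mean of the contributing weights. Sign-conflicting edges are evidence
of instability and are dropped regardless of support. Nodes untouched by a
kept edge are dropped from consensus networks (noted in the output), since
isolated nodes say nothing about associations.

**Metrics.** Density, global transitivity, greedy-agglomerative modularity
and Newman nominal assortativity over phylum labels are computed with
igraph on the unsigned graph. Edge categories enumerate unordered pairs of
endpoint categories; the "sharing" percentage counts edges joining a
producer to a cobamide-dependent salvager or nonproducer — the network
signature of the sharing hypothesis.

## Community statistics

* **Rarefaction** is an exact multivariate hypergeometric draw (sequential
  conditional `rhyper`), default depth 1.5 million reads; shallower samples
  raise a catchable `sample_discarded` condition rather than silently
  disappearing.
* **Shannon** uses the natural log by default (the convention of the
  ecology toolchain this package sits in); the base is an argument because
  published analyses do not always state it.
* **Bray–Curtis** is computed by vegan's `vegdist` after an optional
  square-root transform (default on, to up-weight low-abundance taxa).
  Pairs of all-zero samples are undefined and returned as `NA` with a
  warning.
* **Quartile grouping** of cumulative producer abundance uses strict
  inequalities — "below" 0.05% is Low, "above" 0.75% is High, boundaries
  are Mid — and the type-7 quantile rule when bounds are computed from
  data.
* **Rank tests**: Kruskal–Wallis with tie correction, Dunn's post hoc
  z-tests with Bonferroni multiplication capped at 1, two-sided
  Mann–Whitney U, and Spearman as Pearson on average ranks. Batch-effect
  adjustment across studies is out of scope; cross-study inputs are used
  as supplied.

## The synthetic-data generator

The generator produces every input dialect the parsers read, together with
the ground truth that produced it, so the whole pipeline can be validated
without any download.

* `make_community()` plants categories: producers carry the full pathway
  complement (all 10 producer markers, plus `bluB` with probability 0.7),
  salvagers exactly the salvage set, nonproducers neither; dependent
  species carry 1–3 of the 7 enzyme families; phyla rotate over the four
  major skin phyla.
* `simulate_hit_table()` draws per-sample species abundances log-normal
  (σ = 1 by default — a standard heavy-tailed microbiome abundance model
  that exercises rare-taxon code paths), allocates a multinomial
  `hits_per_sample` (default 2000) over (species, gene) cells with
  probability ∝ abundance × HMM length, and draws 100-position envelopes
  uniformly over models of 180–450 positions, so every truly expressed
  gene passes the 20% coverage gate from its first read while planted
  "trace" genes (envelopes confined to the first 15% of the model) are
  guaranteed to fail it. Classifier false positives are a flat Bernoulli
  reassignment to out-of-roster taxa. Deliberately *not* emulated:
  read-level sequence error, classifier confusion structure beyond the
  flat rate, strain-level variation, and gene-length-dependent
  classification bias — so passing tests demonstrate the correctness of
  the rules, not robustness to every artefact of real data.
* `simulate_count_matrices()` uses a normal-to-anything copula: the signed
  graph defines a sparse precision matrix (unit diagonal, off-diagonal
  −sign × 0.35, ridge-inflated to a minimum eigenvalue of 0.01), and
  latent Gaussian draws are mapped through the Gaussian CDF and a
  negative-binomial (or Poisson) quantile function. The copula preserves
  the planted graph's rank correlations — exactly what CLR-based inference
  consumes — which is why it is preferred over direct multivariate count
  constructions. Marginal means spread log-uniformly over 20–200 so
  discreteness does not drown the latent signal.

All generator randomness flows through one seeded stream per call
(`withr`-style local RNG), leaving the caller's RNG untouched; identical
(parameters, seed) give bit-identical output.

## Validation scale and numerical conventions

The validation suite runs at desk scale: planted-truth recovery uses a
3-study, 60-sample, 50-species community with 5 producers; false-positive
estimation uses 10⁵ hits at a planted rate of 0.1%; network recovery uses
a 30-node band graph at n = 800 samples per study with three generator
seeds, requiring edge precision ≥ 0.6 and recall ≥ 0.5 in the majority;
type-I calibration uses 2000-replicate null simulations. These sizes are
chosen so the full suite completes in a few minutes while keeping binomial
and subsampling noise well inside the stated tolerances.

Numeric parsing is C-locale with scientific notation; probability vectors
are checked to 1e-12; lasso convergence uses glmnet at threshold 1e-12
(validated against an independent coordinate-descent implementation to
1e-4 per coefficient); all genomic and HMM coordinates are 1-based
inclusive on input and converted to half-open intervals only inside
interval arithmetic. Reads aligning to HMMs in different samples are
treated as independent per sample: run-level reconciliation across samples
has no defensible semantics for per-sample presence calls.

## Known limitations

* Category thresholds and the marker-panel identity are documented
  defaults, not community standards; analyses sensitive to them should
  sweep the rules file.
* The consensus drops sign-conflicting edges outright; with many studies a
  support-weighted sign vote could retain more information.
* The copula generator plants rank-correlation structure only; it cannot
  test robustness to zero inflation beyond what the negative binomial
  produces.
* Riboswitch context assignment trusts the supplied GFF3 gene calls and a
  user gene→function map; it does not re-annotate products.
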