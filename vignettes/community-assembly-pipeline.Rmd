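---
title: "Diversity, assembly processes and co-occurrence networks for benthic microbial eukaryotes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity, assembly processes and co-occurrence networks for benthic microbial eukaryotes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sedcomm` re-implements, as a tested and reusable pipeline, the downstream
community-ecology analysis typically applied to benthic microbial-eukaryote
metabarcoding surveys: a transect of sediment sites, each cored at 1-cm
layers, characterised by an OTU count table, a rooted OTU phylogeny,
taxonomy assignments and per-sample environmental measurements (water
depth, bottom temperature and salinity, seven metal concentrations, three
grain-size fractions). The pipeline deliberately starts at the OTU table:
read quality control, chimera removal, OTU clustering and taxonomy
assignment are upstream concerns of other tools.

This vignette is the package's methods account: the statistics it
implements, the assumptions and conventions each one carries, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices a maintainer would want stated.

## Diversity

**Rarefaction.** Counts are subsampled without replacement to a common
depth — by convention the lowest sample total — in one seeded draw per
sample (`rarefy_table()`). Averaging over repeated draws is out of scope;
a single-table workflow keeps every downstream statistic attributable to
one concrete table. Samples below the target depth are dropped with a
warning rather than failing the run, since simulated or filtered tables
may legitimately contain shallow samples.

**Alpha diversity** (`alpha_diversity()`): OTU richness; Shannon entropy
in log base 2 (bits) — the base is configurable, but 2 is the default of
the sequence-processing toolchains this pipeline descends from; and
Faith's phylogenetic diversity in the *rooted* convention, i.e. the branch
length of the minimal subtree connecting the sample's tips *to the root*.
Whether PD includes the root path is a genuine one-constant ambiguity in
the literature; the choice here is fixed by tests (a sample containing all
tips has PD equal to the total tree length; `{A,B}` on the four-tip
cherry-pair tree has PD 3).

**Beta diversity**: Bray-Curtis on counts
(`BC = 1 - 2*sum(min)/sum(total)`) and unweighted UniFrac — the fraction
of branch length leading exclusively to one community's tips, over the
branch length leading to either, with all branches of the rooted tree
eligible. Principal coordinates analysis uses Gower double-centring;
negative eigenvalues are reported but excluded from coordinates and from
the proportion of variance explained.

## Community statistics

Spearman screens (midranks, two-sided t-approximation p-values) relate
alpha indices and taxon-group relative abundances to environmental
variables. ANOSIM uses the rank-based R statistic with seeded label
permutations (default 999). Environmental distance is Euclidean on
z-scored variables; geographic distance is haversine with Earth radius
6371 km. Mantel tests correlate lower triangles (Pearson) with joint
row/column permutation of the first matrix, **one-tailed for positive
association by default** — the ecological convention for distance-decay
questions; the tail is recorded in every result. The partial Mantel
variant residualises both matrices against the control and permutes the
residualised first matrix (residual permutation); if the control explains
a matrix completely the partial correlation is degenerate and defined as
0, flagged. Permutation p-values always carry the +1 correction, so
`p >= 1/(n_perm+1)`. SIMPER decomposes the mean between-group Bray-Curtis
into per-OTU contributions — the decomposition is exact and tested to
1e-10 — and is computed on the rarefied table, matching the analysis
order of the wider pipeline.

## Assembly processes

The core of the package quantifies, per sample pair, the evidence for
deterministic versus stochastic assembly:

* **bMNTD** — abundance-weighted mean distance from each taxon to its
  nearest relative in the paired community, on the tree's patristic
  distances. Weighted mode (within-sample relative abundances) is the
  default; unweighted mode uses uniform weights over present taxa.
* **bNTI** — the standardized effect size of bMNTD against a
  *taxa-shuffle* null: OTU identities are permuted across the tree's tips,
  999 times by default, and
  `bNTI = (obs - mean(null)) / sd(null)`. Pairs with identical membership
  have a degenerate null (every shuffle reproduces the observed value);
  they are reported `NA`, counted, and excluded from partition
  denominators.
* **RCbray** — Raup-Crick on Bray-Curtis: null communities preserve each
  sample's richness and total abundance, drawing taxa with probability
  proportional to occurrence frequency and individuals proportional to
  regional relative abundance; ties count half, and the null quantile is
  rescaled to [-1, 1].
* **Partition** — per pair: `bNTI > 2` variable selection; `bNTI < -2`
  homogeneous selection; otherwise `RCbray > 0.95` dispersal limitation,
  `RCbray < -0.95` homogenizing dispersal, else undominated ("drift" in
  common usage — the output label is `undominated` because the category is
  defined by the absence of a dominant process, not by drift alone).
  Boundary ties (`bNTI` exactly 2, `RCbray` exactly 0.95) fall on the
  stochastic side; the published threshold prose is ambiguous at exactly
  these points, and a deterministic convention matters more than which
  side is chosen.

The bMNTD and RCbray inner loops are in C++ (they are evaluated hundreds
of millions of times per analysis); both consume R's RNG, so `set.seed()`
governs them like any R code. bMNTD is verified against an explicit
brute-force double loop and against an independent nearest-taxon
implementation from the phylogenetic-ecology literature.

Two calibration facts, established by the test suite, are worth knowing.
First, on communities with no phylogenetic structure about 95-97% of bNTI
values fall in [-2, 2] — the null is slightly conservative rather than
exactly normal. Second, RCbray is *not* exactly centred for finite sample
counts even on data generated by its own null process: the null conditions
on the realized occurrence frequencies of the table, which injects a
positive bias that decays roughly as 1/n_samples (about +0.15 at 25
samples, +0.05 at 144). The calibration test therefore uses a large
sample count; users comparing small sample sets should expect mildly
inflated RCbray values.

## SparCC networks

OTUs with more than 20 total reads in a sample group enter the network
stage. SparCC estimates correlations robust to compositionality:
Dirichlet draws (unit pseudocount) convert counts to fractions; pairwise
log-ratio variances `t_ij = var(log x_i / x_j)` are reduced to basis
variances under the sparsity assumption (linear system
`(J + (D-2) I) w = t`); correlations follow as
`(w_i^2 + w_j^2 - t_ij) / (2 w_i w_j)`, clipped to [-1, 1]; the most
strongly correlated pair is iteratively excluded from the system and the
result averaged over 20 Dirichlet draws. Two stabilizations, both
documented in `sparcc()`: the working exclusion threshold is floored at
two standard errors of a log-ratio variance (`2*sqrt(2/(n-1))`), because
at small sample counts the conventional threshold of 0.1 sits *below* the
estimator's noise and excluding top noise pairs truncates the noise
distribution and biases the basis solve; and exclusion stops once
removing the top pair no longer shrinks the strongest remaining
correlation. Estimator noise at n = 200 samples is irreducibly about 0.05
per pair; bounds on the *maximum* off-diagonal error tighten only with
more samples, not more Dirichlet draws.

Significance comes from a permutation null (each OTU's counts shuffled
across samples independently; resampling with replacement is available),
with two-sided pseudo p-values under the +1 correction, adjusted by
Benjamini-Hochberg over the unique pairs. Edges require `|r| > 0.4` and
adjusted `p < 0.01`, both strict; a flag for thresholding on raw p-values
exists because published pipelines are ambiguous on this point, but
adjusted is the default. Isolated nodes are dropped, so reported node
counts mean "nodes with at least one edge". Topology: average degree,
density, average local clustering (isolates count 0), diameter and
average path length on the largest component with unweighted shortest
paths, modularity from seeded Louvain on |r| weights, and the percentage
of positive edges, plus per-taxon-group-pair positive-edge percentages.

## The synthetic-data generator

`simulate_scenario()` emulates the study design the pipeline targets: 9
sites on a line at 2.5 km spacing (configurable), 1-5 sediment layers per
site, environmental gradients along the transect (metals declining
seaward, temperature falling, salinity and water depth rising, Dirichlet
grain-size mixtures summing to exactly 100), a Yule phylogeny rescaled to
unit height, a Brownian niche trait from root value 0, and communities
assembled under a controllable regime, multinomially sampled to a fixed
depth (default 10,000 reads).

Regimes:

* **drift** — every sample is a multinomial draw from one shared
  lognormal regional profile; no structure at all.
* **selection** — the profile is multiplied by a Gaussian niche filter
  `exp(-(trait - env)^2 / (2 sigma_sel^2))`, plus sample-level lognormal
  noise and an occupancy lottery (each passing OTU colonises a sample
  with probability `occupancy`). Without those two stochastic layers,
  equal environments produce near-identical communities whose
  phylogenetic turnover is degenerate (0/0 in the bNTI null) — real
  communities always carry demographic turnover on top of the filter.
* **dispersal_limitation** — each site holds a sparse, independently
  re-weighted source pool; a sample's expected profile is the
  kernel-weighted mixture `exp(-kappa * distance)` over site pools. This
  produces distance decay of similarity at transect scale without
  per-individual migration bookkeeping.
* **mixed** — the filter applied to the dispersal-limited mixture.

Two generator parameters deserve their rationale spelled out:

* `trait_depth_power` (default 1 = plain Brownian motion). On a
  unit-height Yule tree, Brownian clades carry only a minor share of
  trait variance, so a Gaussian filter on the trait selects
  trait-convergent tips scattered across the tree and carries little
  phylogenetic signal — measured directly, no 30-100-tip clade captures
  more than ~40% of the filter weight. Values below 1 raise node depths
  to a power, concentrating trait change on deep branches: the
  strongly-conserved-niche regime that nearest-taxon statistics are
  designed to detect. Analyses always use the untransformed tree; only
  the trait diffusion sees the transform.
* `env_offset = "focal_clade"`. A homogeneous environment with its
  optimum at the ancestral trait value (0) targets the trait mode, which
  every clade reaches by ancestry — selection is then real but
  phylogenetically invisible. The `"focal_clade"` mode places the shared
  optimum at the niche of the clade that captures the largest share of
  the filter weight (`focal_clade_optimum()`), the configuration under
  which homogeneous selection is phylogenetically detectable at all.

`reference_scenarios()` freezes four named configurations — variable
selection (conserved trait, divergent gradient), homogeneous selection
(sharp filter, uniform environment at a focal clade's niche), dispersal
limitation and drift — at the standard design of 9 sites x 4 layers, 300
OTUs, depth 10,000. These are the conditions under which the test suite
and `scripts/acceptance.R` demonstrate that the partition recovers each
regime's modal process.

What the generator does **not** emulate: sequencing-read error, PCR and
primer bias, chimeras, variable library sizes (every sample has exactly
the configured depth before rarefaction), taxonomic mis-assignment, and
multi-trait niches. Passing the recovery tests therefore shows the
statistics behave correctly on communities with known, cleanly separated
assembly regimes — not that any real community's partition is correct.

## Pipeline and reproducibility

`validate_config()` reads a YAML configuration (defaults filled, unknown
keys rejected) and `run_pipeline()` executes
simulate, rarefy, alpha, beta, stats, assembly and network stages in
order, writing every artifact as UTF-8 TSV with LF endings and
round-trip-exact floats, plus a JSON run summary. Every stochastic stage
derives its own sub-seed as a stable hash of the global seed and the
stage name (`derive_seed()`), so adding or disabling a stage never
perturbs another stage's random stream, and two runs with one seed are
byte-identical — the pipeline's most important engineering property, and
an explicit test.

Problem sizes throughout the tests are the package's own choices: module
tests use tens of samples and taxa; the recovery tests run the four
reference scenarios at full design size (36 samples x 300 OTUs, 999
randomizations each for bNTI and RCbray), the bNTI calibration pools 224
pairs from eight 8-sample x 100-OTU tables, and the RCbray calibration
uses 144 samples x 100 OTUs with 199 null draws per pair (the mean is
insensitive to the per-pair null count, and the occurrence-conditioning
bias shrinks with sample count, not null count).

## Known limitations

* The upstream steps (read QC through taxonomy assignment) and
  region-specific choices (which sites form the "nearshore" group) are
  configuration, not science, and live in the run configuration.
* RCbray's finite-sample positive bias (above) means process fractions
  from small designs lean slightly towards dispersal limitation.
* SparCC p-values use a permutation null rather than parametric theory;
  with 100 permutations the p floor is 1/101, so after BH adjustment very
  sparse signals can be undetectable at p < 0.01 — raise `n_boot` when
  edges are unexpectedly absent.
* The lineage-exclusion filter (removing, e.g., metazoan reads) is
  exposed in the data model but its order relative to upstream filtering
  is a user decision; published pipelines are ambiguous about it.
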