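---
title: "Linking bacterial metabolism to community modules: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking bacterial metabolism to community modules: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BacMetNet)
```

# Scope

BacMetNet implements a desk-scale version of a survey workflow used in
oligotrophic ocean studies: bulk bacterial metabolic rates are derived from
tracer incubations, the 16S ASV community is summarized with standard
diversity and ordination statistics, strong pairwise associations among ASVs
are assembled into seasonal co-occurrence networks with module structure,
and respiration is regressed on the per-sample abundance of those modules to
ask whether community production and respiration are coupled. Because the
interesting claims of such surveys (e.g., that production and respiration
can be *decoupled*, with respiration tracking particular community modules)
depend on a long chain of conversions and statistics, every link in the
chain here is a small, separately tested function, and a synthetic-data
generator with planted structure lets the whole chain be validated
end-to-end against known truth.

# Rate conversions

Three empirical relations convert raw tracer measurements into carbon units.

**Production.** Leucine incorporation (nmol Leu L^-1^ d^-1^) is converted
with the standard leucine-to-carbon factor of 0.37 kg C mol^-1^ Leu; the
units collapse so that BP in mg C m^-3^ d^-1^ is numerically
`0.37 * leu`. `leucineToBP()` is exactly linear, and its default constant is
configurable through `conversionConstants()`.

**Respiration.** In vitro INT (tetrazolium salt) reduction proxies electron
transport system activity. Total INT reduction is mapped to community
respiration in oxygen units through the empirical power law

$$\log_{10} CR_{O_2} = 0.72\,\log_{10} INT_T + 0.44,$$

applied with INT~T~ in µmol INT L^-1^ d^-1^ and CR~O2~ in µmol O~2~ L^-1^
d^-1^ (the units of the source calibration; both are recorded in the output
metadata and the two coefficients are configurable). The bacterial share is
the size-fractionated ratio `INT_0.2-0.8 / INT_T`, and oxygen consumption is
converted to carbon at a respiratory quotient of 1 using 12.011 µg C
µmol^-1^ (the IUPAC atomic mass rather than 12; configurable). The
calibration's logarithm is undefined at zero, so `intToCR()` errors on
non-positive input and the panel builder maps measured zeros to
`CR_O2 = 0` explicitly — the domain restriction is never silent.

**Cell-specific rates.** BP and BR divided by bacterial abundance, reported
in fg C cell^-1^ d^-1^ (1 mg C m^-3^ = 10^6^ fg C mL^-1^); the literature
rarely states this unit explicitly, so it is fixed here and documented.

Degenerate inputs are policy decisions, not accidents: blank-corrected
absorbances that come out negative (field blanks can exceed samples by
noise) are clamped to zero with a warning; a size fraction exceeding its
total is an error naming the offending sample; missing raw fields propagate
as missing outputs, never as zeros; and per-sample failures are collected
into a validation report instead of aborting the panel.

# Community processing

The ASV table lives in a `SummarizedExperiment` (ASVs as rows, taxonomy in
`rowData`, station metadata in `colData`). Chloroplast and mitochondrial
reads are removed by case-insensitive substring matching across all
taxonomic ranks — the permissive match is deliberate, since contaminant
labels appear at different ranks in different reference taxonomies.
Rarefaction subsamples each station uniformly without replacement to a
fixed depth (default 49,920 reads, a typical minimum-depth choice), drops
and reports shallower stations, and is seeded so repeated runs are
bit-identical. Diversity (richness; Shannon in natural log, base
configurable) is computed after rarefaction, which is the conventional
order when rarefaction is used to normalize sampling effort.

Between-station structure uses Bray–Curtis dissimilarity, classical-scaling
PCoA (negative eigenvalues are reported but not corrected — no
Lingoes/Cailliez — since the axes retained are those with positive
eigenvalues), and a one-factor PERMANOVA whose permutation p-value is
`(1 + #{F_perm >= F_obs}) / (1 + n_perm)` with a seeded default of 999
permutations. Seasonal univariate contrasts use the Wilcoxon rank-sum test
with average ranks for ties, exact enumeration when both groups have at
most 8 values and no ties, and the tie- and continuity-corrected normal
approximation otherwise.

# Co-occurrence networks

ASVs present in fewer than 5 samples are excluded; all remaining pairs get
a Spearman correlation (average ranks; two-sided p from the t
approximation, with an exact option for very small n) and the pair-level
p-values are Benjamini–Hochberg adjusted. An edge survives iff
|rho| > 0.75 *and* adjusted p < 0.001. Two printed conventions conflict in
this literature — "correlations greater than 0.75" versus a figure-caption
p < 0.01 — so the magnitude criterion uses |rho| (negative associations are
real edges, carried with their sign), the default p cut-off is the stricter
0.001, and 0.01 is available as a configuration override. Nodes with no
surviving edge are dropped (survey node counts far below ASV counts imply
this convention).

Modules are found on the unweighted graph by seeded greedy modularity
maximization with local move refinement (the multilevel/Louvain scheme via
igraph); the algorithm choice is ours, because survey methods sections
typically name packages rather than algorithms. Labels are assigned in
decreasing size order, so "module 1" is always the largest. Topology
metrics mirror the usual survey table: modularity Q of the stored
partition, average local clustering (degree < 2 nodes contribute 0),
average shortest-path length over connected pairs only, average degree
2E/N, and Freeman degree centralization. All are computed unweighted, and
all are tested against brute-force enumeration oracles on hundreds of
random small graphs.

A module's per-sample abundance is the mean z-score of its members'
relative abundances (population-SD standardization by default, sample-SD by
option; zero-variance members contribute an all-zero series). Relative
abundance for this scoring is taken from the rarefied, lineage-filtered
table.

# Linkage and the decoupling verdict

`decouplingReport()` assembles (i) a Spearman correlation panel over
chlorophyll a, BA, BP and BR (Spearman by default for consistency with the
network stage; Pearson by option; raw stars at p < 0.05 and p < 0.01 with
an off-by-default BH option, since survey heatmaps conventionally report
raw stars), (ii) per-season OLS regressions of max-scaled BR (each value
divided by the global maximum of the season's analysis set) on each
module's z-score abundance, and (iii) a verdict table labelling each rate
pair "coupled" (p < 0.05) or "decoupled" — explicitly descriptive labels
for observed correlation, not causal claims. PCA for the community-rate
ordination standardizes columns (correlation PCA) because the variables mix
units; axis signs are fixed so the largest-magnitude loading is positive.

# The synthetic generator

The generator emulates the study conditions of a two-season oligotrophic
survey; its defaults are the conditions, not dials:

* 40 summer and 48 winter stations; temperature 29.8 ± 0.6 / 26.9 ± 1.4 °C,
  salinity 34.7 ± 0.4 / 34.8 ± 0.5, Chl a 0.05 ± 0.02 / 0.10 ± 0.04
  µg L^-1^ (seasonal normals truncated at zero).
* BA = 5.45×10^5^ + 3×10^6^·Chl + N(0, 1.1×10^5^) cells mL^-1^: the
  intercept and slope are chosen so the seasonal Chl contrast alone
  reproduces the survey-scale seasonal BA means (6.95 / 8.45 ×10^5^ cells
  mL^-1^).
* BP = csBP·BA with csBP = 0.085 fg C cell^-1^ d^-1^ and mean-one lognormal
  noise (sdlog 0.4). The noise level is set so the planted
  abundance–production coupling is detectable at p < 0.01 with high power
  at n = 88 — the generator's job is to produce a *decisively* coupled
  pair, mirroring the clearly significant BA–BP association such surveys
  report.
* BR = 4.7 + 1.0·z₁ + N(0, 1.4) mg C m^-3^ d^-1^, where z₁ is the realized
  module-1 z-score abundance of the generated community. BR is therefore
  independent of BP *given the module* — the planted decoupling. The effect
  size gives the within-season regression roughly 0.8–0.9 power at n ≈ 48.
* Raw tracer inputs are back-computed by exactly inverting the rate
  formulas (leucine from BP; INT~T~ and the size fraction from BR via a
  uniform 0.4–0.9 bacterial share of community respiration, the range
  reported for ocean surveys), so the rates module reproduces the true
  panel to numerical precision and the whole pipeline is testable
  end-to-end.
* The community holds 120 ASVs: 12 contaminants (chloroplast/mitochondria
  lineages, never module members) and three planted modules of 20/15/10
  members among the rest. Log-abundance is `base + lambda*F_m + eps` with a
  shared per-sample factor per module; counts are multinomial at depths
  drawn uniformly from 50,000–120,000, so the default rarefaction depth of
  49,920 is exercised realistically. A latent-factor scheme was preferred
  over Dirichlet-multinomial because it gives direct control of pairwise
  correlation structure.

Two calibrations deserve note. The intra-module correlation target (0.85,
Spearman) is imposed at the latent level through the bivariate-normal
identity ρ~P~ = 2 sin(πρ~S~/6); and module members receive a −1 shift in
baseline log-abundance so the three co-varying blocks stay a modest share
of each sample. Without that shift, closure (normalizing to relative
abundance) subtracts part of the modules' shared factor from every member
and visibly attenuates the realized correlations — a compositional effect
worth remembering when interpreting real co-occurrence networks too. The
realized median intra-module Spearman on counts is ≈ 0.82, slightly below
the latent target because multinomial sampling and closure cannot be fully
undone.

What the generator does *not* emulate: spatial autocorrelation along cruise
tracks, seasonal turnover in community composition (seasons share one
community model, so a between-season PERMANOVA on synthetic data is a null
statistic), read-level sequencing error, and taxon-specific dynamics.
Passing tests on synthetic data therefore validate the *machinery* — the
conversions, statistics, graph algorithms and their composition — not the
ecological claims themselves.

# Pipeline, seeding and determinism

`runPipeline()` composes the stages per season (seasons are independent
strata; they are pooled only for the cross-season Wilcoxon contrasts and
the pooled rate-correlation panel), validates inputs first with file- and
record-level messages, and writes a JSON manifest containing the
configuration, the derived per-stage seeds, input checksums and per-stage
counts. All randomness (rarefaction, permutations, module detection) flows
from the master seed, and two runs on the same inputs with the same seed
produce byte-identical outputs. The generator's `genRates()` accepts the
module series as an argument (with a latent stand-in when called alone)
because the respiration coupling is defined on the realized community — the
orchestrator `genDataset()` wires that dependency.

# Problem sizes and test design

The test suite builds all fixtures in code. Statistical properties use
deliberately small designs where exhaustive enumeration is feasible
(Wilcoxon at 4+4, PERMANOVA at n = 6, Spearman against rank-Pearson by
hand) and simulation elsewhere (500 null PERMANOVA replicates at 199
permutations for the type-I error; 500 random graphs of at most 8 nodes
against brute-force metric oracles; 20 generator seeds for module recovery
and coupling detection at the full 88-station, 120-ASV design). These sizes
keep the full suite under a minute on one CPU while leaving each check
statistically meaningful.

# Known limitations

* The Spearman p-value uses the t approximation except for tiny n; at 88
  samples this is accurate, but for very small surveys the exact option
  should be preferred.
* PCoA applies no correction for negative eigenvalues; with strongly
  non-Euclidean dissimilarities the omitted axes can carry non-trivial
  magnitude (it is reported as `n_negative`).
* Module detection maximizes unweighted Newman–Girvan modularity; signed or
  weighted community detection would treat negative edges differently.
* The decoupling verdicts are marginal-correlation statements at a fixed
  alpha; they are not adjusted for multiplicity (by design, matching field
  convention) and carry no causal content.
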