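---
title: "Methods: network analysis of mitochondrial proteome remodeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network analysis of mitochondrial proteome remodeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitonet)
```

`mitonet` analyses quantitative mitochondrial (mt) proteomics from
mtDNA-depleted (ρ0) versus parental (ρ+) cells. This vignette is the
package's own account of the models and procedures it implements, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic validation does and does not show.

## Regulation classification

Input is a table of linear-scale abundance ratios ρ0/ρ+, one per protein.
Classification is a fixed two-threshold rule: up when ratio ≥ `up_min`
(default 1.5), down when ratio ≤ `down_max` (default 0.67), unchanged in
between, with inclusive boundaries on both sides. The down threshold is kept
at the literal conventional value 0.67 rather than 2/3: proteomics studies
print 0.67, and the classification must reproduce printed counts exactly.
Ratios are consumed on the linear scale; logarithms appear only in the
concordance analysis. Rows with missing ratios are dropped with a logged
count — a quantification table lists only quantified proteins, so a missing
ratio carries no usable signal. Non-positive or non-finite ratios are
rejected with the offending protein named, since they indicate a corrupted
input rather than a borderline measurement.

## Reliability tiering

A measured protein is trusted either because reference knowledge supports it
or because the network places it next to supported proteins:

* **Reference tier** — carries the mitochondrial cellular-component
  annotation *and* occurs in at least one reference catalog
  (`rule = "and"`). The conjunction is the default because the two evidence
  routes are qualitatively different (curated localisation vs observation in
  an independent dataset) and demanding both is the conservative reading;
  `rule = "or"` is exposed because the pooled reading is also defensible.
* **Physical tier** — not reference-supported, but at least one
  physical-channel link to a reference-tier protein.
* **Functional tier** — the same with a functional-channel link, evaluated
  only for proteins not already rescued physically. Physical evidence takes
  precedence so tiers are disjoint and their counts add up.

Rescue is deliberately single-hop: a link to a rescued protein does not
propagate trust, because each hop multiplies the false-positive rate of the
link evidence. Link rows touching ids outside the identified universe are
ignored with a logged count rather than rejected — interaction databases
always cover more proteins than one experiment identifies.

## Functional network statistics

The network is the simple graph induced on reliable proteins: duplicate rows
for one unordered pair collapse to the highest-confidence row (the physical
channel wins exact ties so the result is deterministic), self-links are
forbidden, and `score_min` (default 0, i.e. keep everything) filters on
confidence. All topology statistics are computed on the largest connected
component; size ties break toward the component containing the
lexicographically smallest protein id.

Edges are categorised *intra* (up–up or down–down), *inter* (up–down), or
*other* (any unchanged endpoint). Two totals matter and are both reported:
the component's full edge count, and the regulatory edge count
(intra + inter) over which the intraregulatory percentage is taken. These
are different denominators, and summaries that quote "links" without saying
which are ambiguous — the report never does.

Per-protein link fractions (the per-node view of the same tendency) use the
node's *regulatory* edges as denominator, so intra + inter fractions sum to
one for every sampled node; nodes whose incident edges are all `other` are
excluded rather than given a 0/0. Shortest-path samples take every unordered
pair of regulated nodes in the component, binned same-class versus
opposite-class, with unweighted breadth-first distances over all edges —
confidence scores are evidence strengths, not metric lengths, so they do not
weight paths. An alternative reading ("connected within intraregulatory
links" as paths inside the intra-edge subgraph) is available via
`pair_set = "regulatory_subgraph"`; the all-pairs default is used because the
subgraph reading makes the two samples structurally incomparable (they live
in different graphs).

The two-sample comparison is a Mann–Whitney U test: mid-rank ties,
tie-corrected normal approximation with continuity correction, and an exact
permutation distribution when the pooled sample has at most 12 observations.
The default direction is one-sided in the direction asserted (same-class
pairs closer; intra fractions larger); two-sided is a flag. A constant pooled
sample returns p = 1 with a warning rather than an error, since it is a
legitimate degenerate outcome on tiny networks.

## Module detection

Similarity between proteins is the link confidence (0 where no edge,
1 on the diagonal). Average-linkage (UPGMA) agglomeration merges the pair of
clusters with the greatest mean cross-pair similarity — maintained by the
size-weighted running update, which equals the unweighted mean over all
cross pairs — and stops when that best mean falls below the cut `tau`.
Merge heights are produced in non-increasing order (average linkage is
reducible), which the tests assert. Exact ties in the merge choice break
toward the smallest matrix indices, so results are reproducible.

Two parameters shape the cluster set:

* `tau` (default 0.4) — the similarity cut, unitless in [0, 1]. The default
  suits dense, high-confidence empirical association networks. For
  block-model-like data the right cut depends on edge density and confidence
  levels: the expected average-linkage similarity between two fragments of
  one true module is `p_in * E[within-module confidence]`, versus
  `p_out * E[between confidence]` across modules. `suggest_tau()` places the
  cut at the geometric mean of those two expectations. The geometric rather
  than arithmetic midpoint matters: the two levels usually differ by orders
  of magnitude, and greedy agglomeration concentrates each module's densest
  pairs into early cores, leaving observed cross-core averages that
  fluctuate well below the within-module expectation. An arithmetic midpoint
  sits inside that fluctuation band and fragments modules; the log-scale
  midpoint stays below it while remaining far above the between-module
  level.
* `min_size` (default 3) — smaller clusters go to an unassigned pool instead
  of module candidacy; a "module" of two proteins is a single link, not a
  functional unit.

A cluster is promoted to a functional module only if it passes **both**
one-sided hypergeometric tests at `alpha_module` (default 0.01): enrichment
of at least one annotation term (tested term-for-term over terms with ≥ 2
annotated cluster members, representative term = smallest p), and enrichment
of one regulation class, which labels the module. The hypergeometric upper
tail is computed through the survival function, stable for the extreme tails
enrichment produces. P-values are used raw at the printed α = 0.01 criterion;
a Benjamini–Hochberg flag exists (`adjust = TRUE`) but is off by default for
module selection. The background for both tests is the clustered universe
(cluster members plus the unassigned pool) — the clustering only ever sees
networked proteins, so that is the population a draw is made from; for term
enrichment the background further restricts to annotated proteins, the
standard convention for annotation tests. Equal enrichment p in both
directions breaks toward the direction with more members, and is logged.
Annotations are flat term sets; ontology parent–child propagation is out of
scope. One global cut produces the cluster set — no per-subtree curation —
because a single reproducible criterion beats manual dendrogram surgery in a
pipeline meant to be rerun.

Module coverage is reported per class as the fraction of the clustering
universe's up (down) proteins captured by up- (down-) labelled modules.

## Proteome–transcriptome concordance

The expression matrix (positive intensities, replicated in both conditions,
with per-entry detection p-values) is processed as: detection filter, log2,
quantile normalization. The filter removes a gene only when it is undetected
(p > 0.05) in *every* sample of at least one condition — a per-sample
reading would discard genes on a single bad replicate, and a ratio needs
signal on both sides. Quantile normalization (via `limma`, ties receiving
the mean of their target quantiles) forces all samples onto one empirical
distribution before ratios are formed. The per-gene mRNA log2 ratio is the
mean over all ρ0 × ρ+ replicate-pair differences, which equals the
difference of per-condition means — replicates are unpaired, so no pairing
convention is assumed.

Profiles (protein log2 ratio, mRNA log2 ratio) are partitioned by k-means
with k = 5, ten random restarts, best inertia kept, deterministic given the
seed. The feature space is the 2-D log2-ratio plane: the analysis is about
joint direction of change, and the symmetric log scale makes up- and
down-regulation commensurable. Clusters are labelled from centroid geometry:
smallest-norm centroid = unchanged; the rest by quadrant, requiring each
coordinate to clear a dead band `delta` (default log2(1.2), i.e. a 20%
change) so that a centroid sitting on an axis is flagged as unlabelable
(with the centroids printed) instead of silently mislabelled. Group sizes
are convention-dependent — only their sums (positively and negatively
correlated totals) are stable quantities.

Module-level summaries give mean ± sd (n − 1 denominator) of linear-scale
protein and mRNA ratios over profiled members, with direction flags relative
to 1. Cross-platform pattern agreement is the percentage of shared proteins
given the same class by two calls; the accompanying significance is an exact
binomial test of the agreement count against a null agreement probability
(default 0.5). The original comparison statistic for this kind of validation
is typically unstated in publications, so the binomial test is an explicit
assumption of this implementation, and its p-value is descriptive, not a
selection criterion.

## The synthetic world

`generate_world()` plants: modules as a weighted stochastic block model
(within-module edge probability `p_in = 0.3`, background `p_out = 0.01`,
Beta(8,2) confidences within modules, Beta(2,8) elsewhere, 30% of edges
physical); per-module regulation patterns (defaults: five up and eight down
modules of 15, mirroring the study structure) with a 5% opposing fraction —
the empirical scale of proteins moving against their module; protein ratios
as 2^(±1 + N(0, 0.3)) so classification at 1.5/0.67 captures most planted
members while leaving realistic overlap; regulated proteins outside any
module (30 up, 37 down by default — the study-scale gap between regulated
proteins and module members); an unchanged background (300) and contaminants
(100) that never enter the reference catalog and link only at `p_out`; a
13-set reference catalog with 0.9 annotation sensitivity, 0.3 per-set
sensitivity and a 2% contaminant false-positive rate; flat annotations with
a dominant module term carried by 80% of members plus uniform background
terms; and a triplicate two-condition intensity matrix, intensity =
2^(base + effect + noise), with planted concordance patterns — mRNA rises in
both up- and down-modules (protein falling in the latter), the
characteristic compensatory signature under mtDNA depletion.

What the generator does *not* emulate: peptide-level quantification noise
(ratios are protein-level draws), correlated annotation structure (terms are
flat and independent), degree heterogeneity of real association networks
(block-model degrees are near-Poisson), probe effects and batch structure in
the arrays, and dependence between protein and mRNA noise. Passing recovery
tests therefore demonstrates the pipeline's correctness and its behaviour
under the planted generative assumptions — not performance guarantees on
real STRING/HPRD-scale data, whose inventory of significant modules is
data-dependent.

A deterministic companion, `generate_study_world()`, constructs inputs whose
marginal counts equal a published study's printed tables (tier sizes
569/82/119/351 of 1,121; a 726-node component with 13,618 links, 4,854
intra- and 859 interregulatory; module universes covering 59 of 89 up and
138 of 175 down proteins; concordance clouds 127/147/78/218/118; a 33-protein
panel agreeing on 30). It is synthetic by construction — ids and geometry
are invented; only the marginals are anchored — and exists so that every
reported count and percentage is recomputed by the pipeline from actual
inputs rather than asserted.

## Problem sizes and numerical choices

The validation suites run at desk scale, chosen to exercise every code path
while keeping the full suite under a couple of minutes: recovery worlds use
ten modules of 20 (about 340 proteins, ~60k candidate pairs) over ten seeds;
oracle sweeps enumerate the full hypergeometric parameter space to N = 12,
all Mann–Whitney splits to n = 10, 200 random graphs against Floyd–Warshall,
and 100 random similarity matrices against a naive UPGMA reference.
Determinism is enforced end to end: the generator consumes a mandatory seed
(restoring the caller's RNG state afterwards), k-means takes an explicit
seed, and serialized worlds and pipeline reports are byte-identical across
reruns — the tests assert this on files, not on in-memory objects.

Degenerate inputs have defined behaviour rather than errors where a
legitimate analysis can reach them: no regulatory links → the intra
percentage is reported absent; a constant pooled sample → U test p = 1 with
a warning; clusters with no annotated member → rejected from module
candidacy; modules with no profiled member → omitted from expression
summaries with a log. Hard errors are reserved for contract violations
(non-positive ratios, confidences outside [0, 1], malformed tables — reported
with line numbers).

## Known limitations

* UPGMA at one global cut cannot represent nested module structure; τ trades
  off module granularity directly.
* Enrichment p-values are raw per the α = 0.01 selection criterion; with
  many clusters and terms, expect false-positive modules at roughly that
  rate unless `adjust = TRUE`.
* The concordance grouping inherits k-means' sensitivity to cluster shape;
  the dead-band labelling guards against mislabelled centroids but cannot
  repair a poorly separated plane.
* The reliability step trusts the link table's channel labels; no attempt is
  made to re-derive physical versus functional evidence.
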