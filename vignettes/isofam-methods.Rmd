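---
title: "Detecting isofunctional protein subfamilies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting isofunctional protein subfamilies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isofam)
```

## The problem

A protein family groups evolutionarily related sequences, but relatedness
does not imply identical molecular function: many families split into
*isofunctional subfamilies*, each performing a specific reaction the rest
of the family does not. `isofam` partitions a family into such subfamilies
using only data that can be computed or collected per protein pair, and
ranks the active-site residues that make each cluster distinctive — the
specificity determining positions (SDPs).

The pipeline has five stages: family definition (filtering), evidence
collection, evidence integration, clustering, and quality evaluation.

## Family definition filters

Two filters reduce a raw family to a modellable protein set:

* **Length filter** (`filter_by_length()`): proteins whose domain
  subsequence length differs from the family mean by more than one sample
  standard deviation are dropped. We use the n−1 (sample) standard
  deviation — the family at hand is a sample of the sequences that exist —
  and compute the statistics on the filter's *input*, so re-application is
  contractive rather than idempotent-by-recomputation.
* **Reference-identity filter** (`filter_by_reference_identity()`):
  proteins with less than 30% sequence identity to every reference
  structure are dropped (30% being the conventional floor for usable
  homology models). Proteins with no identity entries are an error by
  default; a `drop` mode is available.

## Evidence matrices

Every data source becomes one symmetric N×N `evidence_matrix` with an
orientation flag: *similarity-like* (alignment scores, shared annotation
counts, context scores) or *distance-like* (property differences,
signature distances). Matrices computable from sequence are built here
(pairwise global/local alignment scores under BLOSUM62 with affine gaps,
active-site identity and BLOSUM62 score, property differences,
composition distances, shared-annotation counts); matrices requiring
external tools or databases (structural alignments, structural
signatures, genomic-context scores, isoelectric point, instability index)
are *inputs*, read from pair tables or property tables, and missing pairs
are carried as a mask, never fabricated.

Parameter choices that matter:

* **Gap penalties** default to open 10 / extension 4 (a gap of length L
  costs 10 + 4L), the defaults of the alignment engine used; both are
  arguments of `alignment_score()`.
* **Active-site comparisons** exclude gap columns from numerator *and*
  denominator: a gap records a modelling failure, not a functional
  difference, so it should neither count as mismatch nor dilute identity.
* **Amino-acid classes** follow the pepstats convention (aliphatic AILV,
  aromatic FHWY, non-polar ACFGILMPVWY, polar DEHKNQRST, charged DEHKR,
  basic HKR, acidic DE); the composition array divides each residue's
  molar percent by the packaged Dayhoff reference composition, so 1 means
  "typical protein abundance".

### Normalization

`normalize_evidence()` min–max rescales present off-diagonal values to
[0, 1], or to [−1, 1] when negatives exist; distance-like matrices are
then interval-reversed (x → 1 − x, resp. x → −x). Decisions taken where
the convention was open:

* the self-pair diagonal is excluded from min/max and set to maximal
  similarity afterwards (self-similarity carries no information about the
  spread of pair values);
* missing pairs are imputed at the interval's minimum-similarity value —
  absence of evidence contributes no similarity, which lets known-sparse
  sources (context scores exist only for a subset of pairs) participate
  without bias toward the pairs they cover;
* a constant matrix maps to all zeros with a warning rather than dividing
  by zero.

## Putative active site selection

Given candidate pockets of a reference structure, each with a fixed-width
alignment of the family onto its positions and a detection score, the
putative active site is the highest-scoring pocket having at least three
positions conserved in at least half the family (enzymes average ~3.5
catalytic residues, so three conserved positions is the natural floor).
Conservation counts a residue over *all* rows by default — it must be
present and identical in ≥ 50% of the family, gapped rows included — since
the rule reads over the family, not over the modellable subset; a
`denominator = "ungapped"` switch gives the other reading. Score ties
break lexicographically by pocket id so selection is reproducible; when
no pocket qualifies we raise an error listing per-pocket conserved
counts rather than silently picking a best effort.

## Spectral clustering

`build_affinity()` makes the combined similarity a valid adjacency of the
fully connected similarity graph: affine shift by −min when negatives
exist, zero diagonal, and a 1e−12 degree floor for all-zero rows.
`spectral_cluster()` then computes the random-walk (normalized
asymmetric) Laplacian `L_rw = I − D⁻¹W`, takes the eigenvectors of its K
smallest eigenvalues, and K-means the rows of the N×K embedding.

Numerical choices: the eigenvectors of the asymmetric `L_rw` are obtained
from the equivalent symmetric generalized problem
(`L_sym = D^{-1/2}(D − W)D^{-1/2}`, back-transformed by `D^{-1/2}`), which
is stable and guarantees real, orthogonal eigenvectors; eigenvalues are
checked non-negative to 1e−8. The embedding rows are *not* row-normalized
(that belongs to a different spectral variant). K-means uses 10 restarts
with greedy farthest-point (kmeans++-style) seeding from a stream derived
from the run seed, keeping runs deterministic; a draw yielding an empty
cluster is re-seeded up to 5 times and then errors, since the contract is
K non-empty clusters.

## The mutual-information quality measure

A clustering is good when clusters own (almost) exclusive residues at
specific active-site positions. For position `p_i`, cluster `c_j` and
residue `r_k`,

$$MI_{p_i}(c_j, r_k) = p_{p_i}(c_j, r_k)\,PMI_{p_i}(c_j, r_k) +
  p_{p_i}(\bar c_j, r_k)\,PMI_{p_i}(\bar c_j, r_k),$$

with $PMI(x, y) = \ln p(x,y)/(p(x)p(y))$, floored to 0 when the
cluster-side PMI is non-positive, and $0\ln 0 \equiv 0$. The PMI joint and
marginal probabilities are computed over **all non-gap rows at the
position** — this is the only reading under which the documented
opposite-sign property of the cluster-side and complement-side PMIs
actually holds — while the two weights are the residue's frequency
*within* the cluster (resp. its complement), as the measure's definition
states. Rows gapped at a position are dropped from that position's
probability space entirely, cluster marginals included. Aggregation is

$$MI_{p_i}(c_j) = \sum_k f_k\,MI_{p_i}(c_j, r_k), \qquad
  MI = \frac{1}{P}\frac{1}{C}\sum_i \sum_j MI_{p_i}(c_j),$$

with $f_k$ again the within-cluster frequency. The double frequency
weighting (the weight inside $MI_{p_i}(c_j,r_k)$ *and* the outer $f_k$)
is implemented as defined; `overall_mi(..., outer_weight = FALSE)`
disables the outer weight for sensitivity analysis. Under the literal
$1/(PC)$ average the measure is bounded by $\ln C$ (attained by C
equal-size clusters with exclusive, fully covering residues at every
position — a closed form the tests assert); published family-level values
sometimes exceed that envelope, suggesting the plain double sum, so the
report carries both `overall` and `unnormalized` and asserts neither as
the only convention.

Partial MI values sorted per cluster give the SDP ranking
(`rank_discriminative_residues()`); ties break by position index then
residue for determinism.

## Evidence integration by genetic programming

Individuals are **addition-only expression trees** over matrix names;
integer coefficients arise as leaf multiplicities, which reproduces the
printed form of integration equations ("2ASid + ASscr + seqAliG") without
a separate constant mechanism. Crossover swaps random subtrees (offspring
exceeding the depth bound are rejected and the parents cloned); mutation
replaces a random subtree with a fresh random tree; reproduction copies.
Fitness is the overall MI of the spectral clustering of the combined
matrix. Defaults — population 50, 30 generations, crossover/mutation/
reproduction rates 0.8/0.1/0.1, tournament size 3, max depth 6, one
elite — are this package's own (the search is easy at these sizes and the
elitist best-fitness trajectory is monotone by construction); all are
`gp_config()` arguments and are echoed in every report. One clustering
seed is drawn per run and held fixed across individuals, so selection
compares combinations rather than K-means draws; fitness is cached by
coefficient vector, which the addition-only genome makes exact.

## External validation

`cluster_agreement()` compares a clustering with a reference
classification through the class-by-cluster contingency table: pairwise
precision, recall, F1, Rand and Jaccard (via binomial identities on the
table, cross-checked in tests against O(N²) pair enumeration), variation
of information in nats (natural logs, consistent with the PMI measure —
and confirmed by reproducing the packaged gold-standard suite), and the
split/merge edit distance `2·(co-occupied cells) − #classes − #clusters`.
Two published enzyme-superfamily validation tables (crotonases, N = 2,694;
enolases, N = 4,791, each vs. twelve clusters) ship as TSV fixtures and
load with `sfld_contingency()`.

## The synthetic benchmark

`generate_family()` plants the structure every other module is tested
against: K subfamilies of stated sizes; SDP positions drawing one dominant
residue per subfamily (distinct across subfamilies, mirroring the
known two-residue swaps that flip specificity in real families), flipped
to a random residue at the noise rate; family-wide conserved positions;
uniform-random positions; gaps at a per-cell rate; evidence matrices that
are two-level block matrices plus Gaussian noise (informative),
ρ-correlated copies (redundant), pure symmetric Gaussian noise, or
partially masked (missing). Defaults — N = 60, K = 3, 10 positions
(3 SDP / 4 conserved / 3 random), 5% SDP noise, 2% gaps, one informative
matrix (within 0.9 / between 0.1 / noise sd 0.05) and two noise matrices —
describe a planted-partition regime a spectral method should recover
comfortably, and are the conditions under which the end-to-end recovery
checks run. Gaussian similarity noise is a simplicity choice; the
contracts are on block-mean separation, not the noise family.

What the generator does **not** emulate: phylogenetic correlation between
sequences (no evolutionary model), realistic active-site geometry,
data-type redundancy structure of real sources, or family imbalance of
the kind that dominates real superfamilies. Passing the synthetic
recovery checks therefore shows the machinery is correct and well-wired,
not that real families of comparable size will separate as cleanly.

## Problem sizes and determinism

The shipped tests and the acceptance script use small instances chosen to
exercise every contract: alignments up to length 30 against a brute-force
dynamic-programming oracle, 100 random small alignments against a
probability-table MI oracle, planted partitions at N ≤ 200 for clustering
and N = 40–60 for the evolutionary search (where exhaustive enumeration
of coefficient vectors in {0,…,3}³ provides the optimum). All randomness
descends from explicit integer seeds through named substreams
(`derive_seed`), so every run — including the full pipeline — is
reproducible from its provenance log.

## Known limitations

* The number of clusters K is an input; no internal measure the MI family
  provides can compare clusterings across different K (the value shrinks
  as K grows), so choosing K remains manual.
* Fuzzy membership is out of scope: each protein belongs to exactly one
  cluster, although real promiscuous enzymes straddle subfamilies.
* Upstream tools (structure modelling, pocket detection, structural
  alignment, context databases) are not run; their outputs are file
  inputs, and the quality of the clustering inherits their quality.
* Heavily imbalanced families tend to split their dominant subfamily
  before isolating small ones — a property of the data, visible in the
  packaged gold-standard tables, not something the measure corrects.
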