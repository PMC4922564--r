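# isofam

Detection of **isofunctional subfamilies** inside a protein family, with
identification of the residues that differentiate them.

Large protein families (a Pfam family, an enzyme superfamily) often contain
subfamilies whose members share a specific molecular function not common to
the whole family — adenylate vs. guanylate cyclases, Ser/Thr vs. Tyr
kinases. Finding those subfamilies, and the **specificity determining
positions (SDPs)** whose residues separate them, is a first step toward
annotating families of unknown function. `isofam` is for computational
biologists who have a family's sequences, a putative active-site alignment,
and any number of heterogeneous pairwise comparison tables, and want an
automated partition of the family into functionally coherent clusters.

## Method

Every available comparison between two proteins — global/local alignment
score, structural alignment size/identity/TM-score, structural-signature
distance, genomic-context scores, physicochemical property differences,
shared InterPro/GO annotations, active-site identity and BLOSUM62 score —
is treated as weak **evidence of functional similarity** and stored as a
symmetric evidence matrix. Each matrix is min–max normalized to [0, 1]
(or [−1, 1] when negative values exist) with distance-like matrices
interval-reversed, so that larger always means more similar.

A **genetic programming** system evolves addition-only expression trees
over the matrix names; a tree's leaf multiplicities are integer weights,
so each individual is an integration equation such as

```
s_ij = interpro + neighborhood + 3 strAliScr
```

Each candidate combination `s` is clustered by **spectral clustering**:
the random-walk Laplacian `L_rw = I − D⁻¹W` of the fully connected
similarity graph is computed, the eigenvectors of its K smallest
eigenvalues embed the N proteins into K dimensions, and seeded K-means
partitions the embedding. The fitness of the individual is the clustering's
**active-site mutual information**

```
MI = (1/P)(1/C) Σ_i Σ_j MI_pi(c_j),
MI_pi(c_j)       = Σ_k f_k · MI_pi(c_j, r_k),
MI_pi(c_j, r_k)  = p_pi(c_j, r_k) PMI_pi(c_j, r_k) + p_pi(c̄_j, r_k) PMI_pi(c̄_j, r_k),
PMI(x, y)        = ln p(x, y) / (p(x) p(y)),
```

floored at 0 when the cluster-side PMI is non-positive: a clustering
scores highly when clusters own (almost) exclusive residues at specific
active-site positions. The same partial MI values, sorted per cluster,
rank the SDPs.

Against a known classification, clusterings are validated with pairwise
precision/recall/F1, Rand, Jaccard, variation of information (nats) and
the split/merge edit distance; two published enzyme-superfamily
contingency tables ship as fixtures.

## Worked example

A planted three-subfamily benchmark (60 proteins, 10 active-site positions
of which 3 are SDPs, one informative evidence matrix among two pure-noise
ones) is generated, the full pipeline is run, and the result is validated
against the planted truth:

```r
library(isofam)

spec <- synthetic_family_spec(n = 60, k = 3)
data <- generate_family(spec, seed = 42)
run  <- detect_subfamilies(data$matrices, data$msa, k = 3,
                           config = gp_config(seed = 42))
run
#> <isofam_run: 3informative1 + 3noise1 + noise2  (MI = 0.3125, k = 3 clusters)>

head(run$sdp_ranking, 3)
#> # A tibble: 3 × 4
#>   cluster residue position partial_mi
#>   <chr>   <chr>      <int>      <dbl>
#> 1 1       T              1      1.12
#> 2 1       T              3      1.07
#> 3 1       N              2      0.966

evaluate_run(run, data$family[, c("id", "label")])
#> # A tibble: 1 × 8
#>   precision recall    f1  rand jaccard    vi  edit     n
#>       <dbl>  <dbl> <dbl> <dbl>   <dbl> <dbl> <int> <int>
#> 1         1      1     1     1       1     0     0    60
```

The evolved equation gives the informative matrix a large weight; the
top-ranked discriminative residues sit at the planted SDP positions 1–3
(partial MI ≈ ln 3 ≈ 1.10 for an exclusive, fully covering residue); and
the recovered partition matches the planted subfamilies exactly
(F1 = 1, VI = 0, edit distance 0).

The packaged gold-standard fixtures evaluate the same way:

```r
cluster_agreement(sfld_contingency("crotonase"))
#> # A tibble: 1 × 8
#>   precision recall    f1  rand jaccard    vi  edit     n
#>       <dbl>  <dbl> <dbl> <dbl>   <dbl> <dbl> <int> <int>
#> 1     0.938  0.451 0.609 0.803   0.438 0.803    26  2694
```

A thin command-line front end (`inst/scripts/isofam.R`) exposes
`simulate`, `select-pocket`, `cluster`, `score`, `detect` and `evaluate`
subcommands over the same functions.

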