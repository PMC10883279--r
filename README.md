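# sampleOT

Sample-level analysis of multi-scale single-cell and pathomics cohorts
with exact optimal transport.

## The problem

A single-cell or pathomics study of a disease cohort is *multi-scale*:
each sample (patient, biopsy, histology slide) is itself a population of
thousands of cells or tissue structures grouped into clusters — cell
types, cell states, morphological classes. Comparing samples is therefore
not a vector comparison: two samples can differ a little (mass shifted
between related cell states) or fundamentally (mass shifted between
unrelated cell types), and a useful distance has to know the difference.
The package is aimed at analysts of disease atlases who want *unsupervised*
sample-level structure — disease-progression trajectories or patient
subgroups — plus the statistics to say which cell populations and genes
drive it.

## The model

Each sample `l` is a distribution over the `K` cell clusters, estimated
robustly as the mode of a Dirichlet-multinomial posterior,

    p̂_lk = (z_lk + α_k) / (N_l + Σ_i α_i),   α_k = (N_k / N) · c,

so rare clusters missing from shallow samples are smoothed toward the
cohort-wide composition (`c = 0.1` by default). The distance between two
samples is the exact Wasserstein (earth mover's) distance

    W(p_l, p_q) = min_{T ≥ 0} Σ_ij t_ij c_ij,
    subject to row sums = p_l and column sums = p_q,

with the ground cost `c_ij` the cosine distance between cluster medians in
a low-dimensional embedding, solved by an exact transportation simplex
(no entropic approximation). The resulting `L × L` distance matrix feeds:

* **trajectories** — a variable-bandwidth diffusion map, a minimum
  spanning tree backbone, and a per-sample disease progression rank;
* **clustering** — Leiden community detection on a kNN graph with
  silhouette-guided resolution selection;
* **interpretation** — stepwise robust Huber trend regression with a
  Huber-penalized R², Wald curve-difference tests per cluster, Welch tests
  on proportions, limma-moderated differential expression, and covariate
  association checks;
* **benchmarking** — adjusted Rand index, silhouette, AUCPR of an
  ordering, Spearman vs. ordinal severity, Friedman–Nemenyi rank tests.

A synthetic-cohort generator with planted trajectories or sample groups
backs every claim with measurable ground truth. See the vignette
(`vignettes/sample-level-transport.Rmd`) for models, assumptions, and
numerical choices.

## Worked example

```r
library(sampleOT)

# a synthetic 20-sample cohort with a planted disease trajectory
sim <- generate_dataset(synth_config(n_samples = 20, cells_per_sample = 500,
                                     n_genes = 10, seed = 3))
dataset <- sim$dataset
dataset
#> cell_dataset: 10000 cells, 10 features
#>   samples:  L = 20
#>   clusters: K = 5
#>   embedding: 10 dims
#>   metadata: sample, status, batch

ot <- wasserstein_distances(dataset, prior_strength = 0.1, metric = "cosine")
ot$distances
#> sample_dist: 20 samples, range [ 0 , 0.442221 ]

traj <- fit_backbone_and_progression(
  diffusion_map(ot$distances), root = "auto",
  status = setNames(dataset$sample_metadata$status, dataset$sample_ids))
head(traj$progression)
#> sample01 sample02 sample03 sample04 sample05 sample06
#>       17       18        6       16       13        7

cor(traj$progression, sim$truth$time, method = "spearman")
#> [1] 0.9759398
```

The recovered progression ranks correlate at ρ ≈ 0.98 with the planted
disease time. Which cell-cluster proportions change along the trajectory,
and with what shape?

```r
props <- estimate_proportions(dataset)$proportions
trends <- fit_trends(props[names(traj$progression), ], traj$progression)
head(trends[, c("feature", "family", "beta1", "beta2", "r2_mod", "p_adjusted")], 3)
#>    feature    family      beta1 beta2    r2_mod   p_adjusted
#> 4 cluster4 quadratic  0.2207748    NA 0.9693504 4.427800e-13
#> 5 cluster5 quadratic -0.2181394    NA 0.9596889 1.880648e-12
#> 3 cluster3    linear -0.2421608    NA 0.9376578 1.673543e-11
```

The generator planted a quadratic increase for cluster4, a quadratic
decrease for cluster5 and a linear decrease for cluster3 — exactly the
families, signs and rough magnitudes reported. Finally, covariate checks
distinguish biology from batch:

```r
association_tests(traj, dataset$sample_metadata)
#>   covariate     type  test statistic dof      p_value   p_adjusted
#> 1    status discrete anova 57.081492   2 2.866949e-08 5.733897e-08
#> 2     batch discrete anova  2.192308   1 1.559933e-01 1.559933e-01
```

The disease status explains the trajectory (p ≈ 3e-8); the random batch
label does not.

A thin command-line interface wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "sampleot.R", package = "sampleOT"))') \
  distance --input cells.csv --prior-c 0.1 --metric cosine --out W.tsv
# then: trajectory --dist W.tsv --out traj.tsv ; cluster --dist W.tsv --out clusters.tsv
```

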