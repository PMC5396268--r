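# clusterrank

Ranking clusters of docked protein–protein complexes by pairwise cluster
comparison.

## The problem

Docking programs produce thousands of candidate poses per receptor–ligand
pair, and single-pose energy functions rank many incorrect binding modes
above near-native ones. `clusterrank` targets the cluster level instead:
poses are grouped into candidate binding regions by ligand RMSD, and a
machine-learning model ranks those clusters by how likely each is to
contain the lowest-LRMSD pose. The package is for structural
bioinformaticians who score docking decoy sets (e.g. CAPRI-style
ensembles) and want a cluster-centric ranking that integrates many
molecular descriptors rather than one energy function.

## The method

For a target with clusters *n*, *m*, …:

1. **GROMOS clustering** at a 10 Å LRMSD cutoff: iteratively, the pose
   with the most neighbours within the cutoff seeds a cluster with those
   neighbours; clusters with > 5 members are kept. LRMSD is the RMSD of
   ligand Cα atoms after superposing the receptor Cα atoms (Kabsch).
2. **Cluster features**: each per-model molecular descriptor (standardized
   to zero mean / unit variance per target) is summarised over the
   cluster's members by five points — MIN, Q1, AVG (median), Q3, MAX —
   plus the cluster size: 5·D + 1 features per cluster (546 for D = 109
   descriptors). Clusters may first be densified with enrichment poses
   (sub-clustered at 3 Å; centroid-closest members of the top ten
   sub-clusters), which feed the descriptor distributions but never the
   size feature or the labels.
3. **Pairwise learning**: every unordered cluster pair of a target is one
   record of 2·(5·D + 1) features (1092 at D = 109) with label
   **1 iff min LRMSD(n) < min LRMSD(m)**. An extremely randomized trees
   classifier (3000 trees, bootstrapped, Gini splits, √p candidate
   features = 33 at p = 1092, depth ≤ 100, leaves ≥ 1) is trained on the
   records, evaluated by leave-complex-out cross-validation (one fold per
   target) and by its out-of-bag error.
4. **Win-count ranking**: each pair is evaluated once; the predicted
   lower-LRMSD cluster collects a win, and clusters are ranked by
   descending wins (probability-margin tie-break).

Around this core the package provides CAPRI-style quality measures
(LRMSD / IRMSD / FNAT and class assignment), van der Waals clash
filtering, descriptor screening (Mann–Whitney U with significance tiers,
Pearson correlation / collinearity counts), recursive feature elimination
in steps of 10 with fold-averaged importances, dimensionality-reduction
sweeps (PCA, ML factor analysis, RBF kernel PCA — fitted on training folds
only), and a synthetic benchmark generator with planted ground truth.

## Worked example

Generate a small synthetic benchmark (4 targets × 6 clusters, 8
descriptors correlated 0.9 with LRMSD, 5% heavy-tailed outliers), train,
cross-validate, and rank a new target without its reference structure:

```r
library(clusterrank)
cfg   <- synth_config(n_targets = 4, clusters_per_target = 6,
                      n_descriptors = 8, seed = 42)
bench <- generate_benchmark(cfg)
pcfg  <- pipeline_config(ert = ert_config(n_trees = 500, seed = 42))
fit   <- run_train(bench, pcfg)
fit$cv
#> <lco_cv: 4 folds>
#>      recall precision    f1 accuracy
#> mean  0.867     0.977 0.910    0.950
#> sd    0.163     0.045 0.086    0.033

cv_rank_eval(fit, pcfg)[, c("target_id", "best_cluster", "rank", "n_clusters")]
#>   target_id best_cluster rank n_clusters
#> 1       T01            4    1          6
#> 2       T02            3    1          6
#> 3       T03            6    1          6
#> 4       T04            3    1          6

tgt <- generate_target(cfg, 99991, "TNEW")
tgt$reference <- NULL                 # ranking is reference-free
head(run_rank(fit$model, tgt, pcfg), 3)
#>   cluster_id wins rank tie_break_key
#> 1          1    4    1         3.816
#> 2          2    3    2         0.440
#> 3          3    2    3        -1.116
```

The cross-validated pairwise classifier reaches ~0.95 accuracy, and in
every held-out fold the cluster containing the lowest-LRMSD pose (the
planted near-native cluster) is ranked first; win counts over k clusters
always sum to k(k−1)/2.

A thin command-line wrapper over the same functions ships at
`inst/cli/clusterrank` (`synth`, `quality`, `cluster`, `train`, `cv`,
`rank`, `screen` subcommands).

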