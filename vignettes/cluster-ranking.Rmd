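---
title: "Ranking clusters of docked protein-protein complexes by pairwise comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking clusters of docked protein-protein complexes by pairwise comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clusterrank)
```

## The problem

Protein-protein docking programs emit thousands of candidate poses
("decoys") per target, of which at most a handful resemble the native
complex. Single-pose scoring with one energy function suffers from false
positives: incorrect binding modes frequently score better than near-native
ones. `clusterrank` instead ranks *clusters* of poses. Clusters represent
candidate binding regions; a cluster is ranked highly when a learned model
predicts, pairwise against every other cluster of the same target, that it
contains the pose with the lower ligand RMSD (LRMSD).

The pipeline is:

1. **Cluster** the decoys of a target by pairwise LRMSD with the GROMOS
   neighbour-count algorithm at a 10 Å cutoff, then keep clusters with
   more than 5 members (small near-native clusters can be exempted by
   hand via `always_include`).
2. **Enrich** (optionally) each cluster with locally re-docked poses:
   the enrichment pool is sub-clustered at 3 Å, sub-clusters are ranked by
   size, and the centroid-closest member of each of the top ten becomes an
   additional observation for the cluster's descriptor distributions.
   Enrichment poses never count toward the cluster-size feature or the
   LRMSD labels.
3. **Featurise**: per-model molecular descriptors (ingested from CSV;
   two exemplar descriptors are computable from coordinates alone) are
   standardized per target, and each cluster is summarised per descriptor
   by five points - MIN, Q1, AVG (the median), Q3, MAX - plus the cluster
   size. With D descriptors a cluster has 5D + 1 features (546 at D = 109).
4. **Learn pairwise**: every unordered pair of clusters of a target is one
   training record of 2(5D + 1) features (1092 at D = 109), labelled 1
   when the first cluster's minimum member LRMSD is strictly lower. An
   extremely randomized trees (ERT) classifier is trained on these records.
5. **Rank** by tournament: each pair is evaluated once; the cluster
   predicted to hold the lower-LRMSD pose collects a win, and clusters are
   ranked by descending win count.

The pairwise formulation has two statistical advantages: it multiplies the
number of training examples (a target with k clusters yields k(k-1)/2
records), and it removes the class imbalance that a direct
near-native-vs-incorrect labelling would suffer from, because every record
compares two clusters rather than classifying one.

## Model quality measures

Quality versus a reference (bound) structure follows the CAPRI conventions,
with one deliberate deviation: LRMSD is computed from C-alpha atoms for
*both* the receptor superposition and the ligand deviation (`lrmsd()`,
backbone available via `atoms = "backbone"`). FNAT is the fraction of
reference receptor-ligand residue contacts (any heavy-atom pair within 5 Å)
preserved in the model; IRMSD superposes on the backbone atoms of the
reference interface residues (any heavy atom within 10 Å of the partner
chain) and reports that fit RMSD. All three cutoffs are arguments. Quality
classes (high / medium / acceptable / incorrect) come from a configurable
threshold table (`capri_thresholds()`); externally supplied class labels can
be used instead where an assessed decoy set provides them.

Superpositions use the Kabsch SVD solution with the determinant correction
that excludes reflections; near-collinear coordinate sets trigger a warning
because the rotation is then ill-determined. The test-suite cross-checks the
implementation against an independent quaternion eigen-decomposition oracle
to 1e-6.

## Steric clashes

A clash is two atoms across the interface overlapping by their van der
Waals radii, `d < r_i + r_j` with strict inequality - touching spheres are
legal. Radii come from a packaged element table (H 1.2, C 1.7, N 1.55,
O 1.52, S 1.8 Å, ...; unknown elements fall back to 1.7 Å with a warning)
and can be replaced via `vdw_radii(file)`. Hydrogens are excluded from
clash checks by default (`include_hydrogens = FALSE`); published radii sets
and the role of hydrogens vary between assessment pipelines, so both are
configurable rather than hard-coded.

## Tunable parameters

| Parameter | Default | Where | Meaning |
|---|---|---|---|
| clustering cutoff | 10 Å | `pipeline_config()` | GROMOS neighbour radius on LRMSD |
| size cutoff | > 5 models | `pipeline_config()` | strict lower bound on cluster size |
| sub-cluster cutoff | 3 Å | `pipeline_config()` | enrichment sub-clustering radius |
| representatives | 10 | `select_enrichment_representatives()` | top sub-clusters kept |
| trees | 3000 | `ert_config()` | ensemble size |
| max features | floor(sqrt(p)) | `ert_config()` | candidate split features (33 at p = 1092) |
| max depth / leaf size | 100 / 1 | `ert_config()` | tree growth limits |
| FNAT contact cutoff | 5 Å | `fnat()` | heavy-atom contact distance |
| IRMSD interface cutoff | 10 Å | `irmsd()` | interface residue selection |
| RFE step | 10 | `recursive_feature_elimination()` | features dropped per round |
| sweep step | 10 | `transform_sweep()` | dimension grid spacing |

## Numerical choices

* **Quartiles** use linear interpolation of order statistics at positions
  `(n - 1) p` (`stats::quantile` type 7). The choice matters because MIN and
  Q1 features dominate the learned models, so it is fixed and documented
  rather than left to a default.
* **Standardisation** uses the population (divide-by-n) standard deviation,
  computed per target over all of the target's models including enrichment
  poses. Zero-variance descriptors become all-zero columns and are flagged.
  The n vs n-1 distinction is immaterial to tree classifiers but is pinned
  for bit-reproducibility.
* **GROMOS tie-breaks**: when two candidate centroids have equal neighbour
  counts the lexicographically smallest model id wins, which makes the
  partition invariant to input order. Neighbourhoods are inclusive
  (`d <= cutoff`).
* **Pair orientation**: each unordered pair is built and evaluated once in
  canonical order (lower cluster id in slot C1). Prediction-time averaging
  of both orientations is available (`ert_config(orientation = "both")`).
  Pairs with exactly equal minimum LRMSD carry no defined label and are
  excluded with a warning.
* **Rank ties** are broken by the summed class-1 probability margin
  (descending), then by cluster id - deterministic by construction.
* **Degenerate inputs**: single-model descriptor tables cannot be
  standardized (error); targets with fewer than two surviving clusters
  cannot be ranked (error naming the size cutoff); an all-clashed model set
  aborts the target with a stage-tagged error.
* **Factor analysis** is maximum-likelihood via EM with a fixed iteration
  cap (default 100, tolerance 1e-3 on the per-observation log-likelihood).
  The EM formulation is used because the classical constraint on the number
  of factors relative to variables would forbid most of the top-down
  dimension grid; the transform is the posterior factor mean. Kernel PCA
  uses an RBF kernel with bandwidth 1/p by default; PCA is exact via SVD.
* **Dimension grids** run top-down from the full feature count to 2 in
  steps of 10 by default (`anchoring = "bottom_up"` starts at 2 instead).
  Within every cross-validation fold the transformer is fitted on the
  training records only and then applied to both splits; the fitted row ids
  are recorded so the leakage contract is testable.
* **Mann-Whitney screening** operates per cluster: each cluster contributes
  its median descriptor value and clusters are grouped into near-native
  (containing at least one acceptable-or-better model) versus incorrect.
  Per-model pooling is available via `aggregate = "model"`. Significance
  tiers are `***` < 1e-4, `**` < 1e-3, `*` < 1e-2.
* The median is reported under the token `AVG` in feature names
  (`C2_Q1_N_CP_TB`-style), keeping the established naming convention even
  though the statistic is the median.

## The synthetic benchmark

`generate_benchmark()` produces fully self-contained targets so that every
stage is testable without external decoy sets:

* **Geometry**: a rigid ~30-residue C-alpha helix receptor and a
  ~20-residue ligand. One reference pose sits in surface contact (8 Å
  backbone gap). Cluster centres are placed on a sphere around the receptor
  via a Fibonacci lattice scaled so centres are at least 3 clustering
  cutoffs apart; with probability `planted_prob` one centre is perturbed
  onto the reference pose (the planted near-native cluster). Members are
  rigid rotation + translation perturbations of their centre pose, bounded
  by `cluster_spread` (default 4 Å, at most half the clustering cutoff so
  the planted partition is recoverable) and redrawn if they clash with the
  receptor.
* **Cluster sizes** follow a discrete power law (Pareto tail, exponent 2.5,
  minimum 6, cap 60): a few large clusters, many small ones - the size
  imbalance the five-point features have to cope with.
* **Descriptors** are noisy monotone transforms of the per-model LRMSD. The
  configured `rho` is the realised Pearson correlation: the noise component
  (a Gaussian / scaled-t3 mixture, with the heavy-tailed part injected as
  *low-value* outliers at rate `outlier_frac`) is standardized and
  orthogonalized against the LRMSD before mixing, so correlation checks
  hold without per-seed luck while the tails mimic the deceptive
  favourable-energy outliers that make incorrect clusters hard to reject.
  Separate seed streams drive geometry and descriptors, so descriptor noise
  can be varied with geometry held fixed.

What the generator does **not** emulate: physically realistic energetics,
flexible-backbone decoys, receptor conformational variability between
models, heterogeneous chain truncation, and descriptor-descriptor
correlation structure beyond what the shared LRMSD dependence induces.
Passing the simulation tests therefore demonstrates that the protocol's
machinery (clustering, featurisation, pairwise learning, ranking,
selection) behaves correctly and recovers planted signal under realistic
noise and outlier contamination - not that any particular accuracy will be
attained on real decoy sets, which depend on the quality of the real
descriptors.

## Study conditions used by the tests

The reference simulation conditions are the `synth_config()` defaults:
8 targets of 10 clusters, descriptor-LRMSD correlation 0.9, 5% outliers,
12 descriptors. The end-to-end recovery test runs these conditions over
5 seeds with the forest reduced to 300 trees, and requires the planted
near-native cluster at mean leave-complex-out rank <= 2 with mean pairwise
accuracy > 0.8. Unit tests use smaller instances (2-6 targets, 3-8
clusters, 30-80 trees) chosen to exercise the code paths at second-scale
runtimes; the feature-arithmetic checks use D = 109 to pin the 546/1092
feature counts, and the comparison-matrix census uses the 11-target
cluster counts (49, 24, 12, 12, 44, 57, 25, 35, 20, 42, 49), which sum to
7248 records.

## A worked run

```{r example, eval = FALSE}
cfg <- synth_config(n_targets = 4, clusters_per_target = 6,
                    n_descriptors = 8, seed = 42)
bench <- generate_benchmark(cfg)
pcfg <- pipeline_config(ert = ert_config(n_trees = 500, seed = 42))
fit <- run_train(bench, pcfg)
fit$cv                      # leave-complex-out classification metrics
cv_rank_eval(fit, pcfg)     # rank of the best cluster per held-out target

tgt <- generate_target(cfg, 99991, "TNEW")
tgt$reference <- NULL       # ranking is reference-free
run_rank(fit$model, tgt, pcfg)
```

## Known limitations

* The 109-descriptor panel of the original protocol is not re-implemented;
  the package is descriptor-agnostic (any numeric CSV), with two built-in
  exemplars (`residue_contact_potential()`, `atomic_contact_count()`) that
  allow an end-to-end run from PDB files alone.
* Enrichment pose *generation* (local re-docking) is out of scope; the
  package consumes externally produced pools or synthetic stand-ins.
* Pairwise LRMSD matrices are computed densely in R; hundreds of models per
  target are second-scale, tens of thousands are not.
* The win-count tournament is not guaranteed transitive; ties and
  near-cycles are resolved by the probability-margin key.
* `mmCIF` input, hydrogen placement and side-chain rebuilding are not
  supported.
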