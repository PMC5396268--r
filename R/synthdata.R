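# Synthetic multi-target decoy benchmark with known ground truth:
# rigid toy receptor/ligand C-alpha scaffolds, planted cluster structure
# with power-law sizes, and descriptor columns correlated with LRMSD at
# configurable strength plus heavy-tailed low-energy outliers.

#' Synthetic benchmark configuration
#'
#' The defaults define the reference study conditions used throughout the
#' package's simulation tests: 8 targets of 10 clusters each, descriptor
#' columns with Pearson correlation 0.9 to per-model LRMSD, and a 5%
#' admixture of heavy-tailed low-energy outliers (mimicking the failure
#' mode where incorrect poses score deceptively well). Cluster sizes
#' follow a discrete power law with minimum 6, so all clusters survive the
#' "> 5 models" size cutoff.
#'
#' @param n_targets Number of targets.
#' @param clusters_per_target Clusters planted per target.
#' @param cluster_size_min Minimum cluster population.
#' @param cluster_size_alpha Power-law (Pareto) exponent of cluster sizes.
#' @param cluster_size_cap Upper bound on cluster population.
#' @param n_descriptors Number D of descriptor columns.
#' @param rho Descriptor-LRMSD Pearson correlation; scalar or named vector
#'   by category code (rc, ac, sp, cs, se, hb, ve, mi).
#' @param outlier_frac Fraction of models whose descriptor noise comes
#'   from the heavy-tailed (t, 3 df) component, injected as low-value
#'   (favourable-energy) outliers.
#' @param outlier_scale Scale of the heavy-tailed component relative to
#'   the Gaussian component.
#' @param planted_prob Probability that a target has a planted near-native
#'   cluster at the reference pose.
#' @param cluster_cutoff Clustering cutoff the geometry is scaled to, A.
#' @param cluster_spread Maximum member LRMSD to its cluster centre, A;
#'   must be <= cluster_cutoff / 2 so planted clusters are recoverable.
#' @param separation_factor Minimum inter-centre separation in units of
#'   `cluster_cutoff`.
#' @param receptor_residues,ligand_residues Sizes of the toy chains.
#' @param n_holdout Number of trailing targets marked hold-out.
#' @param seed Master seed; per-target geometry and descriptor streams are
#'   derived from it.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_targets = 8, clusters_per_target = 10,
                         cluster_size_min = 6, cluster_size_alpha = 2.5,
                         cluster_size_cap = 60,
                         n_descriptors = 12, rho = 0.9,
                         outlier_frac = 0.05, outlier_scale = 4,
                         planted_prob = 1,
                         cluster_cutoff = 10, cluster_spread = 4,
                         separation_factor = 3,
                         receptor_residues = 30, ligand_residues = 20,
                         n_holdout = 0, seed = 1) {
  stopifnot(n_descriptors >= 1, outlier_frac >= 0, outlier_frac < 1,
            all(rho >= -1), all(rho <= 1))
  structure(as.list(environment()), class = "synth_config")
}

.categories <- c("rc", "ac", "sp", "cs", "se", "hb", "ve", "mi")

synth_descriptor_names <- function(d) {
  cats <- rep(.categories, length.out = d)
  sprintf("N_%s_%02d", toupper(cats), seq_len(d))
}

#' Descriptor metadata of a synthetic benchmark
#'
#' @param config A `synth_config`.
#' @return data.frame(name, category), categories assigned round-robin.
#' @export
synth_descriptor_meta <- function(config) {
  d <- config$n_descriptors
  descriptor_meta(synth_descriptor_names(d),
                  rep(.categories, length.out = d))
}

# ideal alpha-helix C-alpha trace, centred at the origin, axis = z
helix_ca <- function(n, radius = 2.3, rise = 1.5, turn = 100 * pi / 180) {
  i <- seq_len(n) - 1
  xyz <- cbind(radius * cos(i * turn), radius * sin(i * turn), rise * i)
  sweep(xyz, 2, colMeans(xyz))
}

# near-uniform unit directions (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# random rotation matrix with given angle about a random axis
random_rotation <- function(angle) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  k <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
}

ca_atoms <- function(xyz, chain, resid = "ALA") {
  n <- nrow(xyz)
  data.frame(chain = chain, resno = seq_len(n), insert = "",
             resid = resid, elety = "CA", elesy = "C",
             alt = NA_character_, o = 1,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

# pose = rotation of centred ligand template + centre position
ligand_pose <- function(template, rot, centre) {
  sweep(template %*% t(rot), 2, centre, "+")
}

#' Generate one synthetic target
#'
#' Builds a rigid toy receptor (C-alpha helix scaffold) and a reference
#' ligand pose in surface contact, plants `clusters_per_target` cluster
#' centres (one near the reference with probability `planted_prob`, the
#' rest well separated on a sphere around the receptor), populates each
#' cluster with rigid rotation/translation perturbations of the centre
#' pose bounded by `cluster_spread`, and draws descriptor columns as
#' correlated noisy transforms of the per-model LRMSD with heavy-tailed
#' low-value outliers. Geometry and descriptors use separate seed streams,
#' so descriptor noise can be varied with geometry held fixed.
#'
#' @param config A `synth_config`.
#' @param target_seed Integer seed for this target.
#' @param target_id Target identifier.
#' @return List: `target_id`, `models` (list of `complex_model`),
#'   `reference` (`complex_model`), `descriptors` (raw
#'   `descriptor_table`), `truth` (cluster assignment, per-model LRMSD,
#'   planted and best cluster ids).
#' @export
generate_target <- function(config, target_seed, target_id = "T01") {
  stopifnot(inherits(config, "synth_config"))
  if (config$cluster_spread > config$cluster_cutoff / 2)
    stop("infeasible geometry: cluster_spread exceeds half the cutoff")
  set.seed(target_seed)                       # geometry stream
  rec_xyz <- helix_ca(config$receptor_residues)
  lig_template <- helix_ca(config$ligand_residues)
  # reference pose: ligand axis parallel to receptor, 8 A surface gap
  gap <- 8
  d0 <- gap + 4.6                              # two helix radii
  ref_centre <- c(d0, 0, 0)
  ref_rot <- diag(3)

  k <- config$clusters_per_target
  planted <- stats::runif(1) < config$planted_prob
  sep_min <- config$separation_factor * config$cluster_cutoff
  n_far <- if (planted) k - 1 else k
  # lattice directions, rotated so the first points along +x, then dropped
  # so far centres stay away from the reference pocket
  u <- fibonacci_sphere(n_far + 1)
  v1 <- u[1, ]
  ax <- c(1, 0, 0)
  w <- v1 + ax
  refl <- diag(3) - 2 * tcrossprod(w) / sum(w^2)   # maps v1 -> -ax
  u <- -(u %*% t(refl))                            # now u[1,] == +x
  u <- u[-1, , drop = FALSE]
  radius <- sep_min / min(stats::dist(u))
  repeat {
    centres <- u * radius
    ok <- all(sqrt(rowSums(sweep(centres, 2, ref_centre)^2)) >= sep_min)
    if (ok) break
    radius <- radius * 1.1
  }
  centre_list <- list()
  rot_list <- list()
  if (planted) {
    off <- stats::rnorm(3)
    off <- off / sqrt(sum(off^2)) * stats::runif(1, 0.5, 1.5)
    centre_list[[1]] <- ref_centre + off
    rot_list[[1]] <- random_rotation(stats::runif(1, 0, 0.05))
  }
  for (i in seq_len(n_far)) {
    centre_list[[length(centre_list) + 1]] <- centres[i, ]
    rot_list[[length(rot_list) + 1]] <-
      random_rotation(stats::runif(1, 0, pi))
  }

  # power-law cluster populations
  uu <- stats::runif(k)
  sizes <- pmin(floor(config$cluster_size_min * uu^(-1 / config$cluster_size_alpha)),
                config$cluster_size_cap)

  rg_max <- sqrt(max(rowSums(lig_template^2)))
  theta_max <- 2 * asin(min(1, config$cluster_spread / (4 * rg_max)))
  ref_lig <- ligand_pose(lig_template, ref_rot, ref_centre)
  models <- list()
  cluster_of <- integer(0)
  lrmsd_truth <- numeric(0)
  idx <- 0
  for (ci in seq_len(k)) {
    for (mi in seq_len(sizes[ci])) {
      for (try in 1:25) {
        rot <- rot_list[[ci]] %*% random_rotation(stats::runif(1, 0, theta_max))
        tr <- stats::rnorm(3, 0, config$cluster_spread / 4)
        pose <- ligand_pose(lig_template, rot, centre_list[[ci]] + tr)
        centre_pose <- ligand_pose(lig_template, rot_list[[ci]],
                                   centre_list[[ci]])
        # keep the pose within the cluster spread and van der Waals legal
        if (rmsd_of(pose, centre_pose) <= config$cluster_spread &&
            min(cross_dist(rec_xyz, pose)) >= 3.5) break
      }
      idx <- idx + 1
      mid <- sprintf("m%04d", idx)
      models[[idx]] <- new_complex_model(
        mid, target_id, ca_atoms(rec_xyz, "A"), ca_atoms(pose, "B"))
      cluster_of[mid] <- ci
      lrmsd_truth[mid] <- rmsd_of(pose, ref_lig)
    }
  }
  reference <- new_complex_model("reference", target_id,
                                 ca_atoms(rec_xyz, "A"),
                                 ca_atoms(ref_lig, "B"))

  set.seed(target_seed + 1000003L)             # descriptor stream
  d <- config$n_descriptors
  cats <- rep(.categories, length.out = d)
  rho <- config$rho
  rho_of <- function(cat) {
    if (length(rho) == 1 && is.null(names(rho))) return(rho)
    if (!cat %in% names(rho)) stop("no rho for category ", cat)
    rho[[cat]]
  }
  n <- length(models)
  zl <- (lrmsd_truth - mean(lrmsd_truth)) / sd_pop(lrmsd_truth)
  vals <- matrix(0, n, d,
                 dimnames = list(names(lrmsd_truth),
                                 synth_descriptor_names(d)))
  for (j in seq_len(d)) {
    r <- rho_of(cats[j])
    e <- stats::rnorm(n)
    out <- stats::runif(n) < config$outlier_frac
    if (any(out))
      e[out] <- -abs(stats::rt(sum(out), df = 3)) * config$outlier_scale
    e <- (e - mean(e)) / sd_pop(e)
    # project out the sample correlation with zl so the realised
    # descriptor-LRMSD correlation is r up to outlier-tail jitter
    e <- e - zl * sum(e * zl) / sum(zl * zl)
    e <- e / sd_pop(e)
    z <- r * zl + sqrt(1 - r^2) * e
    vals[, j] <- z * exp(stats::runif(1, -0.5, 1.5)) + stats::rnorm(1, 0, 10)
  }
  truth <- list(target_id = target_id,
                cluster_of = cluster_of,
                lrmsd = lrmsd_truth,
                planted_cluster = if (planted) 1L else NA_integer_,
                best_cluster = unname(cluster_of[which.min(lrmsd_truth)]),
                geometry_seed = target_seed,
                descriptor_seed = target_seed + 1000003L)
  list(target_id = target_id, models = models, reference = reference,
       descriptors = new_descriptor_table(target_id, vals),
       truth = truth)
}

#' Generate a synthetic benchmark
#'
#' Generates `n_targets` targets with per-target seeds derived from the
#' master seed. With `out_dir = NULL` the benchmark is returned in memory;
#' otherwise each target is written to `<out_dir>/<target>/` as
#' `models.pdb` (multi-MODEL), `reference.pdb`, `descriptors.csv` and
#' `truth.json`, with a top-level `manifest.yaml`.
#'
#' @param config A `synth_config`.
#' @param out_dir Output directory or `NULL`.
#' @param force Overwrite an existing non-empty directory?
#' @return List of class `synth_benchmark`: `targets` (list of
#'   [generate_target()] outputs), `manifest` (target ids, training /
#'   hold-out split, seeds).
#' @export
generate_benchmark <- function(config, out_dir = NULL, force = FALSE) {
  stopifnot(inherits(config, "synth_config"), config$n_targets >= 2)
  ids <- sprintf("T%02d", seq_len(config$n_targets))
  seeds <- config$seed + 7919L * seq_len(config$n_targets)
  targets <- Map(function(id, s) generate_target(config, s, id), ids, seeds)
  holdout <- if (config$n_holdout > 0) utils::tail(ids, config$n_holdout)
             else character(0)
  manifest <- list(target_ids = ids,
                   training = setdiff(ids, holdout),
                   holdout = holdout,
                   seed = config$seed, target_seeds = seeds,
                   n_descriptors = config$n_descriptors,
                   cluster_cutoff = config$cluster_cutoff)
  bench <- structure(list(targets = targets, manifest = manifest),
                     class = "synth_benchmark")
  if (!is.null(out_dir)) write_benchmark(bench, out_dir, force)
  bench
}

write_benchmark <- function(bench, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force)
    stop("output directory not empty (use force = TRUE): ", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (tgt in bench$targets) {
    td <- file.path(out_dir, tgt$target_id)
    dir.create(td, showWarnings = FALSE)
    write_models_pdb(tgt$models, file.path(td, "models.pdb"))
    write_models_pdb(list(tgt$reference), file.path(td, "reference.pdb"))
    utils::write.csv(
      cbind(data.frame(model_id = rownames(tgt$descriptors$values)),
            as.data.frame(tgt$descriptors$values)),
      file.path(td, "descriptors.csv"), row.names = FALSE)
    jsonlite::write_json(tgt$truth, file.path(td, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  yaml::write_yaml(bench$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Read a benchmark directory written by [generate_benchmark()]
#'
#' @param dir Benchmark directory containing `manifest.yaml`.
#' @return A `synth_benchmark` list (truth is included when present).
#' @export
read_benchmark <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  targets <- lapply(manifest$target_ids, function(id) {
    td <- file.path(dir, id)
    models <- read_models(file.path(td, "models.pdb"), "A", "B", id)
    reference <- read_models(file.path(td, "reference.pdb"), "A", "B", id)[[1]]
    reference$model_id <- "reference"
    desc <- read_descriptor_table(
      file.path(td, "descriptors.csv"), id,
      known_model_ids = vapply(models, `[[`, character(1), "model_id"))
    truth_file <- file.path(td, "truth.json")
    truth <- if (file.exists(truth_file))
      jsonlite::read_json(truth_file, simplifyVector = TRUE)
    list(target_id = id, models = models, reference = reference,
         descriptors = desc, truth = truth)
  })
  names(targets) <- manifest$target_ids
  structure(list(targets = targets, manifest = manifest),
            class = "synth_benchmark")
}

#' Generate synthetic enrichment poses around one cluster
#'
#' Produces locally resampled ligand poses arranged into `n_subclusters`
#' well-separated sub-clusters (inter-centre distance above
#' `sub_separation`, intra-sub-cluster spread below `sub_spread`), as a
#' stand-in for locally re-docked poses feeding the enrichment
#' representative selection.
#'
#' @param n_subclusters Number of planted sub-clusters.
#' @param poses_per_subcluster Poses per sub-cluster.
#' @param sub_separation Minimum distance between sub-cluster centres, A.
#' @param sub_spread Maximum pose RMSD to its sub-cluster centre, A.
#' @param seed Integer seed.
#' @param target_id Target identifier for the generated models.
#' @return List of `complex_model` with `source = "enrichment"`.
#' @export
generate_enrichment_poses <- function(n_subclusters = 12,
                                      poses_per_subcluster = 5,
                                      sub_separation = 4.5,
                                      sub_spread = 1.0,
                                      seed = 1, target_id = "T01") {
  stopifnot(sub_separation > 2 * sub_spread)
  set.seed(seed)
  rec_xyz <- helix_ca(30)
  lig_template <- helix_ca(20)
  base <- c(10.6, 0, 0)
  # sub-cluster centres on a line + lattice jitter, pairwise >= separation
  u <- fibonacci_sphere(n_subclusters)
  radius <- sub_separation / min(stats::dist(u))
  centres <- sweep(u * radius, 2, base, "+")
  models <- list()
  idx <- 0
  for (ci in seq_len(n_subclusters)) {
    rot0 <- random_rotation(stats::runif(1, 0, pi / 8))
    # descending sizes so sub-cluster ranking by size is unambiguous
    n_poses <- poses_per_subcluster + (n_subclusters - ci)
    for (mi in seq_len(n_poses)) {
      tr <- stats::rnorm(3)
      tr <- tr / sqrt(sum(tr^2)) * stats::runif(1, 0, sub_spread * 0.9)
      pose <- ligand_pose(lig_template, rot0, centres[ci, ] + tr)
      idx <- idx + 1
      models[[idx]] <- new_complex_model(
        sprintf("e%04d", idx), target_id,
        ca_atoms(rec_xyz, "A"), ca_atoms(pose, "B"),
        source = "enrichment")
    }
  }
  models
}
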