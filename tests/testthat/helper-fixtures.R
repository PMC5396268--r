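# Fixture builders and independent oracles shared across the test files.
# All fixtures are built in code; oracles deliberately avoid the code
# paths they check.

helix <- function(n) clusterrank:::helix_ca(n)

ca_df <- function(xyz, chain, resid = "ALA") {
  clusterrank:::ca_atoms(xyz, chain, resid)
}

mk_model <- function(rec_xyz, lig_xyz, id = "m1", target = "T01",
                     source = "scoreset_like") {
  clusterrank:::new_complex_model(id, target,
                                  ca_df(rec_xyz, "A"), ca_df(lig_xyz, "B"),
                                  source = source)
}

# one residue with backbone atoms (N, CA, C, O) near `centre`
residue_atoms <- function(centre, chain, resno, resid = "ALA") {
  off <- rbind(N = c(-1.2, 0.5, 0), CA = c(0, 0, 0),
               C = c(1.2, 0.4, 0), O = c(1.9, 1.4, 0))
  data.frame(chain = chain, resno = resno, insert = "", resid = resid,
             elety = rownames(off), elesy = substr(rownames(off), 1, 1),
             alt = NA_character_, o = 1,
             x = centre[1] + off[, 1], y = centre[2] + off[, 2],
             z = centre[3] + off[, 3], stringsAsFactors = FALSE)
}

mk_backbone_model <- function(rec_centres, lig_centres, id = "m1",
                              target = "T01") {
  rec <- do.call(rbind, lapply(seq_len(nrow(rec_centres)), function(i)
    residue_atoms(rec_centres[i, ], "A", i)))
  lig <- do.call(rbind, lapply(seq_len(nrow(lig_centres)), function(i)
    residue_atoms(lig_centres[i, ], "B", i)))
  clusterrank:::new_complex_model(id, target, rec, lig)
}

random_rot <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rigid_move <- function(xyz, rot, shift) {
  sweep(xyz %*% t(rot), 2, shift, "+")
}

transform_model <- function(model, rot, shift) {
  for (part in c("receptor", "ligand")) {
    xyz <- rigid_move(cbind(model[[part]]$x, model[[part]]$y,
                            model[[part]]$z), rot, shift)
    model[[part]]$x <- xyz[, 1]
    model[[part]]$y <- xyz[, 2]
    model[[part]]$z <- xyz[, 3]
  }
  model
}

# --- quaternion (Horn) superposition oracle -------------------------------
# Independent of the SVD-based implementation: builds the 4x4 key matrix
# whose leading eigenvector is the optimal rotation quaternion.
quaternion_superpose <- function(ref, mov) {
  rc <- sweep(ref, 2, colMeans(ref))
  mc <- sweep(mov, 2, colMeans(mov))
  m <- crossprod(mc, rc)
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  key <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,       -sxx - syy + szz),
    4, 4, byrow = TRUE)
  e <- eigen(key, symmetric = TRUE)
  q <- e$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rot <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z),   2 * (x * z + w * y),
    2 * (x * y + w * z),   w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y),   2 * (y * z + w * x),   w^2 - x^2 - y^2 + z^2),
    3, 3, byrow = TRUE)
  fitted <- mc %*% t(rot)
  list(rotation = rot,
       fit_rmsd = sqrt(mean(rowSums((fitted - rc)^2))))
}

# --- exhaustive Mann-Whitney U oracle -------------------------------------
# U statistic by direct pair counting and its exact two-sided p-value by
# enumeration of all group assignments of the pooled sample.
exact_mannwhitney <- function(x, y) {
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_stat(x, y)
  pooled <- c(x, y)
  n1 <- length(x)
  picks <- utils::combn(length(pooled), n1)
  us <- apply(picks, 2, function(ix)
    u_stat(pooled[ix], pooled[-ix]))
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  list(u = u_obs, p = min(1, 2 * min(p_lo, p_hi)))
}

# --- brute-force GROMOS oracle --------------------------------------------
# Literal restatement of the algorithm with explicit loops; ties broken by
# the smallest id, matching the documented tie-break.
gromos_oracle <- function(ids, d, cutoff) {
  remaining <- seq_along(ids)
  out <- list()
  while (length(remaining) > 0) {
    counts <- sapply(remaining, function(i)
      sum(d[i, remaining] <= cutoff))
    cand <- remaining[counts == max(counts)]
    centroid <- cand[order(ids[cand])][1]
    members <- remaining[d[centroid, remaining] <= cutoff]
    out[[length(out) + 1]] <- list(members = sort(ids[members]),
                                   centroid = ids[centroid])
    remaining <- setdiff(remaining, members)
  }
  out
}

rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# random cluster_features object for pair-learning tests
mk_cf <- function(cluster_id, values, names = NULL) {
  if (is.null(names)) names <- sprintf("F%02d", seq_along(values))
  structure(list(cluster_id = as.integer(cluster_id),
                 feature_names = names,
                 values = stats::setNames(values, names)),
            class = "cluster_features")
}

# a set of targets whose single informative feature is monotone in the
# cluster minimum LRMSD, for separable-learning fixtures
mk_monotone_targets <- function(n_targets, k, n_features = 4, noise = 0.05,
                                seed = 1) {
  set.seed(seed)
  out <- list()
  for (t in seq_len(n_targets)) {
    ml <- runif(k, 1, 40) + seq_len(k) * 1e-3
    feats <- lapply(seq_len(k), function(i) {
      v <- c(ml[i] / 40 + rnorm(1, 0, noise),
             rnorm(n_features - 1))
      mk_cf(i, v)
    })
    out[[sprintf("S%02d", t)]] <- list(features = feats,
                                       min_lrmsd = stats::setNames(ml, seq_len(k)))
  }
  out
}

write_pdb_fixture <- function(lines, file = tempfile(fileext = ".pdb")) {
  writeLines(lines, file)
  file
}

atom_line <- function(eleno, elety, resid, chain, resno, x, y, z,
                      occ = 1, b = 0, elesy = substr(elety, 1, 1),
                      alt = " ") {
  sprintf("ATOM  %5d  %-3s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          eleno, elety, alt, resid, chain, resno, x, y, z, occ, b, elesy)
}
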