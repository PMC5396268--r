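# CAPRI-style model quality measures: LRMSD, IRMSD, FNAT and quality
# classes, built on least-squares rigid superposition.

#' Least-squares rigid superposition (Kabsch)
#'
#' Computes the proper rotation and translation minimising the RMSD of
#' `mov_coords` onto `ref_coords` by singular value decomposition of the
#' covariance matrix, with the determinant correction that excludes
#' reflections.
#'
#' @param ref_coords,mov_coords N x 3 coordinate matrices with rows in 1:1
#'   correspondence; N >= 3.
#' @return Object of class `rigid_superposition`: `rotation` (3 x 3,
#'   det +1), `translation` (length-3), `fit_rmsd`. The transform maps a
#'   moving-frame point y to `rotation %*% y + translation`.
#' @export
kabsch_superpose <- function(ref_coords, mov_coords) {
  ref_coords <- as.matrix(ref_coords)
  mov_coords <- as.matrix(mov_coords)
  if (nrow(ref_coords) < 3) stop("need at least 3 atom pairs to superpose")
  if (!all(dim(ref_coords) == dim(mov_coords)))
    stop("coordinate sets differ in shape")
  mu_r <- colMeans(ref_coords)
  mu_m <- colMeans(mov_coords)
  rc <- sweep(ref_coords, 2, mu_r)
  mc <- sweep(mov_coords, 2, mu_m)
  sv_m <- svd(mc)$d
  if (sv_m[2] < 1e-9 * max(sv_m[1], 1))
    warning("(near-)collinear coordinates: rotation is ill-determined",
            call. = FALSE)
  h <- crossprod(mc, rc)              # 3 x 3 covariance
  s <- svd(h)
  d <- sign(det(tcrossprod(s$v, s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- as.numeric(mu_r - rot %*% mu_m)
  fitted <- mc %*% t(rot)
  structure(
    list(rotation = rot, translation = trans,
         fit_rmsd = rmsd_of(fitted, rc)),
    class = "rigid_superposition")
}

apply_superposition <- function(sp, coords) {
  sweep(as.matrix(coords) %*% t(sp$rotation), 2, sp$translation, "+")
}

# Coordinates of the atoms named in `atom_names`, ordered by residue key
# (and atom name), matched 1:1 between model and reference. Errors list
# the mismatching keys.
matched_coords <- function(model, reference, part, atom_names = "CA") {
  pick <- function(m) {
    at <- m[[part]]
    at <- at[at$elety %in% atom_names, , drop = FALSE]
    key <- paste(residue_keys(at), at$elety, sep = "|")
    at <- at[order(key), , drop = FALSE]
    list(key = sort(key), xyz = atom_xyz(at))
  }
  a <- pick(model)
  b <- pick(reference)
  if (!identical(a$key, b$key)) {
    miss <- c(setdiff(a$key, b$key), setdiff(b$key, a$key))
    stop("unmatched ", part, " atoms between model and reference: ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ..." else "")
  }
  list(model = a$xyz, reference = b$xyz)
}

#' Ligand RMSD after receptor superposition
#'
#' Superposes the model's receptor C-alpha atoms onto the reference
#' receptor, applies the transform to the model's ligand C-alpha atoms and
#' returns their RMSD to the reference ligand. Using C-alpha atoms for both
#' the superposition and the deviation (rather than full backbone) is the
#' default; set `atoms = "backbone"` for N, CA, C, O.
#'
#' @param model,reference `complex_model` objects sharing receptor and
#'   ligand residue sets.
#' @param atoms `"CA"` (default) or `"backbone"`.
#' @return LRMSD in Angstrom.
#' @export
lrmsd <- function(model, reference, atoms = c("CA", "backbone")) {
  atoms <- match.arg(atoms)
  sel <- if (atoms == "CA") "CA" else c("N", "CA", "C", "O")
  rec <- matched_coords(model, reference, "receptor", sel)
  lig <- matched_coords(model, reference, "ligand", sel)
  sp <- kabsch_superpose(rec$reference, rec$model)
  rmsd_of(apply_superposition(sp, lig$model), lig$reference)
}

# receptor-ligand residue contacts: unique (receptor key, ligand key)
# pairs with any heavy-atom pair within cutoff
residue_contacts <- function(model, cutoff) {
  rec <- heavy_atoms(model$receptor)
  lig <- heavy_atoms(model$ligand)
  d <- cross_dist(atom_xyz(rec), atom_xyz(lig))
  hit <- which(d <= cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0) return(character(0))
  unique(paste(residue_keys(rec)[hit[, 1]],
               residue_keys(lig)[hit[, 2]], sep = " :: "))
}

#' Fraction of native contacts
#'
#' Native contacts are receptor-ligand residue pairs in the reference with
#' any heavy-atom pair within `contact_cutoff` (default 5 A). Returns the
#' fraction of those pairs also in contact in the model.
#'
#' @inheritParams lrmsd
#' @param contact_cutoff Heavy-atom contact cutoff in Angstrom.
#' @return Fraction in \[0, 1\].
#' @export
fnat <- function(model, reference, contact_cutoff = 5.0) {
  native <- residue_contacts(reference, contact_cutoff)
  if (length(native) == 0)
    stop("reference has no native contacts at ", contact_cutoff, " A")
  modeled <- residue_contacts(model, contact_cutoff)
  length(intersect(native, modeled)) / length(native)
}

#' Interface RMSD
#'
#' Interface residues are reference residues (of either chain) with any
#' heavy atom within `interface_cutoff` of the partner chain. The model is
#' superposed onto the reference on the backbone atoms (N, CA, C, O) of
#' those residues and the superposition RMSD is returned.
#'
#' @inheritParams lrmsd
#' @param interface_cutoff Heavy-atom cutoff defining the interface, A.
#' @param atoms `"backbone"` (default) or `"CA"`.
#' @return IRMSD in Angstrom.
#' @export
irmsd <- function(model, reference, interface_cutoff = 10.0,
                  atoms = c("backbone", "CA")) {
  atoms <- match.arg(atoms)
  sel <- if (atoms == "CA") "CA" else c("N", "CA", "C", "O")
  rec <- heavy_atoms(reference$receptor)
  lig <- heavy_atoms(reference$ligand)
  d <- cross_dist(atom_xyz(rec), atom_xyz(lig))
  hit <- which(d <= interface_cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0) stop("no interface residues at ", interface_cutoff, " A")
  rec_keys <- unique(residue_keys(rec)[hit[, 1]])
  lig_keys <- unique(residue_keys(lig)[hit[, 2]])
  grab <- function(m) {
    r <- m$receptor[residue_keys(m$receptor) %in% rec_keys &
                      m$receptor$elety %in% sel, , drop = FALSE]
    l <- m$ligand[residue_keys(m$ligand) %in% lig_keys &
                    m$ligand$elety %in% sel, , drop = FALSE]
    at <- rbind(r, l)
    key <- paste(residue_keys(at), at$elety, sep = "|")
    at <- at[order(key), , drop = FALSE]
    list(key = sort(key), xyz = atom_xyz(at))
  }
  a <- grab(model)
  b <- grab(reference)
  if (!identical(a$key, b$key))
    stop("unmatched interface atoms between model and reference")
  kabsch_superpose(b$xyz, a$xyz)$fit_rmsd
}

#' Default CAPRI-style class thresholds
#'
#' One row per class (best first); a model gets the first class whose
#' conditions `fnat >= fnat_min & (lrmsd <= lrmsd_max | irmsd <= irmsd_max)`
#' hold, else `"incorrect"`.
#'
#' @return data.frame with columns class, fnat_min, lrmsd_max, irmsd_max.
#' @export
capri_thresholds <- function() {
  data.frame(
    class = c("high", "medium", "acceptable"),
    fnat_min = c(0.5, 0.3, 0.1),
    lrmsd_max = c(1, 5, 10),
    irmsd_max = c(1, 2, 4),
    stringsAsFactors = FALSE)
}

#' Assign a CAPRI-style quality class
#'
#' @param fnat,lrmsd,irmsd Quality measures of one model.
#' @param thresholds Threshold table, see [capri_thresholds()].
#' @return One of `"high"`, `"medium"`, `"acceptable"`, `"incorrect"`.
#' @export
capri_class <- function(fnat, lrmsd, irmsd, thresholds = capri_thresholds()) {
  for (i in seq_len(nrow(thresholds))) {
    t <- thresholds[i, ]
    if (fnat >= t$fnat_min && (lrmsd <= t$lrmsd_max || irmsd <= t$irmsd_max))
      return(t$class)
  }
  "incorrect"
}

#' Quality report for a set of models against a reference
#'
#' @param models List of `complex_model` (residue sets shared with the
#'   reference, see [truncate_to_shared_residues()]).
#' @param reference Reference (bound) `complex_model`.
#' @param file Optional CSV output path.
#' @param thresholds Class threshold table.
#' @param contact_cutoff FNAT contact cutoff, Angstrom (raise for
#'   coarse-grained C-alpha-only models).
#' @param interface_cutoff IRMSD interface cutoff, Angstrom.
#' @return data.frame: model_id, lrmsd, irmsd, fnat, capri_class.
#' @export
quality_report <- function(models, reference, file = NULL,
                           thresholds = capri_thresholds(),
                           contact_cutoff = 5.0, interface_cutoff = 10.0) {
  rows <- lapply(models, function(m) {
    l <- lrmsd(m, reference)
    i <- irmsd(m, reference, interface_cutoff)
    f <- fnat(m, reference, contact_cutoff)
    data.frame(model_id = m$model_id, lrmsd = l, irmsd = i, fnat = f,
               capri_class = capri_class(f, l, i, thresholds),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
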