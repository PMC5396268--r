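# Reading docked models from (multi-model) PDB files, residue-set
# normalisation across models, and van der Waals clash detection.

.radii_cache <- new.env(parent = emptyenv())

#' Van der Waals radii table
#'
#' Returns the element -> radius (Angstrom) lookup used for steric-clash
#' detection. The packaged defaults (H 1.2, C 1.7, N 1.55, O 1.52, S 1.8, ...)
#' can be overridden by pointing `file` at a two-column TSV
#' (`element`, `radius`).
#'
#' @param file Optional path to a TSV radii table.
#' @return Named numeric vector of radii in Angstrom, names are upper-case
#'   element symbols.
#' @export
vdw_radii <- function(file = NULL) {
  if (is.null(file)) {
    if (!is.null(.radii_cache$default)) return(.radii_cache$default)
    file <- system.file("extdata", "vdw_radii.tsv", package = "clusterrank")
    tab <- utils::read.delim(file, stringsAsFactors = FALSE)
    r <- stats::setNames(tab$radius, toupper(tab$element))
    .radii_cache$default <- r
    return(r)
  }
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  stats::setNames(tab$radius, toupper(tab$element))
}

# Best-effort element symbol from a PDB atom name when the element column
# is absent ("CA" -> C, "1HG1" -> H, "NE2" -> N).
guess_element <- function(elety) {
  s <- gsub("[0-9' ]", "", elety)
  toupper(substr(s, 1, 1))
}

new_complex_model <- function(model_id, target_id, receptor, ligand,
                              source = "scoreset_like") {
  stopifnot(nrow(receptor) > 0, nrow(ligand) > 0)
  structure(
    list(model_id = model_id, target_id = target_id,
         receptor = receptor, ligand = ligand, source = source),
    class = "complex_model")
}

#' @export
print.complex_model <- function(x, ...) {
  cat(sprintf("<complex_model %s/%s: %d receptor / %d ligand atoms (%s)>\n",
              x$target_id, x$model_id, nrow(x$receptor), nrow(x$ligand),
              x$source))
  invisible(x)
}

# atoms of one partner as a plain data.frame
model_part <- function(model, part = c("receptor", "ligand")) {
  model[[match.arg(part)]]
}

atom_xyz <- function(atoms) {
  cbind(x = atoms$x, y = atoms$y, z = atoms$z)
}

residue_keys <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
}

heavy_atoms <- function(atoms) atoms[atoms$elesy != "H", , drop = FALSE]

# Resolve alternate locations: keep, per (chain, resno, insert, elety), the
# highest-occupancy record; ties go to the alphabetically first altloc.
resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "|")
  if (!anyDuplicated(key)) return(atoms)
  occ <- atoms$o
  occ[is.na(occ)] <- 1
  alt <- atoms$alt
  alt[is.na(alt)] <- ""
  ord <- order(key, -occ, alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
}

#' Read docked complex models from a PDB file
#'
#' Parses a (possibly multi-model) PDB file with [bio3d::read.pdb()] and
#' partitions the atoms of every MODEL block into receptor and ligand by
#' chain identifier. Alternate locations are resolved to the
#' highest-occupancy record and hydrogens are retained if present.
#'
#' @param pdb_source Path to a PDB file; multi-model files produce one
#'   `complex_model` per MODEL block.
#' @param receptor_chains,ligand_chains Character vectors of chain IDs.
#' @param target_id Identifier of the docking target the models belong to.
#' @param source Provenance tag, `"scoreset_like"` (ordinary decoys) or
#'   `"enrichment"` (locally resampled poses).
#' @param id_prefix Prefix for generated model identifiers.
#' @return List of `complex_model` objects with model ids unique within
#'   the target.
#' @export
read_models <- function(pdb_source, receptor_chains, ligand_chains,
                        target_id, source = "scoreset_like",
                        id_prefix = "m") {
  if (!file.exists(pdb_source)) stop("PDB file not found: ", pdb_source)
  pdb <- bio3d::read.pdb(pdb_source, multi = TRUE, rm.alt = FALSE,
                         verbose = FALSE)
  atoms <- pdb$atom
  atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0) stop("no ATOM records in ", pdb_source)
  for (ch in c(receptor_chains, ligand_chains)) {
    if (!ch %in% atoms$chain)
      stop("chain ", ch, " not found in ", pdb_source)
  }
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)
  idx <- which(pdb$atom$type == "ATOM")

  insert <- atoms$insert
  insert[is.na(insert)] <- ""
  elesy <- atoms$elesy
  bad <- is.na(elesy) | elesy == ""
  elesy[bad] <- guess_element(atoms$elety[bad])
  base <- data.frame(
    chain = atoms$chain, resno = atoms$resno, insert = insert,
    resid = atoms$resid, elety = atoms$elety, elesy = toupper(elesy),
    alt = atoms$alt, o = atoms$o,
    stringsAsFactors = FALSE)

  lapply(seq_len(n_models), function(i) {
    co <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)[idx, , drop = FALSE]
    at <- base
    at$x <- co[, 1]; at$y <- co[, 2]; at$z <- co[, 3]
    at <- resolve_altloc(at)
    if (!all(is.finite(atom_xyz(at)))) stop("non-finite coordinates in model ", i)
    rec <- at[at$chain %in% receptor_chains, , drop = FALSE]
    lig <- at[at$chain %in% ligand_chains, , drop = FALSE]
    new_complex_model(sprintf("%s%04d", id_prefix, i), target_id,
                      rec, lig, source = source)
  })
}

#' Truncate models to their shared residue set
#'
#' Restricts every model to the intersection, over all models, of residue
#' keys (chain, author residue number, insertion code), separately for the
#' receptor and the ligand. Models gain no atoms; order of models and of
#' atoms within a model is preserved. Idempotent.
#'
#' @param models List of `complex_model`.
#' @return List of truncated `complex_model`.
#' @export
truncate_to_shared_residues <- function(models) {
  stopifnot(length(models) >= 1)
  trunc_part <- function(part) {
    keys <- lapply(models, function(m) unique(residue_keys(m[[part]])))
    shared <- Reduce(intersect, keys)
    if (length(shared) == 0)
      stop("no shared ", part, " residues across models")
    shared
  }
  shared_rec <- trunc_part("receptor")
  shared_lig <- trunc_part("ligand")
  # warn once about residue-name disagreement at a shared key
  check_names <- function(part, shared) {
    ref <- NULL
    for (m in models) {
      at <- m[[part]]
      k <- residue_keys(at)
      nm <- tapply(at$resid, k, function(v) v[1])[shared]
      if (is.null(ref)) ref <- nm
      else if (any(ref != nm, na.rm = TRUE)) {
        warning("residue name mismatch at shared ", part,
                " residue(s): ", paste(shared[which(ref != nm)[1]]),
                call. = FALSE)
        break
      }
    }
  }
  check_names("receptor", shared_rec)
  check_names("ligand", shared_lig)
  lapply(models, function(m) {
    m$receptor <- m$receptor[residue_keys(m$receptor) %in% shared_rec, ,
                             drop = FALSE]
    m$ligand <- m$ligand[residue_keys(m$ligand) %in% shared_lig, ,
                         drop = FALSE]
    m
  })
}

#' Detect steric clashes between receptor and ligand
#'
#' A steric clash is two atoms across the interface overlapping by their
#' van der Waals radii: `dist(i, j) < r_i + r_j` (strict, so touching
#' spheres are legal). Intra-chain contacts are never counted. Hydrogens
#' are excluded by default.
#'
#' @param model A `complex_model`.
#' @param radii Named element -> radius vector, see [vdw_radii()].
#' @param include_hydrogens Include hydrogen atoms in the check?
#' @return List with `clash` (logical) and `pairs`, a data.frame of
#'   offending receptor/ligand atom indices and their distance.
#' @export
has_clash <- function(model, radii = vdw_radii(), include_hydrogens = FALSE) {
  rec <- model$receptor
  lig <- model$ligand
  if (!include_hydrogens) {
    rec <- heavy_atoms(rec)
    lig <- heavy_atoms(lig)
  }
  r_rec <- radii[rec$elesy]
  r_lig <- radii[lig$elesy]
  if (anyNA(r_rec) || anyNA(r_lig)) {
    unk <- unique(c(rec$elesy[is.na(r_rec)], lig$elesy[is.na(r_lig)]))
    warning("unknown element(s) ", paste(unk, collapse = ", "),
            "; using 1.7 A radius", call. = FALSE)
    r_rec[is.na(r_rec)] <- 1.7
    r_lig[is.na(r_lig)] <- 1.7
  }
  d <- cross_dist(atom_xyz(rec), atom_xyz(lig))
  lim <- outer(r_rec, r_lig, "+")
  hit <- which(d < lim, arr.ind = TRUE)
  pairs <- data.frame(
    receptor_atom = hit[, 1], ligand_atom = hit[, 2],
    dist = d[hit], limit = lim[hit])
  list(clash = nrow(pairs) > 0, pairs = pairs)
}

#' Remove clashed models from a set
#'
#' Splits models into clash-free (`kept`, original order preserved) and
#' clashed (`removed`), with a per-model removal report.
#'
#' @inheritParams has_clash
#' @param models List of `complex_model`.
#' @return List with `kept`, `removed` and `report` (model_id, n_clashes).
#' @export
filter_clashed <- function(models, radii = vdw_radii(),
                           include_hydrogens = FALSE) {
  res <- lapply(models, has_clash, radii = radii,
                include_hydrogens = include_hydrogens)
  clashed <- vapply(res, `[[`, logical(1), "clash")
  report <- data.frame(
    model_id = vapply(models, `[[`, character(1), "model_id"),
    n_clashes = vapply(res, function(r) nrow(r$pairs), integer(1)),
    removed = clashed)
  list(kept = models[!clashed], removed = models[clashed], report = report)
}

# Write a list of complex models (shared topology) as a multi-model PDB.
# Used by the synthetic benchmark writer.
write_models_pdb <- function(models, file) {
  stopifnot(length(models) >= 1)
  at0 <- rbind(models[[1]]$receptor, models[[1]]$ligand)
  xyz <- do.call(rbind, lapply(models, function(m) {
    as.vector(t(atom_xyz(rbind(m$receptor, m$ligand))))
  }))
  bio3d::write.pdb(file = file, xyz = xyz,
                   resno = at0$resno, resid = at0$resid,
                   chain = at0$chain, elety = at0$elety,
                   eleno = seq_len(nrow(at0)))
  invisible(file)
}
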