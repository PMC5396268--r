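test_that("kabsch superposition recovers exact rigid motions", {
  set.seed(1)
  ref <- matrix(rnorm(30), 10, 3)
  sp <- kabsch_superpose(ref, ref)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-10)
  expect_equal(sp$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(sp$fit_rmsd, 0, tolerance = 1e-10)

  rot90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  mov <- rigid_move(ref, rot90, c(5, -2, 7))
  sp <- kabsch_superpose(ref, mov)
  expect_equal(sp$fit_rmsd, 0, tolerance = 1e-8)
  # recovered transform inverts the applied one
  expect_equal(sp$rotation %*% rot90, diag(3), tolerance = 1e-8)

  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]), "at least 3")
})

test_that("kabsch agrees with a quaternion eigen-decomposition oracle", {
  set.seed(7)
  for (i in 1:5) {
    ref <- matrix(rnorm(30), 10, 3)
    mov <- rigid_move(ref, random_rot(), rnorm(3)) +
      matrix(rnorm(30, 0, 0.1), 10, 3)
    sp <- kabsch_superpose(ref, mov)
    qo <- quaternion_superpose(ref, mov)
    expect_equal(sp$fit_rmsd, qo$fit_rmsd, tolerance = 1e-6)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-8)
    expect_equal(crossprod(sp$rotation), diag(3), tolerance = 1e-8)
  }
})

test_that("lrmsd isolates ligand displacement after receptor superposition", {
  ref <- mk_model(helix(8), sweep(helix(5), 2, c(15, 0, 0), "+"), "ref")
  expect_equal(lrmsd(ref, ref), 0)

  shifted <- ref
  shifted$ligand$x <- shifted$ligand$x + 3
  expect_equal(lrmsd(shifted, ref), 3, tolerance = 1e-8)

  set.seed(2)
  moved <- transform_model(shifted, random_rot(), rnorm(3, 0, 10))
  expect_equal(lrmsd(moved, ref), 3, tolerance = 1e-6)
  whole <- transform_model(ref, random_rot(), rnorm(3, 0, 10))
  expect_equal(lrmsd(whole, ref), 0, tolerance = 1e-8)

  bad <- ref
  bad$ligand <- bad$ligand[-1, ]
  expect_error(lrmsd(bad, ref), "unmatched")
})

test_that("fnat counts preserved native residue contacts", {
  rec <- t(sapply(1:4, function(i) c(8 * (i - 1), 0, 0)))
  lig <- t(sapply(1:4, function(i) c(8 * (i - 1), 4.2, 0)))
  ref <- mk_backbone_model(rec, lig, "ref")
  # brute-force contact enumeration oracle on the fixture coordinates
  natives <- 0
  for (i in 1:4) for (j in 1:4) {
    d <- clusterrank:::cross_dist(
      as.matrix(residue_atoms(rec[i, ], "A", i)[, c("x", "y", "z")]),
      as.matrix(residue_atoms(lig[j, ], "B", j)[, c("x", "y", "z")]))
    if (min(d) <= 5) natives <- natives + 1
  }
  expect_equal(natives, 4)
  expect_equal(fnat(ref, ref), 1.0)

  # displace ligand residues 3 and 4 -> exactly 2 of 4 contacts survive
  half <- mk_backbone_model(rec, rbind(lig[1:2, ],
                                       sweep(lig[3:4, ], 2, c(0, 50, 0), "+")),
                            "half")
  expect_equal(fnat(half, ref), 0.5)

  gone <- mk_backbone_model(rec, sweep(lig, 2, c(0, 100, 0), "+"), "gone")
  expect_equal(fnat(gone, ref), 0.0)

  no_iface <- mk_backbone_model(rec, sweep(lig, 2, c(0, 100, 0), "+"), "ni")
  expect_error(fnat(ref, no_iface), "no native contacts")
})

test_that("fnat is monotone non-decreasing in the contact cutoff", {
  # ladder fixture: single-atom residues, native contacts all at 3 A,
  # model contacts progressively displaced to 4, 6 and 8 A
  rec <- t(sapply(1:3, function(i) c(20 * i, 0, 0)))
  lig_ref <- t(sapply(1:3, function(i) c(20 * i, 3, 0)))
  lig_mod <- t(sapply(1:3, function(i) c(20 * i, 2 + 2 * i, 0)))
  ref <- mk_model(rec, lig_ref, "ref")
  model <- mk_model(rec, lig_mod, "m")
  vals <- sapply(c(5, 6.5, 9, 25), function(cc) fnat(model, ref, cc))
  expect_equal(vals, c(1 / 3, 2 / 3, 1, 1))
  expect_true(all(diff(vals) >= 0))
})

test_that("irmsd matches an explicit selection + superposition oracle", {
  set.seed(5)
  rec <- t(sapply(1:6, function(i) c(7 * (i - 1), 0, 0)))
  lig <- t(sapply(1:4, function(i) c(7 * (i - 1), 5, 0)))
  ref <- mk_backbone_model(rec, lig, "ref")
  expect_equal(irmsd(ref, ref), 0, tolerance = 1e-10)

  decoy <- mk_backbone_model(rec + matrix(rnorm(18, 0, 0.5), 6, 3),
                             lig + matrix(rnorm(12, 0, 1.5), 4, 3), "d")
  got <- irmsd(decoy, ref, interface_cutoff = 10)

  # oracle: explicit interface selection + quaternion superposition
  pick_iface <- function(m) {
    ra <- m$receptor[m$receptor$elesy != "H", ]
    la <- m$ligand[m$ligand$elesy != "H", ]
    d <- clusterrank:::cross_dist(as.matrix(ra[, c("x", "y", "z")]),
                                  as.matrix(la[, c("x", "y", "z")]))
    list(rec = unique(ra$resno[which(d <= 10, arr.ind = TRUE)[, 1]]),
         lig = unique(la$resno[which(d <= 10, arr.ind = TRUE)[, 2]]))
  }
  sel <- pick_iface(ref)
  bb <- c("N", "CA", "C", "O")
  grab <- function(m) {
    at <- rbind(m$receptor[m$receptor$resno %in% sel$rec &
                             m$receptor$elety %in% bb, ],
                m$ligand[m$ligand$resno %in% sel$lig &
                           m$ligand$elety %in% bb, ])
    at <- at[order(at$chain, at$resno, at$elety), ]
    as.matrix(at[, c("x", "y", "z")])
  }
  oracle <- quaternion_superpose(grab(ref), grab(decoy))$fit_rmsd
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("quality measures are invariant under a common rigid transform", {
  set.seed(6)
  # non-degenerate (non-collinear) receptor scaffold
  rec <- t(sapply(1:5, function(i)
    c(7 * (i - 1), 2 * sin(i), 1.5 * cos(2 * i))))
  lig <- t(sapply(1:4, function(i) c(7 * (i - 1), 4.5, 0)))
  ref <- mk_backbone_model(rec, lig, "ref")
  model <- mk_backbone_model(rec, lig + matrix(rnorm(12, 0, 1), 4, 3), "m")
  rot <- random_rot(); shift <- rnorm(3, 0, 15)
  ref2 <- transform_model(ref, rot, shift)
  model2 <- transform_model(model, rot, shift)
  expect_equal(lrmsd(model2, ref2), lrmsd(model, ref), tolerance = 1e-7)
  expect_equal(irmsd(model2, ref2), irmsd(model, ref), tolerance = 1e-7)
  expect_equal(fnat(model2, ref2), fnat(model, ref))
})

test_that("lrmsd obeys the triangle inequality on a fixed receptor frame", {
  set.seed(8)
  rec <- helix(8)
  mods <- lapply(1:4, function(i)
    mk_model(rec, rigid_move(helix(5), random_rot(),
                             c(14, 0, 0) + rnorm(3, 0, 6)),
             sprintf("m%d", i)))
  d <- pairwise_lrmsd_matrix(mods)$d
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    expect_lte(d[i, k], d[i, j] + d[j, k] + 1e-9)
})

test_that("capri classes follow the threshold table and are monotone", {
  expect_equal(capri_class(fnat = 1, lrmsd = 0, irmsd = 0), "high")
  expect_equal(capri_class(fnat = 0.05, lrmsd = 0.5, irmsd = 0.5),
               "incorrect")
  expect_equal(capri_class(fnat = 0.35, lrmsd = 4, irmsd = 3), "medium")
  expect_equal(capri_class(fnat = 0.15, lrmsd = 8, irmsd = 3.5),
               "acceptable")
  # worsening lrmsd at fixed fnat never raises the class
  lvl <- c(incorrect = 0, acceptable = 1, medium = 2, high = 3)
  cls <- sapply(c(0.5, 2, 6, 12, 20), function(l)
    capri_class(fnat = 0.4, lrmsd = l, irmsd = l / 2))
  expect_true(all(diff(lvl[cls]) <= 0))
})
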