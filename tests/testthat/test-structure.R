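make_pdb_lines <- function(coords, chain = "A", resno = seq_len(nrow(coords)),
                           alt = rep("", nrow(coords)),
                           occ = rep(1, nrow(coords))) {
  vapply(seq_len(nrow(coords)), function(i) {
    sprintf("ATOM  %5d  CA %s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            i, alt[i], "ALA", chain, resno[i],
            coords[i, 1], coords[i, 2], coords[i, 3], occ[i], 20)
  }, character(1))
}

test_that("PDB parsing keeps C-alpha records and highest-occupancy altlocs", {
  xyz <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0))
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(make_pdb_lines(xyz), "END"), path)
  m <- read_ca_coords(path)
  expect_equal(nrow(m), 3)
  expect_equal(m$x, xyz[, 1])

  # altloc A (occ 0.6) vs B (occ 0.4) for residue 2
  xyz2 <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(9.9, 9.9, 9.9), c(7.6, 0, 0))
  path2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(make_pdb_lines(xyz2, resno = c(1, 2, 2, 3),
                              alt = c("", "A", "B", ""),
                              occ = c(1, 0.6, 0.4, 1)), "END"), path2)
  m2 <- read_ca_coords(path2)
  expect_equal(nrow(m2), 3)
  expect_equal(m2$x[m2$resno == 2], 3.8)

  # altloc B wins when it carries the higher occupancy
  path3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(make_pdb_lines(xyz2, resno = c(1, 2, 2, 3),
                              alt = c("", "A", "B", ""),
                              occ = c(1, 0.3, 0.7, 1)), "END"), path3)
  m3 <- read_ca_coords(path3)
  expect_equal(nrow(m3), 3)
  expect_equal(m3$x[m3$resno == 2], 9.9)

  expect_error(read_ca_coords(path, chain = "Z"), "chain")
})

test_that("mmCIF and PDB renderings of one model give identical coordinates", {
  xyz <- rbind(c(1.2, 0.5, -3), c(4.9, 0.1, -2.2), c(8.8, 1.4, -1),
               c(12.1, 2.2, 0.4))
  pdb_path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(make_pdb_lines(xyz), "END"), pdb_path)
  cif_path <- withr::local_tempfile(fileext = ".cif")
  cif <- c(
    "data_toy",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    vapply(seq_len(nrow(xyz)), function(i) {
      sprintf("ATOM %d C CA . ALA A 1 %d ? %.3f %.3f %.3f 1.00 20.00 ? %d ALA A CA 1",
              i, i, xyz[i, 1], xyz[i, 2], xyz[i, 3], i)
    }, character(1))
  )
  writeLines(cif, cif_path)
  from_pdb <- read_ca_coords(pdb_path)
  from_cif <- suppressWarnings(read_ca_coords(cif_path))  # read.cif beta note
  expect_equal(from_cif$x, from_pdb$x, tolerance = 1e-6)
  expect_equal(from_cif$y, from_pdb$y, tolerance = 1e-6)
  expect_equal(from_cif$z, from_pdb$z, tolerance = 1e-6)
  expect_equal(from_cif$resno, from_pdb$resno)
})

test_that("Kabsch superposition: identity, rigid copies, bio3d oracle", {
  toy <- generate_toy_structures(d = 20, delta = 50, seed = 5)$models[[1]]
  self <- kabsch_superpose(toy, toy)
  expect_lt(self$rmsd, 1e-12)
  expect_equal(det(self$rotation), 1, tolerance = 1e-9)

  moved <- rigid_move(toy)
  sup <- kabsch_superpose(moved, toy)
  expect_lt(sup$rmsd, 1e-6)

  # perturbed copy: agreement with bio3d's least-squares superposition
  set.seed(8)
  pert <- toy
  pert$x <- pert$x + rnorm(nrow(pert), 0, 0.8)
  pert$y <- pert$y + rnorm(nrow(pert), 0, 0.8)
  pert$z <- pert$z + rnorm(nrow(pert), 0, 0.8)
  pert <- rigid_move(pert, th = 1.1, shift = c(-3, 9, 1))
  ours <- kabsch_superpose(pert, toy)
  # oracle on the same atom set the superposition matched (protein chain A)
  toy_a <- toy[toy$chain == "A", ]
  pert_a <- pert[pert$chain == "A", ]
  fixed <- as.vector(t(as.matrix(toy_a[, c("x", "y", "z")])))
  mobile <- as.vector(t(as.matrix(pert_a[, c("x", "y", "z")])))
  b3d <- bio3d::fit.xyz(fixed, mobile,
                        fixed.inds = seq_along(fixed),
                        mobile.inds = seq_along(mobile))
  b3d_rmsd <- sqrt(mean(colSums(matrix((as.vector(b3d) - fixed)^2, nrow = 3))))
  expect_equal(ours$rmsd, b3d_rmsd, tolerance = 1e-6)

  expect_error(kabsch_superpose(toy[1:2, ], toy[1:2, ]), "fewer than 3")
})

test_that("superposition is optimal against random rigid probes", {
  toy <- generate_toy_structures(d = 18, delta = 45, seed = 2)$models[[1]]
  set.seed(13)
  pert <- toy
  pert$x <- pert$x + rnorm(nrow(pert), 0, 1)
  pert$z <- pert$z + rnorm(nrow(pert), 0, 1)
  best <- kabsch_superpose(pert, toy)$rmsd
  P <- as.matrix(pert[, c("x", "y", "z")])
  Q <- as.matrix(toy[, c("x", "y", "z")])
  set.seed(14)
  probes <- replicate(1000, {
    th <- runif(3, 0, 2 * pi)
    Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]),
                   0, sin(th[1]), cos(th[1])), 3, 3)
    Ry <- matrix(c(cos(th[2]), 0, sin(th[2]), 0, 1, 0,
                   -sin(th[2]), 0, cos(th[2])), 3, 3)
    Rz <- matrix(c(cos(th[3]), -sin(th[3]), 0, sin(th[3]), cos(th[3]), 0,
                   0, 0, 1), 3, 3)
    M <- sweep(P, 2, colMeans(P)) %*% (Rx %*% Ry %*% Rz)
    M <- sweep(M, 2, colMeans(Q), FUN = "+")
    sqrt(mean(rowSums((M - Q)^2)))
  })
  expect_true(all(probes >= best - 1e-9))
})

test_that("core RMSD is symmetric and matches the direct formula", {
  toys <- generate_toy_structures(d = c(18, 18), delta = c(45, 45),
                                  core_sd = 0.2, term_sd = 0.2,
                                  seed = 6)$models
  a <- toys[[1]]; b <- toys[[2]]
  expect_equal(core_rmsd(a, b), core_rmsd(b, a), tolerance = 1e-9)
  expect_equal(core_rmsd(a, a), 0, tolerance = 1e-12)

  # known displacement: move every core atom of a copy by 0.3 A in +x is an
  # exact rigid motion, removed by superposition
  shifted <- a
  shifted$x <- shifted$x + 0.3
  expect_lt(core_rmsd(a, shifted), 1e-9)
})

test_that("per-residue peptide RMSD does the pairwise arithmetic", {
  base <- generate_toy_structures(d = 20, delta = 50, core_sd = 0,
                                  term_sd = 0, seed = 1)$models[[1]]
  # two identical conformations -> all zero
  two <- list(a = base, b = base)
  pr <- per_residue_peptide_rmsd(two)
  expect_true(all(pr$mean_rmsd < 1e-9))

  # three models, position 8 displaced by exactly 2 A in one
  displaced <- base
  i <- which(displaced$chain == "B" & displaced$resno == 8)
  displaced$z[i] <- displaced$z[i] + 2
  three <- list(a = base, b = base, c = displaced)
  pr3 <- per_residue_peptide_rmsd(three)
  expect_equal(pr3$mean_rmsd[pr3$position == 8], 4 / 3, tolerance = 1e-9)
  expect_equal(pr3$n_pairs, rep(3L, 15))

  # a position missing everywhere is undefined, not zero
  gappy <- lapply(three, function(m) m[!(m$chain == "B" & m$resno == 1), ])
  gappy <- lapply(gappy, as_structure_model)
  pr_g <- per_residue_peptide_rmsd(gappy)
  expect_true(is.na(pr_g$mean_rmsd[pr_g$position == 1]))
  expect_equal(pr_g$n_pairs[pr_g$position == 1], 0L)
})

test_that("inter-domain metrics reproduce prescribed geometry", {
  # collinear: 145 and 95 on opposite sides of 19 -> 180 degrees
  m <- as_structure_model(tibble::tibble(
    chain = "A", resno = c(19L, 95L, 99L, 145L, 146L),
    x = c(0, -8, 10, 12, 15), y = c(0, 0, 25, 0, 0), z = 0))
  got <- interdomain_metrics(m)
  expect_equal(got$delta, 180)
  expect_equal(got$d, sqrt(5^2 + 25^2))

  # right angle
  m2 <- as_structure_model(tibble::tibble(
    chain = "A", resno = c(19L, 95L, 99L, 145L, 146L),
    x = c(0, 0, 25, 12, 0), y = c(0, 9, 0, 0, 0), z = c(0, 0, 0, 0, 0)))
  expect_equal(interdomain_metrics(m2)$delta, 90)
  expect_equal(interdomain_metrics(m2)$d, 25)

  # missing residue is named in the error
  m3 <- m[m$resno != 95, ]
  expect_error(interdomain_metrics(as_structure_model(m3)), "95")

  # invariance under rigid motion
  toy <- generate_toy_structures(d = 23, delta = 77, seed = 9)$models[[1]]
  moved <- rigid_move(toy, th = 0.9, shift = c(12, -5, 3))
  expect_equal(interdomain_metrics(moved)$d,
               interdomain_metrics(toy)$d, tolerance = 1e-9)
  expect_equal(interdomain_metrics(moved)$delta,
               interdomain_metrics(toy)$delta, tolerance = 1e-9)
})

test_that("conformation classification: centroids, cutoff, references", {
  refs <- conformation_references()
  expect_true(all(c("closed", "tight", "loose", "open") %in% refs$state))

  # a point equal to a reference centroid gets that label
  cen <- dplyr::summarise(dplyr::group_by(refs, state),
                          d = mean(d), delta = mean(delta))
  got <- classify_conformation(cen[, c("d", "delta")])
  expect_equal(got$state, cen$state)

  # far outside every group -> intermediate
  far <- tibble::tibble(d = 60, delta = 160)
  expect_equal(classify_conformation(far)$state, "intermediate")

  # toy structures built at the reference geometries classify correctly
  toy <- generate_toy_structures(d = c(12, 16, 22, 30),
                                 delta = c(33, 42, 51, 65), seed = 4)
  tab <- conformation_table(toy$models)
  expect_equal(tab$state, c("closed", "tight", "loose", "open"))
})
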