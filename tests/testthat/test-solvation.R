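make_water_top <- function(n_waters, extra = NULL) {
  atoms <- tibble::tibble(name = rep("O", n_waters),
                          resname = "HOH",
                          resseq = seq_len(n_waters),
                          element = "O")
  if (!is.null(extra)) atoms <- dplyr::bind_rows(extra, atoms)
  topology_map(atoms)
}

test_that("a static water accumulates raw counts in one voxel only", {
  top <- make_water_top(1)
  coords <- array(0, c(10, 1, 3))
  coords[, 1, ] <- matrix(rep(c(2.5, 2.5, 2.5), each = 10), 10)
  g <- water_occupancy(md_trajectory(coords), top, origin = c(0, 0, 0),
                       dims = c(5, 5, 5), spacing_A = 1)
  expect_equal(g$counts[3, 3, 3], 10)
  expect_equal(sum(g$counts), 10)
})

test_that("grid totals conserve in-bounds water observations exactly", {
  set.seed(51)
  n_w <- 40; n_f <- 25
  coords <- array(runif(n_f * n_w * 3, -2, 12), c(n_f, n_w, 3))
  top <- make_water_top(n_w)
  tr <- md_trajectory(coords)
  g <- water_occupancy(tr, top, origin = c(0, 0, 0), dims = c(10, 10, 10))
  in_bounds <- sum(vapply(1:n_f, function(i) {
    xyz <- matrix(coords[i, , ], ncol = 3)
    sum(xyz[, 1] >= 0 & xyz[, 1] < 10 & xyz[, 2] >= 0 & xyz[, 2] < 10 &
          xyz[, 3] >= 0 & xyz[, 3] < 10)
  }, numeric(1)))
  expect_identical(sum(g$counts), as.integer(in_bounds))
})

test_that("an empty water set yields an all-zero grid", {
  atoms <- tibble::tibble(name = "CA", resname = "GLY", resseq = 1L,
                          element = "C")
  top <- topology_map(atoms)
  tr <- md_trajectory(array(0, c(3, 1, 3)))
  g <- water_occupancy(tr, top, origin = c(0, 0, 0), dims = c(4, 4, 4))
  expect_true(all(g$counts == 0))
  expect_error(water_occupancy(tr, top, origin = c(0, 0, 0),
                               dims = c(0, 4, 4)), "volume")
})

test_that("uniform water at bulk density gives bulk-relative mean near 1", {
  box <- gen_solvated_box(0.0334, box_A = c(15, 15, 15), n_frames = 200,
                          seed = 52)
  g <- water_occupancy(box$traj, box$top, origin = c(0, 0, 0),
                       dims = c(15, 15, 15))
  vals <- grid_values(g, "bulk_relative")
  n_tot <- sum(g$counts)
  # 3 sigma Poisson tolerance on the grand mean
  expect_lt(abs(mean(vals) - 1), 3 * sqrt(n_tot) / n_tot + 0.01)
})

test_that("waters_near averages the within-cutoff count over frames", {
  # one water inside 2 A of the marker in 7 of 10 frames
  extra <- tibble::tibble(name = "CA", resname = "GLY", resseq = 100L,
                          element = "C")
  atoms <- dplyr::bind_rows(extra,
                            tibble::tibble(name = "O", resname = "HOH",
                                           resseq = 1L, element = "O"))
  bw <- bw_table("5.36", 100L, "GLY")
  top <- topology_map(atoms, bw = bw)
  coords <- array(0, c(10, 2, 3))
  coords[, 2, 1] <- c(rep(1.5, 7), rep(8, 3))
  tr <- md_trajectory(coords)
  expect_equal(waters_near(tr, top, "5.36", "CA", cutoff_A = 2), 0.7)
  expect_equal(waters_near(tr, top, "5.36", "CA", cutoff_A = 0.5), 0)
  # two waters always inside -> 2.0
  atoms2 <- dplyr::bind_rows(extra, tibble::tibble(
    name = c("O", "O"), resname = "HOH", resseq = 1:2, element = "O"))
  top2 <- topology_map(atoms2, bw = bw)
  coords2 <- array(0, c(4, 3, 3))
  coords2[, 2, 1] <- 1; coords2[, 3, 2] <- 1.2
  expect_equal(waters_near(md_trajectory(coords2), top2, "5.36", "CA", 2),
               2.0)
})

test_that("pinned-water generator reproduces the target near fraction", {
  box <- gen_solvated_box(0.01, box_A = c(12, 12, 12), n_frames = 400,
                          pin_fraction = 0.7, seed = 53)
  got <- waters_near(box$traj, box$top, "5.36", "CA", cutoff_A = 2)
  # unpinned waters also wander through the 2 A sphere at a predictable
  # uniform rate; subtract that background before comparing
  n_w <- length(box$top$water_o_idx)
  bg <- (n_w - 1) * (4 / 3) * pi * 2^3 / prod(c(12, 12, 12))
  expect_equal(got - bg, mean(box$pinned), tolerance = 0.05)
})

contact_fixture <- function(ligand_x, n_frames = 4) {
  atoms <- tibble::tibble(
    name = c("CA", "CA", "C1"),
    resname = c("ALA", "GLY", "LIG"),
    resseq = c(1L, 2L, 900L),
    element = c("C", "C", "C"))
  top <- topology_map(atoms, ligand_resnames = "LIG")
  coords <- array(0, c(n_frames, 3, 3))
  coords[, 2, 2] <- 50  # second residue far away
  coords[, 3, 1] <- ligand_x
  list(top = top, traj = md_trajectory(coords))
}

test_that("contact frequencies follow the 3 A heavy-atom rule", {
  fx <- contact_fixture(rep(2.9, 4))
  ct <- contact_frequency(fx$traj, fx$top)
  expect_equal(ct$frequency[ct$resseq == 1], 1.0)
  expect_equal(ct$frequency[ct$resseq == 2], 0.0)
  # nearest approach 3.5 A -> no contact
  ct2 <- contact_frequency(contact_fixture(rep(3.5, 4))$traj,
                           contact_fixture(rep(3.5, 4))$top)
  expect_equal(ct2$frequency[ct2$resseq == 1], 0.0)
  # contact in exactly half the frames
  fx3 <- contact_fixture(c(2.0, 2.0, 6.0, 6.0))
  ct3 <- contact_frequency(fx3$traj, fx3$top)
  expect_equal(ct3$frequency[ct3$resseq == 1], 0.5)
  # monotone non-decreasing in the cutoff
  freqs <- vapply(c(1, 2, 3, 4, 7), function(co) {
    ct <- contact_frequency(fx3$traj, fx3$top, cutoff_A = co)
    ct$frequency[ct$resseq == 1]
  }, numeric(1))
  expect_true(all(diff(freqs) >= 0))
  no_lig <- topology_map(fx3$top$atoms)
  expect_error(contact_frequency(fx3$traj, no_lig), "ligand")
})

ligand_system <- function(n_frames) {
  n_ca <- 8
  atoms <- tibble::tibble(
    name = c(rep("CA", n_ca), "C1", "C2"),
    resname = c(rep("ALA", n_ca), "LIG", "LIG"),
    resseq = c(seq_len(n_ca), 900L, 900L),
    element = "C")
  set.seed(55)
  ref <- rbind(matrix(rnorm(n_ca * 3, sd = 6), n_ca),
               matrix(c(1, 0, 0, 2, 0, 0), 2, byrow = TRUE))
  top <- topology_map(atoms, xyz = ref, ligand_resnames = "LIG")
  coords <- array(rep(ref, each = n_frames), c(n_frames, n_ca + 2, 3))
  list(top = top, coords = coords, ref = ref, lig = n_ca + (1:2))
}

test_that("ligand RMSD is zero on the reference and exact on rigid offsets", {
  sys <- ligand_system(3)
  tr <- md_trajectory(sys$coords)
  expect_equal(ligand_rmsd(tr, sys$top)$rmsd_A, rep(0, 3), tolerance = 1e-9)
  # translate the ligand only, by 1 A
  coords <- sys$coords
  coords[, sys$lig, 1] <- coords[, sys$lig, 1] + 1
  r <- ligand_rmsd(md_trajectory(coords), sys$top)
  expect_equal(r$rmsd_A, rep(1, 3), tolerance = 1e-9)
  expect_equal(glance(r)$mean_rmsd_A, 1, tolerance = 1e-9)
})

test_that("ligand RMSD matches the brute-force formula and ignores rigid motion", {
  sys <- ligand_system(5)
  set.seed(56)
  coords <- sys$coords
  # perturb ligand atoms only, so receptor superposition is exact
  pert <- array(rnorm(5 * 2 * 3, sd = 0.5), c(5, 2, 3))
  coords[, sys$lig, ] <- coords[, sys$lig, ] + pert
  base <- ligand_rmsd(md_trajectory(coords), sys$top)$rmsd_A
  oracle <- vapply(1:5, function(i) {
    sqrt(mean(rowSums(matrix(pert[i, , ], ncol = 3)^2)))
  }, numeric(1))
  expect_equal(base, oracle, tolerance = 1e-9)
  # apply a global rigid motion per frame: RMSD unchanged
  for (i in 1:5) {
    r <- random_rotation()
    coords[i, , ] <- sweep(matrix(coords[i, , ], ncol = 3) %*% t(r), 2,
                           rnorm(3, sd = 30), `+`)
  }
  moved <- ligand_rmsd(md_trajectory(coords), sys$top)$rmsd_A
  expect_equal(moved, base, tolerance = 1e-8)
})

test_that("OpenDX export writes a well-formed grid file", {
  top <- make_water_top(1)
  coords <- array(1.5, c(2, 1, 3))
  g <- water_occupancy(md_trajectory(coords), top, origin = c(0, 0, 0),
                       dims = c(3, 3, 3))
  path <- withr::local_tempfile(fileext = ".dx")
  write_dx(g, path, normalization = "raw_counts")
  lines <- readLines(path)
  expect_match(lines[1], "gridpositions counts 3 3 3")
  vals <- as.numeric(unlist(strsplit(paste(lines[8:16], collapse = " "),
                                     "\\s+")))
  expect_equal(sum(vals, na.rm = TRUE), 2)
})
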