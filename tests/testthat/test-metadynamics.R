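write_hills_text <- function(path, mat, header = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (header) {
    writeLines("#! FIELDS time cv1 cv2 sigma_cv1 sigma_cv2 height biasf", con)
  }
  writeLines(apply(mat, 1, paste, collapse = " "), con)
}

test_that("multi-walker hills files merge sorted by time, walker-stable", {
  dirs <- withr::local_tempdir()
  paths <- file.path(dirs, sprintf("HILLS.%d", 1:6))
  set.seed(61)
  for (w in 1:6) {
    mat <- cbind(time = c(4, 8, 12), cv1 = runif(3, 8, 11),
                 cv2 = runif(3, 8, 11), s1 = 0.1, s2 = 0.1,
                 h = 0.1, biasf = 10)
    write_hills_text(paths[w], mat)
  }
  log <- read_hills(paths, gamma = 10)
  expect_equal(nrow(log), 18)
  expect_true(!is.unsorted(log$time_ps))
  # ties in time are ordered by walker id
  expect_equal(log$walker[log$time_ps == 4], 1:6)
  # single pre-sorted file reads back unchanged
  single <- read_hills(paths[1], gamma = 10)
  expect_equal(single$time_ps, c(4, 8, 12))
})

test_that("malformed hills input fails with the offending line", {
  path <- withr::local_tempfile()
  writeLines(c("#! FIELDS time cv1 cv2 s1 s2 h",
               "4 9.0 9.0 0.1 0.1 0.1",
               "8 9.1 bad 0.1 0.1 0.1"), path)
  expect_error(read_hills(path, gamma = 10), "line 3")
  writeLines(c("4 9.0 9.0 0.1 0.1", "8 9.0 9.0 0.1 0.1 0.1"), path)
  expect_error(read_hills(path, gamma = 10), "line 1")
  # negative width violates the log invariant
  writeLines("4 9.0 9.0 -0.1 0.1 0.1", path)
  expect_error(read_hills(path, gamma = 10), "width")
})

test_that("bias potential sums recorded Gaussians exactly", {
  empty <- hills_log(tibble::tibble(time_ps = numeric(), cv1 = numeric(),
                                    cv2 = numeric(), sigma1 = numeric(),
                                    sigma2 = numeric(), height = numeric(),
                                    walker = integer()), gamma = 10)
  expect_equal(bias_potential(empty, cbind(c(8, 10), c(8, 10))), c(0, 0))
  one <- hills_log(tibble::tibble(time_ps = 4, cv1 = 10, cv2 = 10,
                                  sigma1 = 0.1, sigma2 = 0.1, height = 0.1,
                                  walker = 1), gamma = 10)
  expect_equal(bias_potential(one, c(10, 10)), 0.1)
  expect_equal(bias_potential(one, c(10.1, 10)), 0.1 * exp(-0.5),
               tolerance = 1e-12)
  # additivity over log concatenation
  set.seed(62)
  recs <- tibble::tibble(time_ps = 1:20, cv1 = runif(20, 7, 13),
                         cv2 = runif(20, 7, 13), sigma1 = 0.1, sigma2 = 0.1,
                         height = runif(20, 0.05, 0.1), walker = 1L)
  a <- hills_log(recs[1:8, ], gamma = 10)
  b <- hills_log(recs[9:20, ], gamma = 10)
  ab <- hills_log(recs, gamma = 10)
  pts <- cbind(runif(30, 6, 14), runif(30, 6, 14))
  expect_equal(bias_potential(ab, pts),
               bias_potential(a, pts) + bias_potential(b, pts),
               tolerance = 1e-12)
})

test_that("FES equals the analytic Gaussian sum times -gamma/(gamma-1)", {
  set.seed(63)
  recs <- tibble::tibble(time_ps = 1:50, cv1 = runif(50, 7, 13),
                         cv2 = runif(50, 7, 13), sigma1 = 0.1, sigma2 = 0.1,
                         height = 0.1 * exp(-runif(50)), walker = 1L)
  log <- hills_log(recs, gamma = 10)
  fes <- reconstruct_fes(log, n_nodes = 60)
  # closed-form oracle at every node, referenced the same way
  oracle <- matrix(NA_real_, 60, 60)
  for (i in 1:60) for (j in 1:60) {
    v <- sum(recs$height * exp(-((fes$cv1[i] - recs$cv1)^2 / (2 * 0.01) +
                                   (fes$cv2[j] - recs$cv2)^2 / (2 * 0.01))))
    oracle[i, j] <- -10 / 9 * v
  }
  expect_lt(max(abs(fes$F - (oracle - min(oracle)))), 1e-9)
  # single-hill prefactor: unshifted F at the hill centre is -(10/9) w
  one <- hills_log(tibble::tibble(time_ps = 4, cv1 = 10, cv2 = 10,
                                  sigma1 = 0.1, sigma2 = 0.1, height = 0.1,
                                  walker = 1), gamma = 10)
  f1 <- reconstruct_fes(one, cv1_range = c(6, 14), cv2_range = c(6, 14),
                        n_nodes = 81)
  node <- c(which(f1$cv1 == 10), which(f1$cv2 == 10))
  expect_equal(f1$F[node[1], node[2]] + f1$shift, -10 / 9 * 0.1,
               tolerance = 1e-12)
  # empty log -> flat zero surface
  flat <- reconstruct_fes(hills_log(recs[0, ], gamma = 10), n_nodes = 20)
  expect_true(all(flat$F == 0))
})

test_that("surface shape is invariant to a uniform bias background", {
  set.seed(64)
  recs <- tibble::tibble(time_ps = 1:30, cv1 = runif(30, 7, 13),
                         cv2 = runif(30, 7, 13), sigma1 = 0.2, sigma2 = 0.2,
                         height = 0.1, walker = 1L)
  fes <- reconstruct_fes(hills_log(recs, gamma = 10), n_nodes = 40)
  # very wide hill ~ constant over the grid
  bg <- tibble::tibble(time_ps = 100, cv1 = 10, cv2 = 10, sigma1 = 1e5,
                       sigma2 = 1e5, height = 0.5, walker = 2L)
  fes2 <- reconstruct_fes(hills_log(dplyr::bind_rows(recs, bg), gamma = 10),
                          n_nodes = 40)
  expect_equal(fes2$F, fes$F, tolerance = 1e-6)
})

test_that("state regions partition the plane and locate their minima", {
  mk_fes <- function(fmat, cv) {
    structure(list(cv1 = cv, cv2 = cv, F = fmat - min(fmat), gamma = 10,
                   shift = 0), class = "fes_grid")
  }
  cv <- seq(6, 14, length.out = 81)
  # double-well fixture: basins at (10.5, 10.5) and (8.5, 8.5), ridge in
  # the forbidden (d1 active, d2 inactive) quadrant
  well <- function(x, y, cx, cy) 2 * ((x - cx)^2 + (y - cy)^2)
  fmat <- outer(cv, cv, function(x, y) {
    pmin(well(x, y, 10.5, 10.5), well(x, y, 8.5, 8.5)) +
      ifelse(x < 9.5 & y > 9.5, 5, 0)
  })
  st <- label_states(mk_fes(fmat, cv), 9.5)
  expect_setequal(st$region, c("inactive", "intermediate", "active",
                               "forbidden_path"))
  expect_equal(sum(st$n_nodes), 81 * 81)
  act <- st[st$region == "active", ]
  expect_equal(c(act$cv1_min, act$cv2_min), c(8.5, 8.5), tolerance = 0.06)
  ina <- st[st$region == "inactive", ]
  expect_equal(c(ina$cv1_min, ina$cv2_min), c(10.5, 10.5), tolerance = 0.06)
  # flat surface: all four region minima equal
  st_flat <- label_states(mk_fes(matrix(1, 81, 81), cv), 9.5)
  expect_true(all(st_flat$min_free_energy == 0))
  # grid not spanning the threshold
  expect_error(label_states(mk_fes(matrix(1, 81, 81),
                                   seq(10, 14, length.out = 81))), "span")
  # single minimum at (8, 8) sits in the active region
  fmin <- outer(cv, cv, function(x, y) (x - 8)^2 + (y - 8)^2)
  st2 <- label_states(mk_fes(fmin, cv), 9.5)
  act2 <- st2[st2$region == "active", ]
  expect_equal(c(act2$cv1_min, act2$cv2_min), c(8, 8), tolerance = 0.06)
})

test_that("crystal-point CVs agree with the distance-series machinery", {
  set.seed(7)
  top <- make_sidechain_topology()
  # place the CV atoms at known separations: d1 = 10, d2 computed
  xyz <- top$xyz
  at <- top$atoms
  i_cz <- at$atom_index[at$name == "CZ"]
  i_ca550 <- at$atom_index[at$resseq == 229 & at$name == "CA"]
  xyz[i_cz, ] <- c(0, 0, 0)
  xyz[i_ca550, ] <- c(0, 0, 10)
  top$xyz <- xyz
  defs <- builtin_switch_definitions()
  # the fixture has no F6.41, so reuse two resolvable distances as CVs
  cvs <- list(defs[["F6.44 activation"]], defs[["Ionic lock closure"]])
  cp <- crystal_point(top, cv_defs = cvs)
  expect_equal(cp$d1, 10.0, tolerance = 1e-12)
  # cross-module oracle: equals distance_series on a one-frame trajectory
  tr <- md_trajectory(xyz)
  d2 <- distance_series(tr, select_atom(top, "3.50", "arg_CE"),
                        select_atom(top, "6.30", "glu_CD"))
  expect_equal(cp$d2, d2)
  # swapping the CV definitions swaps the outputs
  cp_swap <- crystal_point(top, cv_defs = rev(cvs))
  expect_equal(unname(unlist(cp_swap)), unname(rev(unlist(cp))))
})

test_that("FES text outputs round-trip through the CSV form", {
  set.seed(65)
  recs <- tibble::tibble(time_ps = 1:5, cv1 = runif(5, 8, 11),
                         cv2 = runif(5, 8, 11), sigma1 = 0.3, sigma2 = 0.3,
                         height = 0.1, walker = 1L)
  fes <- reconstruct_fes(hills_log(recs, gamma = 10), n_nodes = 15)
  csv <- withr::local_tempfile(fileext = ".csv")
  dat <- withr::local_tempfile(fileext = ".dat")
  write_fes(fes, csv)
  write_fes(fes, dat)
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(nrow(back), 225)
  expect_equal(sort(unique(back$cv1)), fes$cv1)
  expect_equal(max(back$free_energy_kcal_mol), max(fes$F), tolerance = 1e-6)
  gp <- readLines(dat)
  expect_equal(sum(gp == ""), 15)  # one blank line per cv1 block
})
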