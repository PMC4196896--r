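test_that("distance series match a brute-force per-frame loop", {
  coords <- array(0, c(2, 2, 3))
  coords[, 2, 3] <- c(9.5, 0)
  tr <- md_trajectory(coords)
  expect_equal(distance_series(tr, 1, 2), c(9.5, 0))

  set.seed(11)
  coords <- array(rnorm(100 * 4 * 3, sd = 6), c(100, 4, 3))
  tr <- md_trajectory(coords)
  d <- distance_series(tr, 2, 4)
  oracle <- vapply(1:100, function(i) {
    sqrt(sum((coords[i, 2, ] - coords[i, 4, ])^2))
  }, numeric(1))
  expect_equal(d, oracle, tolerance = 1e-12)
})

test_that("min-over-pairs reduction equals the pairwise minimum", {
  set.seed(12)
  coords <- array(rnorm(50 * 6 * 3, sd = 4), c(50, 6, 3))
  tr <- md_trajectory(coords)
  d <- distance_series(tr, c(1, 2), c(4, 5, 6), reduction = "min_over_pairs")
  oracle <- vapply(1:50, function(i) {
    min(outer(1:2, 4:6, Vectorize(function(a, b) {
      sqrt(sum((coords[i, a, ] - coords[i, b, ])^2))
    })))
  }, numeric(1))
  expect_equal(d, oracle, tolerance = 1e-12)
})

test_that("a distance exactly at the threshold classifies engaged", {
  def <- switch_definition("F6.44 activation",
                           list(bw = "6.44", role = "ring_C4"),
                           list(bw = "5.50", role = "CA"), 9.5)
  expect_identical(classify_states(c(9.4, 9.5, 9.6), def),
                   c(TRUE, TRUE, FALSE))
  lock <- switch_definition("lock", list(), list(), 5.0)
  expect_identical(classify_states(rep(20, 5), lock), rep(FALSE, 5))
})

test_that("engagement percentage equals the brute-force count", {
  # 10 000 distances with exactly 5 400 at or below threshold -> 54.00 %
  set.seed(13)
  d <- c(runif(5400, 8, 9.5), runif(4600, 9.5001, 11))[sample(10000)]
  def <- switch_definition("F6.44 activation", list(), list(), 9.5)
  states <- classify_states(d, def)
  expect_identical(sum(d <= 9.5), 5400L)
  expect_equal(100 * mean(states), 54.00)
  ser <- tibble::tibble(switch = "F6.44 activation", replicate = 1,
                        time_ps = seq_along(d), distance_A = d,
                        engaged = states)
  expect_equal(glance(engagement_summary(ser))$pct_engaged, 54.00)
})

test_that("pooled engagement is frame-weighted across replicates", {
  mk <- function(rep, n, n_eng) {
    tibble::tibble(switch = "s", replicate = rep, time_ps = seq_len(n),
                   distance_A = 1, engaged = c(rep(TRUE, n_eng),
                                               rep(FALSE, n - n_eng)))
  }
  # equal lengths: (10 + 30) / 200
  summ <- engagement_summary(dplyr::bind_rows(mk(1, 100, 10), mk(2, 100, 30)))
  expect_equal(glance(summ)$pct_engaged, 20)
  expect_equal(sort(tidy(summ)$pct_engaged), c(10, 30))
  # unequal lengths: 100 of 400 frames engaged -> 25 %, not 50 %
  summ2 <- engagement_summary(dplyr::bind_rows(mk(1, 100, 100), mk(2, 300, 0)))
  expect_equal(glance(summ2)$pct_engaged, 25)
  # single engaged frame
  expect_equal(glance(engagement_summary(mk(1, 1, 1)))$pct_engaged, 100)
  expect_error(engagement_summary(mk(1, 2, 0)[0, ]), ".")
})

test_that("classification is invariant under rigid motion of each frame", {
  set.seed(14)
  g <- gen_switch_trajectory(0.5, 200, dwell = 10, seed = 21)
  def <- switch_definition("s", list(), list(), 9.5)
  base <- classify_states(distance_series(g$traj, 1, 2), def)
  coords <- g$traj$coords
  for (i in seq_len(dim(coords)[1])) {
    r <- random_rotation()
    shift <- rnorm(3, sd = 50)
    coords[i, , ] <- sweep(matrix(coords[i, , ], ncol = 3) %*% t(r), 2,
                           shift, `+`)
  }
  moved <- classify_states(
    distance_series(md_trajectory(coords), 1, 2), def)
  expect_identical(moved, base)
})

test_that("built-in definitions carry the documented atoms and thresholds", {
  defs <- builtin_switch_definitions()
  expect_named(defs, c("F6.44 activation", "F6.41 activation",
                       "Ionic lock closure", "D3.49-R3.50 salt bridge",
                       "Y7.53-H3 distance", "Y7.53-H2 distance"))
  expect_equal(defs[["F6.44 activation"]]$threshold_A, 9.5)
  expect_equal(defs[["F6.41 activation"]]$sel_b$bw, "5.54")
  lock <- defs[["Ionic lock closure"]]
  expect_equal(lock$threshold_A, 5.0)
  expect_equal(lock$sel_a, list(bw = "3.50", role = "arg_CE"))
  expect_equal(lock$sel_b, list(bw = "6.30", role = "glu_CD"))
  salt <- defs[["D3.49-R3.50 salt bridge"]]
  expect_equal(salt$pair_reduction, "min_over_pairs")
  y <- defs[["Y7.53-H3 distance"]]
  expect_true(is.na(y$threshold_A))
  expect_equal(y$sel_a, list(bw = "7.53", role = "tyr_OH"))
  expect_equal(defs[["Y7.53-H2 distance"]]$sel_b$bw, "2.40")

  # the salt bridge resolves to a 2 x 3 pair set and takes the minimum
  set.seed(7)
  top <- make_sidechain_topology()
  ia <- select_atom(top, salt$sel_a$bw, salt$sel_a$role)
  ib <- select_atom(top, salt$sel_b$bw, salt$sel_b$role)
  expect_length(ia, 2)
  expect_length(ib, 3)
})

test_that("Y7.53 reporter series stay unclassified", {
  set.seed(7)
  top <- make_sidechain_topology()
  tr <- md_trajectory(top$xyz)
  ser <- switch_series(tr, top,
                       builtin_switch_definitions()[["Y7.53-H3 distance"]])
  expect_true(all(is.na(ser$engaged)))
  expect_true(all(ser$distance_A >= 0))
})

test_that("transition counts match the two-state chain expectation", {
  expect_identical(transition_count(c(TRUE, TRUE, TRUE)), 0L)
  expect_identical(transition_count(c(TRUE, FALSE, TRUE, FALSE)), 3L)
  expect_warning(tc <- transition_count(logical(1)), "fewer than 2")
  expect_identical(tc, 0L)
  # analytic expectation: flips per step = 2 p (1 - p) / dwell
  p <- 0.5; dwell <- 10; n <- 50000
  g <- gen_switch_trajectory(p, n, dwell = dwell, seed = 31)
  expected <- (n - 1) * 2 * p * (1 - p) / dwell
  sigma <- sqrt((n - 1) * 2 * p * (1 - p) / dwell *
                  (1 - 2 * p * (1 - p) / dwell))
  expect_lt(abs(transition_count(g$states) - expected), 3 * sigma)
})
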