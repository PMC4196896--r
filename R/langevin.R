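#' Analytic 2D potentials for the toy sampler
#'
#' `potential_harmonic()` is an isotropic harmonic well;
#' `potential_double_well()` is a quartic double well along the first CV,
#' `U = V0 ((x - x0)^2 - a^2)^2 / a^4 + ky/2 (y - y0)^2`, with minima at
#' `x0 -/+ a` (depth 0) and a saddle of height exactly `V0` at `x0` — so
#' basin positions and the barrier are known in closed form.
#'
#' @param k_kcal_A2,k_y force constants (kcal/mol/Angstrom^2).
#' @param center minimum position (length 2 for harmonic, scalar `x0` for
#'   the double well).
#' @param barrier_kcal `V0`, the barrier height.
#' @param half_sep_A `a`, half the distance between the minima.
#' @param y0 transverse minimum position.
#' @return List of class `cv_potential`: `U(s)`, `force(s)` (both take an
#'   `n x 2` matrix), `minima` (`k x 2`), `barrier_kcal`, `saddle`.
#' @export
potential_harmonic <- function(k_kcal_A2 = 2, center = c(10, 10)) {
  structure(list(
    U = function(s) 0.5 * k_kcal_A2 * rowSums(sweep(s, 2, center)^2),
    force = function(s) -k_kcal_A2 * sweep(s, 2, center),
    minima = matrix(center, 1), barrier_kcal = NA_real_, saddle = NULL,
    k = k_kcal_A2, center = center, id = "harmonic"),
    class = "cv_potential")
}

#' @rdname potential_harmonic
#' @export
potential_double_well <- function(barrier_kcal = 2.5, center = 9.5,
                                  half_sep_A = 1.0, k_y = 2.0, y0 = 9.5) {
  v0 <- barrier_kcal; a <- half_sep_A
  structure(list(
    U = function(s) {
      dx <- s[, 1] - center
      v0 * (dx^2 - a^2)^2 / a^4 + 0.5 * k_y * (s[, 2] - y0)^2
    },
    force = function(s) {
      dx <- s[, 1] - center
      cbind(-4 * v0 * dx * (dx^2 - a^2) / a^4, -k_y * (s[, 2] - y0))
    },
    minima = cbind(center + c(-a, a), y0),
    barrier_kcal = v0, saddle = c(center, y0),
    id = "double_well"),
    class = "cv_potential")
}

#' Multiple-walker well-tempered metadynamics on an analytic potential
#'
#' Overdamped (Brownian) Langevin dynamics of `n_walkers` independent
#' walkers on a 2D analytic potential plus the shared history-dependent
#' bias.  Hills of the prescribed width are deposited every `pace_steps`
#' steps with the well-tempered height decay
#' `w = height * exp(-V(s) / (kB * dT))`, `dT = (gamma - 1) T`, and the
#' *deposited* heights are recorded in the returned hills log.  Walkers
#' interact through the shared bias, which each walker re-reads at the
#' exchange interval (mirroring walkers that flush and re-read hills
#' files every 20 ps).  The bias is accumulated on an internal grid with
#' bilinear interpolation for forces, the grid-cache scheme of production
#' metadynamics engines; walkers leaving the CV bounds are reflected.
#'
#' Update rule: `s' = s + (D dt / kBT) F(s) + sqrt(2 D dt) xi` with
#' diffusion `D = kBT / friction`.
#'
#' @param potential a `cv_potential`.
#' @param n_walkers number of walkers (default 6).
#' @param n_steps steps per walker.
#' @param dt_ps time step (ps).
#' @param friction friction coefficient (kcal mol^-1 ps Angstrom^-2);
#'   higher = slower diffusion.
#' @param temperature_K temperature (default 300).
#' @param pace_steps hill deposition interval in steps (default: every
#'   4 ps worth of steps).
#' @param hill_height_kcal,hill_sigma_A nominal hill height and width.
#' @param gamma well-tempered bias factor (default 10).
#' @param exchange_ps bias-sharing refresh interval (default 20 ps).
#' @param bounds CV bounds, list of two length-2 ranges (reflecting walls).
#' @param start `n_walkers x 2` start positions (default: the first
#'   potential minimum, or bounds centre).
#' @param deposit_hills set `FALSE` for plain (unbiased) dynamics.
#' @param seed RNG seed.
#' @return List: `hills` (a [hills_log()]), `cv_traj` (tibble `time_ps`,
#'   `walker`, `cv1`, `cv2`), `potential`, `n_reflections`.
#' @export
run_langevin_metad <- function(potential, n_walkers = 6, n_steps = 5000,
                               dt_ps = 2, friction = 120,
                               temperature_K = 300,
                               pace_steps = max(1L, round(4 / dt_ps)),
                               hill_height_kcal = 0.1, hill_sigma_A = 0.1,
                               gamma = 10, exchange_ps = 20,
                               bounds = list(c(6, 14), c(6, 14)),
                               start = NULL, deposit_hills = TRUE,
                               seed = NULL) {
  stopifnot(inherits(potential, "cv_potential"), gamma > 1, pace_steps >= 1)
  kbt <- KB_KCAL * temperature_K
  d_diff <- kbt / friction
  drift_c <- d_diff * dt_ps / kbt
  noise_c <- sqrt(2 * d_diff * dt_ps)
  exchange_steps <- max(1L, round(exchange_ps / dt_ps))
  kb_dT <- KB_KCAL * (gamma - 1) * temperature_K
  lo <- c(bounds[[1]][1], bounds[[2]][1])
  hi <- c(bounds[[1]][2], bounds[[2]][2])
  if (is.null(start)) {
    s0 <- if (!is.null(potential$minima)) potential$minima[1, ] else
      (lo + hi) / 2
    start <- matrix(rep(s0, each = n_walkers), n_walkers)
  }
  stopifnot(nrow(start) == n_walkers, ncol(start) == 2)

  # shared bias grid (live) and the per-exchange published copy
  h <- hill_sigma_A / 2
  gx <- seq(lo[1], hi[1], by = h); gy <- seq(lo[2], hi[2], by = h)
  live <- matrix(0, length(gx), length(gy))
  published <- live
  support <- ceiling(5 * hill_sigma_A / h)

  bilinear <- function(grid, s) {
    # value and gradient of the piecewise-bilinear bias at points s (n x 2)
    i <- pmin(pmax(floor((s[, 1] - lo[1]) / h) + 1, 1), length(gx) - 1)
    j <- pmin(pmax(floor((s[, 2] - lo[2]) / h) + 1, 1), length(gy) - 1)
    tx <- (s[, 1] - gx[i]) / h; ty <- (s[, 2] - gy[j]) / h
    n <- nrow(s); ng <- length(gx)
    f00 <- grid[cbind(i, j)]; f10 <- grid[cbind(i + 1, j)]
    f01 <- grid[cbind(i, j + 1)]; f11 <- grid[cbind(i + 1, j + 1)]
    v <- (1 - tx) * (1 - ty) * f00 + tx * (1 - ty) * f10 +
      (1 - tx) * ty * f01 + tx * ty * f11
    dvx <- ((1 - ty) * (f10 - f00) + ty * (f11 - f01)) / h
    dvy <- ((1 - tx) * (f01 - f00) + tx * (f11 - f10)) / h
    list(v = v, grad = cbind(dvx, dvy))
  }
  deposit <- function(s, w) {
    # add one Gaussian to the live grid over its +-5 sigma support
    ci <- round((s[1] - lo[1]) / h) + 1
    cj <- round((s[2] - lo[2]) / h) + 1
    ii <- max(1, ci - support):min(length(gx), ci + support)
    jj <- max(1, cj - support):min(length(gy), cj + support)
    ex <- exp(-(gx[ii] - s[1])^2 / (2 * hill_sigma_A^2))
    ey <- exp(-(gy[jj] - s[2])^2 / (2 * hill_sigma_A^2))
    live[ii, jj] <<- live[ii, jj] + w * outer(ex, ey)
  }

  s <- start
  n_hills_max <- if (deposit_hills) n_walkers * (n_steps %/% pace_steps) else 0
  hill_rec <- matrix(NA_real_, n_hills_max, 6)  # time cv1 cv2 s1 s2 height
  hill_walker <- integer(n_hills_max)
  n_rec <- 0L
  thin <- max(1L, n_steps %/% 2000L)
  cv_keep <- array(NA_real_, c(n_steps %/% thin, n_walkers, 2))
  keep_t <- numeric(n_steps %/% thin)
  n_reflect <- 0L

  with_component_seed(seed, "langevin_metad", {
    for (step in seq_len(n_steps)) {
      f <- potential$force(s)
      if (deposit_hills) {
        b <- bilinear(published, s)
        f <- f - b$grad
      }
      s <- s + drift_c * f + noise_c * matrix(rnorm(2 * n_walkers), n_walkers)
      # reflecting walls at the CV bounds
      for (k in 1:2) {
        below <- s[, k] < lo[k]; above <- s[, k] > hi[k]
        n_reflect <- n_reflect + sum(below) + sum(above)
        s[below, k] <- 2 * lo[k] - s[below, k]
        s[above, k] <- 2 * hi[k] - s[above, k]
        s[, k] <- pmin(pmax(s[, k], lo[k]), hi[k])
      }
      if (deposit_hills && step %% pace_steps == 0L) {
        v_here <- bilinear(live, s)$v
        w_dep <- hill_height_kcal * exp(-v_here / kb_dT)
        for (w in seq_len(n_walkers)) {
          deposit(s[w, ], w_dep[w])
          n_rec <- n_rec + 1L
          hill_rec[n_rec, ] <- c(step * dt_ps, s[w, 1], s[w, 2],
                                 hill_sigma_A, hill_sigma_A, w_dep[w])
          hill_walker[n_rec] <- w
        }
      }
      if (step %% exchange_steps == 0L) published <- live
      if (step %% thin == 0L) {
        cv_keep[step %/% thin, , ] <- s
        keep_t[step %/% thin] <- step * dt_ps
      }
    }
  })

  hills <- if (n_rec > 0) {
    hills_log(tibble(time_ps = hill_rec[1:n_rec, 1],
                     cv1 = hill_rec[1:n_rec, 2], cv2 = hill_rec[1:n_rec, 3],
                     sigma1 = hill_rec[1:n_rec, 4],
                     sigma2 = hill_rec[1:n_rec, 5],
                     height = hill_rec[1:n_rec, 6],
                     walker = hill_walker[1:n_rec]),
              gamma = gamma, temperature_K = temperature_K)
  } else {
    hills_log(tibble(time_ps = numeric(), cv1 = numeric(), cv2 = numeric(),
                     sigma1 = numeric(), sigma2 = numeric(),
                     height = numeric(), walker = integer())[0, ],
              gamma = gamma, temperature_K = temperature_K)
  }
  nk <- dim(cv_keep)[1]
  cv_traj <- tibble(
    time_ps = rep(keep_t, times = n_walkers),
    walker = rep(seq_len(n_walkers), each = nk),
    cv1 = as.vector(cv_keep[, , 1]),
    cv2 = as.vector(cv_keep[, , 2]))
  list(hills = hills, cv_traj = cv_traj, potential = potential,
       n_reflections = n_reflect)
}
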