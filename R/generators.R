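#' Two-state Markov switch trajectory with known ground truth
#'
#' Simulates a micro-switch distance as a two-state Markov chain with
#' stationary engaged fraction `p` and a dwell scale, plus iid Gaussian
#' positional noise.  Exit rates are `q_engaged = (1-p)/dwell` and
#' `q_disengaged = p/dwell`, which give stationary fraction exactly `p`
#' and lag-1 state autocorrelation `1 - 1/dwell`.  The trajectory holds
#' two marker atoms whose inter-atomic distance carries the signal; the
#' true state labels are returned alongside (they are drawn first and are
#' never re-derived from coordinates).
#'
#' The default distances straddle the 9.5 Angstrom activation threshold
#' (engaged 8.5 / disengaged 10.5, sigma 0.25); the generator refuses
#' specs whose means are within 3 sigma of the threshold (inseparable).
#'
#' @param p stationary engaged fraction, in (0, 1); 0 and 1 degenerate to
#'   a constant state.
#' @param n_frames number of frames.
#' @param dwell mean dwell scale in frames (>= 1).
#' @param d_engaged_A,d_disengaged_A state mean distances (Angstrom).
#' @param sigma_A Gaussian noise s.d. on the distance.
#' @param threshold_A threshold the distances must straddle.
#' @param dt_ps frame spacing.
#' @param seed RNG seed (component stream derived from it).
#' @param replicate replicate id stored in the trajectory.
#' @return List: `traj` ([md_trajectory()] with 2 atoms), `states`
#'   (logical ground truth), `p`, `dwell`.
#' @export
gen_switch_trajectory <- function(p, n_frames, dwell = 50,
                                  d_engaged_A = 8.5, d_disengaged_A = 10.5,
                                  sigma_A = 0.25, threshold_A = 9.5,
                                  dt_ps = 1, seed = NULL, replicate = 1L) {
  stopifnot(p >= 0, p <= 1, dwell >= 1, n_frames >= 1)
  eng_lo <- min(d_engaged_A, d_disengaged_A) == d_engaged_A
  if (!eng_lo) abort("engaged mean must lie below the disengaged mean")
  if (threshold_A - d_engaged_A < 3 * sigma_A ||
      d_disengaged_A - threshold_A < 3 * sigma_A) {
    abort("state means must straddle the threshold by >= 3 sigma")
  }
  states <- with_component_seed(seed, "switch_markov", {
    markov_states(p, n_frames, dwell)
  })
  noise <- with_component_seed(seed, "switch_noise", {
    rnorm(n_frames, sd = sigma_A)
  })
  d <- ifelse(states, d_engaged_A, d_disengaged_A) + noise
  coords <- array(0, c(n_frames, 2L, 3L))
  coords[, 2, 3] <- d
  traj <- md_trajectory(coords, dt_ps = dt_ps, replicate = replicate)
  list(traj = traj, states = states, p = p, dwell = dwell)
}

# simulate the two-state chain; engaged = TRUE
markov_states <- function(p, n, dwell) {
  if (p == 0) return(rep(FALSE, n))
  if (p == 1) return(rep(TRUE, n))
  q_e <- (1 - p) / dwell   # engaged -> disengaged
  q_d <- p / dwell         # disengaged -> engaged
  s <- logical(n)
  s[1] <- runif(1) < p
  u <- runif(n - 1)
  for (i in seq_len(n - 1)) {
    s[i + 1] <- if (s[i]) u[i] >= q_e else u[i] < q_d
  }
  s
}

#' Ideal alpha-helix C-alpha coordinates
#'
#' Canonical alpha-helix geometry along +z: rise 1.5 Angstrom per residue,
#' twist 100 degrees per residue, radius 2.3 Angstrom.
#'
#' @param n_res number of residues (>= 4).
#' @param rise_A,twist_deg,radius_A helix parameters.
#' @return `n_res x 3` matrix of C-alpha positions.
#' @export
gen_helix <- function(n_res, rise_A = 1.5, twist_deg = 100, radius_A = 2.3) {
  stopifnot(n_res >= 4)
  k <- seq_len(n_res) - 1
  th <- k * twist_deg * pi / 180
  cbind(radius_A * cos(th), radius_A * sin(th), k * rise_A)
}

# rotation matrix about unit axis u by angle (degrees), right-handed
rotation_matrix <- function(u, angle_deg) {
  u <- u / sqrt(sum(u^2))
  th <- angle_deg * pi / 180
  c <- cos(th); s <- sin(th)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  c * diag(3) + s * ux + (1 - c) * outer(u, u)
}

#' Rotating-helix trajectory with ground-truth rotation angles
#'
#' A measured helix span is rigidly rotated about its own axis by a
#' prescribed per-frame angle profile while a second, static helix serves
#' as the alignment core.  Optionally the whole system additionally
#' tumbles (random rigid rotation + translation per frame), which core
#' pre-alignment must remove.
#'
#' @param theta_deg numeric vector: imposed rotation angle per frame.
#' @param n_res_span residues in the measured span (default 7, mirroring
#'   a 6.44-6.50 span).
#' @param n_res_core residues in the static core helix.
#' @param global_motion add random rigid-body tumbling to every atom.
#' @param noise_A iid Gaussian positional noise s.d. per coordinate.
#' @param seed RNG seed.
#' @return List: `traj`, `reference` (frame of theta = 0), `span_idx`,
#'   `core_idx`, `theta_deg`, `top` (a minimal [topology_map()]).
#' @export
gen_rotating_helix_traj <- function(theta_deg, n_res_span = 7,
                                    n_res_core = 20, global_motion = FALSE,
                                    noise_A = 0, seed = NULL) {
  span <- gen_helix(n_res_span)
  core <- sweep(gen_helix(n_res_core), 2, c(15, 0, 0), `+`)
  reference <- rbind(span, core)
  span_idx <- seq_len(n_res_span)
  core_idx <- n_res_span + seq_len(n_res_core)
  axis <- c(0, 0, 1)
  centroid <- colMeans(span)
  nf <- length(theta_deg)
  coords <- array(NA_real_, c(nf, nrow(reference), 3L))
  nuisance <- if (global_motion) {
    with_component_seed(seed, "helix_tumbling", {
      lapply(seq_len(nf), function(i) {
        ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
        list(rot = rotation_matrix(ax, runif(1, -30, 30)),
             shift = runif(3, -5, 5))
      })
    })
  } else NULL
  noise <- if (noise_A > 0) {
    with_component_seed(seed, "helix_noise", {
      array(rnorm(nf * nrow(reference) * 3, sd = noise_A),
            c(nf, nrow(reference), 3L))
    })
  } else NULL
  for (i in seq_len(nf)) {
    xyz <- reference
    r <- rotation_matrix(axis, theta_deg[i])
    xyz[span_idx, ] <- sweep(sweep(span, 2, centroid) %*% t(r), 2,
                             centroid, `+`)
    if (!is.null(noise)) xyz <- xyz + matrix(noise[i, , ], ncol = 3)
    if (!is.null(nuisance)) {
      xyz <- sweep(xyz %*% t(nuisance[[i]]$rot), 2, nuisance[[i]]$shift, `+`)
    }
    coords[i, , ] <- xyz
  }
  n_at <- nrow(reference)
  top <- topology_map(
    tibble(name = rep("CA", n_at), resname = rep("ALA", n_at),
           resseq = seq_len(n_at), element = "C"),
    xyz = reference)
  list(traj = md_trajectory(coords), reference = reference,
       span_idx = span_idx, core_idx = core_idx,
       theta_deg = theta_deg, top = top)
}

#' Uniform solvated box with optional pinned water
#'
#' Places water oxygens iid-uniformly in a rectangular box each frame at a
#' prescribed number density (count = `round(density * volume)` per
#' frame).  Optionally a marker C-alpha sits at the box centre and one
#' designated water is pinned within `pin_cutoff_A` of it in a prescribed
#' fraction of frames (uniform in the sphere when pinned, uniform outside
#' it otherwise) — ground truth for near-residue water counts.
#'
#' @param density_A3 waters per cubic Angstrom (bulk water is 0.0334).
#' @param box_A box edge lengths, length 3.
#' @param n_frames number of frames.
#' @param pin_fraction fraction of frames with the pinned water inside the
#'   cutoff (`NULL` disables the marker/pinned pair).
#' @param pin_cutoff_A pinning radius.
#' @param seed RNG seed.
#' @return List: `traj`, `top` (waters + optional marker GLY C-alpha),
#'   `pinned` (logical per frame, or `NULL`).
#' @export
gen_solvated_box <- function(density_A3, box_A = c(20, 20, 20), n_frames = 100,
                             pin_fraction = NULL, pin_cutoff_A = 2.0,
                             seed = NULL) {
  stopifnot(density_A3 >= 0, n_frames >= 1)
  vol <- prod(box_A)
  n_w <- round(density_A3 * vol)
  has_pin <- !is.null(pin_fraction)
  if (has_pin && n_w < 1) abort("pinning requires at least one water")
  centre <- box_A / 2
  n_at <- n_w + as.integer(has_pin)
  coords <- array(0, c(n_frames, max(n_at, 1L), 3L))
  pinned <- NULL
  with_component_seed(seed, "solvated_box", {
    if (has_pin) pinned <- runif(n_frames) < pin_fraction
    for (i in seq_len(n_frames)) {
      if (n_w > 0) {
        w <- cbind(runif(n_w, 0, box_A[1]), runif(n_w, 0, box_A[2]),
                   runif(n_w, 0, box_A[3]))
        if (has_pin) {
          if (pinned[i]) {
            # uniform in the sphere around the marker
            repeat {
              u <- runif(3, -pin_cutoff_A, pin_cutoff_A)
              if (sum(u^2) <= pin_cutoff_A^2) break
            }
            w[1, ] <- centre + u
          } else {
            while (sum((w[1, ] - centre)^2) <= pin_cutoff_A^2) {
              w[1, ] <- c(runif(1, 0, box_A[1]), runif(1, 0, box_A[2]),
                          runif(1, 0, box_A[3]))
            }
          }
        }
        coords[i, seq_len(n_w), ] <- w
      }
      if (has_pin) coords[i, n_at, ] <- centre
    }
  })
  atoms <- tibble(
    name = c(rep("O", n_w), if (has_pin) "CA"),
    resname = c(rep("HOH", n_w), if (has_pin) "GLY"),
    resseq = c(seq_len(n_w), if (has_pin) n_w + 1L),
    element = c(rep("O", n_w), if (has_pin) "C"))
  if (n_w == 0 && !has_pin) {
    atoms <- tibble(name = "CA", resname = "GLY", resseq = 1L, element = "C")
    coords <- array(0, c(n_frames, 1L, 3L))
  }
  bw <- if (has_pin) {
    bw_table("5.36", n_w + 1L, "GLY")
  } else NULL
  top <- topology_map(atoms, bw = bw,
                      xyz = matrix(coords[1, , ], ncol = 3))
  list(traj = md_trajectory(coords), top = top, pinned = pinned,
       box_A = box_A, density_A3 = density_A3)
}

#' Multi-switch receptor mimic with known engagement fractions
#'
#' Builds a minimal topology carrying real residue and atom names for the
#' three classified micro-switches (F6.44, F6.41 via ring C-4 vs helix-5
#' C-alphas; the R3.50-E6.30 ionic lock) plus a D3.49-R3.50 salt-bridge
#' pair, each pair placed in a spatially separate block, with each
#' switch's distance following its own two-state Markov chain.  The
#' built-in switch definitions resolve against it unchanged, so the whole
#' classification pipeline can run end-to-end against ground truth.
#'
#' @param p named numeric vector of engaged fractions for any of
#'   `"F6.44 activation"`, `"F6.41 activation"`, `"Ionic lock closure"`,
#'   `"D3.49-R3.50 salt bridge"`.
#' @param n_frames,dwell,seed,replicate as in [gen_switch_trajectory()].
#' @return List: `traj`, `top`, `truth` (tibble switch / p / states).
#' @export
gen_microswitch_system <- function(p, n_frames, dwell = 50, seed = NULL,
                                   replicate = 1L) {
  stopifnot(!is.null(names(p)))
  # residue layout: helix anchors chosen so BW positions resolve uniquely
  bw <- bw_table(
    c("2.40", "3.49", "3.50", "5.36", "5.50", "5.54", "6.30", "6.41",
      "6.44", "7.53"),
    c(80L, 119L, 120L, 215L, 229L, 233L, 300L, 311L, 314L, 400L),
    c("ALA", "ASP", "ARG", "GLY", "PRO", "ALA", "GLU", "PHE", "PHE", "TYR"))
  blocks <- list(
    "F6.44 activation" = list(
      a = list(name = "CZ", resname = "PHE", resseq = 314L),
      b = list(name = "CA", resname = "PRO", resseq = 229L),
      lo = 8.5, hi = 10.5, sigma = 0.25, thr = 9.5),
    "F6.41 activation" = list(
      a = list(name = "CZ", resname = "PHE", resseq = 311L),
      b = list(name = "CA", resname = "ALA", resseq = 233L),
      lo = 8.5, hi = 10.5, sigma = 0.25, thr = 9.5),
    "Ionic lock closure" = list(
      a = list(name = "CE", resname = "ARG", resseq = 120L),
      b = list(name = "CD", resname = "GLU", resseq = 300L),
      lo = 3.5, hi = 7.0, sigma = 0.4, thr = 5.0),
    "D3.49-R3.50 salt bridge" = list(
      a = list(name = "OD1", resname = "ASP", resseq = 119L),
      b = list(name = "NE", resname = "ARG", resseq = 120L),
      lo = 2.8, hi = 6.0, sigma = 0.3, thr = 4.0)
  )
  unknown <- setdiff(names(p), names(blocks))
  if (length(unknown) > 0) {
    abort(paste0("unknown switch name(s): ", paste(unknown, collapse = ", ")))
  }
  atoms <- list(); placements <- list(); truth <- list()
  offset <- 0
  for (nm in names(blocks)) {
    blk <- blocks[[nm]]
    atoms[[nm]] <- tibble(
      name = c(blk$a$name, blk$b$name),
      resname = c(blk$a$resname, blk$b$resname),
      resseq = c(blk$a$resseq, blk$b$resseq),
      element = substr(c(blk$a$name, blk$b$name), 1, 1))
    if (nm %in% names(p)) {
      sim <- gen_switch_trajectory(
        p[[nm]], n_frames, dwell = dwell, d_engaged_A = blk$lo,
        d_disengaged_A = blk$hi, sigma_A = blk$sigma, threshold_A = blk$thr,
        seed = if (is.null(seed)) NULL else component_seed(seed, nm),
        replicate = replicate)
      d <- sim$traj$coords[, 2, 3]
      truth[[nm]] <- tibble(switch = nm, p = p[[nm]],
                            frame = seq_len(n_frames), state = sim$states)
    } else {
      d <- rep(blk$hi, n_frames)
    }
    placements[[nm]] <- list(offset = offset, d = d)
    offset <- offset + 100
  }
  # extra single atoms so every BW entry resolves (Y7.53 reporters etc.)
  extra <- tibble(name = c("CA", "OH", "CA", "CA"),
                  resname = c("ALA", "TYR", "GLY", "ARG"),
                  resseq = c(80L, 400L, 215L, 120L),
                  element = c("C", "O", "C", "C"))
  atom_tbl <- bind_rows(c(atoms, list(extra = extra)))
  n_at <- nrow(atom_tbl)
  coords <- array(0, c(n_frames, n_at, 3L))
  row <- 0
  for (nm in names(blocks)) {
    pl <- placements[[nm]]
    coords[, row + 1L, 1] <- pl$offset
    coords[, row + 2L, 1] <- pl$offset
    coords[, row + 2L, 3] <- pl$d
    row <- row + 2L
  }
  coords[, row + 1L, 1] <- 500    # CA 2.40
  coords[, row + 2L, 1] <- 520    # OH Y7.53
  coords[, row + 3L, 1] <- 540    # CA G5.36
  coords[, row + 4L, 1] <- 560    # CA R3.50
  top <- topology_map(atom_tbl, bw = bw,
                      xyz = matrix(coords[1, , ], ncol = 3))
  list(traj = md_trajectory(coords, replicate = replicate), top = top,
       truth = bind_rows(truth))
}
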