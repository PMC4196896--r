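#' Read well-tempered metadynamics hills logs
#'
#' Parses HILLS-style whitespace text: one record per deposited Gaussian
#' with columns `time cv1 cv2 sigma1 sigma2 height [biasfactor]`; lines
#' beginning with `#!` (or `#`) are headers and are skipped.  One file per
#' walker; all files are merged and sorted by deposition time, ties broken
#' by walker id ascending (stable multi-walker merge).  Heights are taken
#' as the *deposited* (already-tempered) values, the convention of
#' standard metadynamics engines, so reconstruction applies only the
#' well-tempered prefactor.
#'
#' @param paths character vector of hills files, one per walker.
#' @param gamma well-tempered bias factor (> 1).
#' @param temperature_K system temperature (default 300).
#' @return Tibble of class `hills_log`: `time_ps`, `cv1`, `cv2`, `sigma1`,
#'   `sigma2`, `height`, `walker`; attributes `gamma`, `temperature_K`.
#' @export
read_hills <- function(paths, gamma, temperature_K = 300) {
  stopifnot(length(paths) >= 1)
  logs <- purrr::imap(paths, function(p, w) {
    lines <- readLines(p)
    keep <- !grepl("^\\s*(#|$)", lines)
    recs <- lines[keep]
    lineno <- which(keep)
    if (length(recs) == 0) return(NULL)
    fields <- strsplit(trimws(recs), "\\s+")
    nf <- vapply(fields, length, 1L)
    if (any(nf < 6)) {
      bad <- lineno[which(nf < 6)[1]]
      abort(paste0("malformed hills record in ", p, " line ", bad,
                   ": expected >= 6 whitespace-separated fields"))
    }
    if (length(unique(nf)) != 1) {
      bad <- lineno[which(nf != nf[1])[1]]
      abort(paste0("inconsistent column count in ", p, " line ", bad))
    }
    num <- suppressWarnings(
      matrix(as.numeric(unlist(fields)), ncol = nf[1], byrow = TRUE))
    if (anyNA(num[, 1:6])) {
      bad <- lineno[which(rowSums(is.na(num[, 1:6, drop = FALSE])) > 0)[1]]
      abort(paste0("non-numeric hills record in ", p, " line ", bad))
    }
    tibble(time_ps = num[, 1], cv1 = num[, 2], cv2 = num[, 3],
           sigma1 = num[, 4], sigma2 = num[, 5], height = num[, 6],
           walker = w)
  })
  merged <- bind_rows(logs)
  if (nrow(merged) == 0) abort("hills files contain no records")
  hills_log(merged, gamma = gamma, temperature_K = temperature_K)
}

#' @rdname read_hills
#' @param records tibble with columns `time_ps`, `cv1`, `cv2`, `sigma1`,
#'   `sigma2`, `height`, `walker`.
#' @export
hills_log <- function(records, gamma, temperature_K = 300) {
  stopifnot(all(c("time_ps", "cv1", "cv2", "sigma1", "sigma2", "height",
                  "walker") %in% names(records)))
  if (any(records$sigma1 <= 0 | records$sigma2 <= 0)) {
    abort("hill widths must be positive")
  }
  if (any(records$height <= 0)) abort("hill heights must be positive")
  if (!is.null(gamma) && gamma <= 1) {
    abort("well-tempered bias factor gamma must exceed 1")
  }
  out <- as_tibble(records) %>%
    arrange(.data$time_ps, .data$walker)
  attr(out, "gamma") <- gamma
  attr(out, "temperature_K") <- temperature_K
  class(out) <- c("hills_log", class(out))
  out
}

#' @rdname read_hills
#' @param log a `hills_log`.
#' @param path output file (HILLS-style text).
#' @param walker restrict to one walker id (default: all records).
#' @export
write_hills <- function(log, path, walker = NULL) {
  stopifnot(inherits(log, "hills_log"))
  recs <- if (is.null(walker)) log else log[log$walker == walker, ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#! FIELDS time cv1 cv2 sigma_cv1 sigma_cv2 height biasf", con)
  writeLines(sprintf("%.6f %.6f %.6f %.6f %.6f %.8f %.1f",
                     recs$time_ps, recs$cv1, recs$cv2, recs$sigma1,
                     recs$sigma2, recs$height, attr(log, "gamma")), con)
  invisible(path)
}

#' Metadynamics bias potential at arbitrary CV points
#'
#' Sum of the recorded Gaussians,
#' `V(s) = sum_i w_i exp(-sum_k (s_k - s_ki)^2 / (2 sigma_ki^2))`,
#' evaluated exactly (no cutoff).  An empty log gives 0 everywhere.
#'
#' @param log a `hills_log` (may have zero rows).
#' @param points numeric matrix or data frame with two columns `(cv1, cv2)`,
#'   or a length-2 vector for a single point.
#' @return Numeric vector of bias values (kcal/mol), one per point.
#' @export
bias_potential <- function(log, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2)
  if (is.null(log) || nrow(log) == 0) return(numeric(nrow(points)))
  v <- numeric(nrow(points))
  for (i in seq_len(nrow(log))) {
    v <- v + log$height[i] *
      exp(-((points[, 1] - log$cv1[i])^2 / (2 * log$sigma1[i]^2) +
              (points[, 2] - log$cv2[i])^2 / (2 * log$sigma2[i]^2)))
  }
  v
}

#' Reconstruct the free-energy surface from a hills log
#'
#' Well-tempered estimator `F(s) = -gamma/(gamma-1) * V(s)` where `V` is
#' the accumulated bias of the recorded (already-tempered) hills; with a
#' bias factor of 10 the prefactor is 10/9.  The surface is shifted so its
#' minimum is 0.
#'
#' @param log a `hills_log` carrying `gamma`.
#' @param cv1_range,cv2_range grid extents in Angstrom (default `c(6, 14)`,
#'   covering the inactive and active basins of the connector-region CVs).
#' @param n_nodes nodes per axis (default 120).
#' @return Object of class `fes_grid`: `cv1`, `cv2` (axes), `F`
#'   (`n1 x n2` matrix, kcal/mol, min 0), `gamma`, `shift`.
#' @export
reconstruct_fes <- function(log, cv1_range = c(6, 14), cv2_range = c(6, 14),
                            n_nodes = 120) {
  gamma <- attr(log, "gamma")
  if (is.null(gamma) || gamma <= 1) {
    abort("reconstruction requires a well-tempered bias factor gamma > 1")
  }
  n_nodes <- rep(as.integer(n_nodes), length.out = 2)
  cv1 <- seq(cv1_range[1], cv1_range[2], length.out = n_nodes[1])
  cv2 <- seq(cv2_range[1], cv2_range[2], length.out = n_nodes[2])
  if (nrow(log) == 0) {
    v <- matrix(0, n_nodes[1], n_nodes[2])
  } else {
    # separable Gaussians: V = crossprod(G1 * w, G2) with
    # G1[h, i] = exp(-(cv1_i - c1_h)^2 / (2 s1_h^2))
    g1 <- exp(-outer(log$cv1, cv1, `-`)^2 / (2 * log$sigma1^2))
    g2 <- exp(-outer(log$cv2, cv2, `-`)^2 / (2 * log$sigma2^2))
    v <- crossprod(g1 * log$height, g2)
  }
  f <- -gamma / (gamma - 1) * v
  shift <- min(f)
  structure(list(cv1 = cv1, cv2 = cv2, F = f - shift, gamma = gamma,
                 shift = shift),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  cat("<fes_grid>", length(x$cv1), "x", length(x$cv2), "nodes over [",
      min(x$cv1), ",", max(x$cv1), "] x [", min(x$cv2), ",", max(x$cv2),
      "] A; F in [0,", round(max(x$F), 3), "] kcal/mol; gamma =",
      x$gamma, "\n")
  invisible(x)
}

#' @rdname reconstruct_fes
#' @param x an `fes_grid`.
#' @param ... unused.
#' @return `tidy()`: long tibble `cv1`, `cv2`, `free_energy`.
#' @export
tidy.fes_grid <- function(x, ...) {
  tibble(cv1 = rep(x$cv1, times = length(x$cv2)),
         cv2 = rep(x$cv2, each = length(x$cv1)),
         free_energy = as.vector(x$F))
}

#' @rdname reconstruct_fes
#' @export
glance.fes_grid <- function(x, ...) {
  tibble(n_nodes = length(x$cv1) * length(x$cv2), gamma = x$gamma,
         max_free_energy = max(x$F))
}

#' Label activation-state regions of the CV plane
#'
#' Partitions the (d1, d2) plane by the activation threshold (9.5 Angstrom
#' by default, the "equal or lower" rule making the boundary active):
#' inactive (d1 > t, d2 > t), intermediate (d1 > t, d2 <= t), active
#' (d1 <= t, d2 <= t), and the fourth quadrant (d1 <= t, d2 > t) reported
#' as `forbidden_path` — the activation ordering states that d1 cannot
#' engage before d2, so a low minimum there would violate it.
#'
#' @param fes an `fes_grid` spanning the threshold on both axes.
#' @param threshold_A activation threshold (default 9.5).
#' @return Tibble: `region`, `min_free_energy`, `cv1_min`, `cv2_min`,
#'   `n_nodes`.
#' @export
label_states <- function(fes, threshold_A = 9.5) {
  stopifnot(inherits(fes, "fes_grid"))
  if (min(fes$cv1) >= threshold_A || max(fes$cv1) <= threshold_A ||
      min(fes$cv2) >= threshold_A || max(fes$cv2) <= threshold_A) {
    abort("FES grid does not span the activation threshold on both axes")
  }
  a1 <- fes$cv1 <= threshold_A   # active side of d1
  a2 <- fes$cv2 <= threshold_A
  regions <- list(
    inactive = outer(!a1, !a2, `&`),
    intermediate = outer(!a1, a2, `&`),
    active = outer(a1, a2, `&`),
    forbidden_path = outer(a1, !a2, `&`)
  )
  purrr::imap(regions, function(mask, nm) {
    f <- fes$F
    f[!mask] <- Inf
    k <- arrayInd(which.min(f), dim(f))
    tibble(region = nm, min_free_energy = f[k],
           cv1_min = fes$cv1[k[1]], cv2_min = fes$cv2[k[2]],
           n_nodes = sum(mask))
  }) %>% bind_rows()
}

#' Locate basins and the dividing barrier of a double-well surface
#'
#' Splits the surface at `divide_cv1` (the activation threshold for the
#' connector-region CVs) and, for each side, reports the grid argmin and
#' the Boltzmann-weighted basin centroid
#' `<s> = sum s exp(-F/kBT) / sum exp(-F/kBT)` — the standard robust
#' estimator of a basin position, insensitive to node-scale roughness of
#' the reconstruction where a raw argmin is not.  The barrier is the
#' minimum free energy along the dividing line (the saddle of the lowest
#' crossing path) minus the global minimum.
#'
#' @param fes an `fes_grid`.
#' @param divide_cv1 dividing value of the first CV (default 9.5).
#' @param temperature_K temperature for the Boltzmann weight.
#' @return List: `basins` (tibble `side`, `cv1_argmin`, `cv2_argmin`,
#'   `cv1_centroid`, `cv2_centroid`, `min_free_energy`), `barrier_kcal`.
#' @export
fes_minima <- function(fes, divide_cv1 = 9.5, temperature_K = 300) {
  stopifnot(inherits(fes, "fes_grid"))
  kbt <- KB_KCAL * temperature_K
  n1 <- length(fes$cv1); n2 <- length(fes$cv2)
  left <- outer(fes$cv1 <= divide_cv1, rep(TRUE, n2), `&`)
  one_side <- function(mask, side) {
    f <- fes$F
    f[!mask] <- Inf
    k <- arrayInd(which.min(f), dim(f))
    w <- exp(-fes$F / kbt) * mask
    tibble(side = side,
           cv1_argmin = fes$cv1[k[1]], cv2_argmin = fes$cv2[k[2]],
           cv1_centroid = sum(outer(fes$cv1, rep(1, n2)) * w) / sum(w),
           cv2_centroid = sum(outer(rep(1, n1), fes$cv2) * w) / sum(w),
           min_free_energy = f[k])
  }
  icol <- which.min(abs(fes$cv1 - divide_cv1))
  list(basins = bind_rows(one_side(left, "low_cv1"),
                          one_side(!left, "high_cv1")),
       barrier_kcal = min(fes$F[icol, ]) - min(fes$F))
}

#' Evaluate the two connector-region CVs on a single structure
#'
#' d1 = ring C-4 of F6.44 to C-alpha of 5.50; d2 = ring C-4 of F6.41 to
#' C-alpha of 5.54 — evaluated on reference coordinates, e.g. to mark the
#' crystal-structure point on a free-energy surface.
#'
#' @param top a [topology_map()] with reference coordinates and BW table.
#' @param xyz optional coordinates overriding the topology reference.
#' @param cv_defs list of two [switch_definition()]s; defaults to the
#'   built-in F6.44 / F6.41 activation distances.
#' @return Tibble with one row: `d1`, `d2` (Angstrom).
#' @export
crystal_point <- function(top, xyz = NULL, cv_defs = NULL) {
  if (is.null(xyz)) xyz <- top$xyz
  if (is.null(xyz)) abort("no reference coordinates available")
  if (is.null(cv_defs)) {
    defs <- builtin_switch_definitions()
    cv_defs <- list(defs[["F6.44 activation"]], defs[["F6.41 activation"]])
  }
  traj <- md_trajectory(as.matrix(xyz))
  eval_cv <- function(def) {
    ia <- select_atom(top, def$sel_a$bw, def$sel_a$role)
    ib <- select_atom(top, def$sel_b$bw, def$sel_b$role)
    distance_series(traj, ia, ib, reduction = def$pair_reduction)
  }
  tibble(d1 = eval_cv(cv_defs[[1]]), d2 = eval_cv(cv_defs[[2]]))
}

#' Write a free-energy surface as plain text
#'
#' Gnuplot-compatible 3-column blocks (`cv1 cv2 F`, blank line between
#' cv1 scans) or CSV.
#'
#' @param fes an `fes_grid`.
#' @param path output path; `.csv` selects CSV, anything else the
#'   3-column text layout.
#' @export
write_fes <- function(fes, path) {
  td <- tidy(fes) %>% arrange(.data$cv1, .data$cv2)
  if (tolower(tools::file_ext(path)) == "csv") {
    readr::write_csv(rename(td, free_energy_kcal_mol = "free_energy"), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (x1 in fes$cv1) {
      blk <- td[td$cv1 == x1, ]
      writeLines(sprintf("%.6f %.6f %.8f", blk$cv1, blk$cv2,
                         blk$free_energy), con)
      writeLines("", con)
    }
  }
  invisible(path)
}
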