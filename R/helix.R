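#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the rotation + translation that best maps `mobile` onto `fixed`
#' (row-wise 3D points, proper rotation enforced) and applies it to
#' `apply_to` (default: `mobile` itself).
#'
#' @param mobile,fixed `n x 3` matrices of matched points.
#' @param apply_to coordinates to transform with the fitted motion.
#' @return Transformed coordinates, same shape as `apply_to`.
#' @export
kabsch_superpose <- function(mobile, fixed, apply_to = mobile) {
  stopifnot(nrow(mobile) == nrow(fixed), ncol(mobile) == 3)
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  a <- crossprod(sweep(mobile, 2, cm), sweep(fixed, 2, cf))
  s <- svd(a)
  d <- sign(det(s$u) * det(s$v))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sweep(sweep(apply_to, 2, cm) %*% rot, 2, cf, `+`)
}

#' Fit a helix axis from C-alpha coordinates
#'
#' The axis is initialised as the principal direction (largest-variance
#' singular vector) of the centred C-alpha point set and then refined by a
#' cylinder fit: the direction and axis offset that minimise the variance
#' of the points' radial distances.  On an ideal alpha-helix every
#' C-alpha lies at the same radius, so the refined axis is exact
#' regardless of how many helical turns the span covers, whereas the raw
#' principal direction is exact only for whole turns (it tilts by up to
#' ~2 degrees on partial turns).  The direction is oriented from the
#' first toward the last residue of the span, so a right-handed positive
#' rotation is consistent between frames.
#'
#' @param ca_coords `n x 3` matrix of C-alpha positions (Angstrom), n >= 4.
#' @param method `"cylinder"` (principal direction + radial-variance
#'   refinement, the default) or `"pca"` (principal direction only).
#' @return List with unit `axis` (length-3) and `centroid`.
#' @export
fit_axis <- function(ca_coords, method = c("cylinder", "pca")) {
  method <- match.arg(method)
  ca_coords <- as.matrix(ca_coords)
  if (nrow(ca_coords) < 4) abort("axis fit needs >= 4 C-alpha positions")
  centroid <- colMeans(ca_coords)
  x <- sweep(ca_coords, 2, centroid)
  s <- svd(x, nu = 0, nv = 3)
  if (s$d[1] < 1e-8 || s$d[2] < 1e-8) {
    abort("degenerate C-alpha set: axis undefined")
  }
  axis <- s$v[, 1]
  if (method == "cylinder") {
    # local frame perpendicular to the PCA axis
    e1 <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- e1 - sum(e1 * axis) * axis
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
            axis[3] * e1[1] - axis[1] * e1[3],
            axis[1] * e1[2] - axis[2] * e1[1])
    radial_var <- function(par) {
      u <- axis + par[1] * e1 + par[2] * e2
      u <- u / sqrt(sum(u^2))
      q <- sweep(x, 2, par[3] * e1 + par[4] * e2)
      q <- q - outer(drop(q %*% u), u)
      rho <- sqrt(rowSums(q^2))
      sum((rho - mean(rho))^2)
    }
    o <- stats::optim(c(0, 0, 0, 0), radial_var, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 500))
    axis <- axis + o$par[1] * e1 + o$par[2] * e2
    axis <- axis / sqrt(sum(axis^2))
  }
  span_vec <- ca_coords[nrow(ca_coords), ] - ca_coords[1, ]
  if (sum(axis * span_vec) < 0) axis <- -axis
  list(axis = axis, centroid = centroid)
}

#' Rotation of a helix about its fitted axis, relative to a reference
#'
#' Each C-alpha is projected onto the plane normal to the reference axis;
#' the signed change of its angular coordinate (right-handed about the
#' axis) between reference and frame is averaged with a circular mean.
#' Residues whose projection radius falls below `min_radius_A` in either
#' structure are excluded with a warning (their angle is undefined near
#' the axis).
#'
#' @param frame_ca,ref_ca `n x 3` matched C-alpha coordinates.
#' @param axis optional axis; default: fitted from `ref_ca`.
#' @param min_radius_A exclusion radius for near-axis residues.
#' @return Signed angle in degrees; the reference scores 0.
#' @export
rotation_about_axis <- function(frame_ca, ref_ca, axis = NULL,
                                min_radius_A = 0.5) {
  frame_ca <- as.matrix(frame_ca); ref_ca <- as.matrix(ref_ca)
  stopifnot(nrow(frame_ca) == nrow(ref_ca))
  if (is.null(axis)) axis <- fit_axis(ref_ca)$axis
  axis <- axis / sqrt(sum(axis^2))
  perp <- function(x, centroid) {
    v <- sweep(x, 2, centroid)
    v - outer(drop(v %*% axis), axis)
  }
  r_ref <- perp(ref_ca, colMeans(ref_ca))
  r_frm <- perp(frame_ca, colMeans(frame_ca))
  rad_ref <- sqrt(rowSums(r_ref^2)); rad_frm <- sqrt(rowSums(r_frm^2))
  keep <- rad_ref >= min_radius_A & rad_frm >= min_radius_A
  if (!all(keep)) {
    warn(paste0(sum(!keep), " residue(s) excluded: projection radius < ",
                min_radius_A, " A"))
  }
  if (!any(keep)) abort("no residues with usable projection radius")
  r1 <- r_ref[keep, , drop = FALSE]; r2 <- r_frm[keep, , drop = FALSE]
  crossp <- cbind(r1[, 2] * r2[, 3] - r1[, 3] * r2[, 2],
                  r1[, 3] * r2[, 1] - r1[, 1] * r2[, 3],
                  r1[, 1] * r2[, 2] - r1[, 2] * r2[, 1])
  sin_t <- drop(crossp %*% axis) / (rad_ref[keep] * rad_frm[keep])
  cos_t <- rowSums(r1 * r2) / (rad_ref[keep] * rad_frm[keep])
  ang <- atan2(sin_t, cos_t)
  # circular mean over residues
  atan2(mean(sin(ang)), mean(cos(ang))) * 180 / pi
}

#' Resolve a contiguous helix span to C-alpha atom indices
#'
#' @param top a [topology_map()].
#' @param start_bw,end_bw BW indices bounding the span (same helix,
#'   `end >= start + 3`: at least four residues for a well-posed axis).
#' @return List of class `helix_span`: `start_bw`, `end_bw`, `ca_idx`.
#' @export
helix_span <- function(top, start_bw, end_bw) {
  a <- bw_index(start_bw); b <- bw_index(end_bw)
  if (a$helix != b$helix) abort("helix span must stay within one helix")
  if (b$position - a$position < 3) abort("helix span needs >= 4 residues")
  positions <- sprintf("%d.%d", a$helix, a$position:b$position)
  ca_idx <- vapply(positions, function(bw) select_atom(top, bw, "CA")[1], 1L)
  structure(list(start_bw = a$bw, end_bw = b$bw, ca_idx = unname(ca_idx),
                 label = paste0(a$bw, "-", b$bw)),
            class = "helix_span")
}

#' Named helix-6 span presets
#'
#' The two documented measurement ranges for the extracellular half of
#' helix 6: the short span 6.44-6.50 and the extended span 6.44-6.60.
#'
#' @param top a [topology_map()].
#' @param preset `"6.44-6.50"` or `"6.44-6.60"`.
#' @export
helix6_span <- function(top, preset = c("6.44-6.50", "6.44-6.60")) {
  preset <- match.arg(preset)
  parts <- strsplit(preset, "-")[[1]]
  helix_span(top, parts[1], parts[2])
}

#' Per-frame helix rotation series
#'
#' Measures the rotation of a helix span about its reference axis for
#' every frame.  To remove rigid-body drift each frame is first
#' least-squares superposed onto the reference using a core atom set
#' (every protein C-alpha outside the measured span by default), then the
#' span rotation is measured.  Angles are unwrapped assuming less than 90
#' degrees of change between consecutive frames.
#'
#' @param traj an [md_trajectory()].
#' @param span a [helix_span()] (or integer C-alpha indices).
#' @param reference `n_atoms x 3` reference coordinates (crystal structure
#'   by convention; defaults to the topology reference).
#' @param top optional [topology_map()] supplying `reference` and the core
#'   C-alpha set.
#' @param core_idx atom indices used for pre-alignment; `NULL` disables
#'   alignment (span measured in place).
#' @return Tibble of class `rotation_series`: `time_ps`, `angle_deg`,
#'   `span`.
#' @export
rotation_series <- function(traj, span, reference = NULL, top = NULL,
                            core_idx = NULL, min_radius_A = 0.5) {
  span_idx <- if (inherits(span, "helix_span")) span$ca_idx else as.integer(span)
  label <- if (inherits(span, "helix_span")) span$label else "custom"
  if (is.null(reference)) {
    if (is.null(top) || is.null(top$xyz)) {
      abort("rotation_series needs a reference structure")
    }
    reference <- top$xyz
  }
  reference <- as.matrix(reference)
  stopifnot(ncol(reference) == 3, nrow(reference) == n_atoms(traj))
  if (!is.null(top) && is.null(core_idx)) {
    core_idx <- setdiff(
      top$atoms$atom_index[top$atoms$name == "CA" &
                             !(top$atoms$resname %in% top$water_resnames)],
      span_idx)
  }
  ref_ca <- reference[span_idx, , drop = FALSE]
  ax <- fit_axis(ref_ca)
  angles <- vapply(seq_len(n_frames(traj)), function(i) {
    xyz <- frame_coords(traj, i)
    if (!is.null(core_idx) && length(core_idx) >= 3) {
      xyz <- kabsch_superpose(xyz[core_idx, , drop = FALSE],
                              reference[core_idx, , drop = FALSE],
                              apply_to = xyz)
    }
    rotation_about_axis(xyz[span_idx, , drop = FALSE], ref_ca,
                        axis = ax$axis, min_radius_A = min_radius_A)
  }, numeric(1))
  out <- tibble(time_ps = traj$times,
                angle_deg = unwrap_degrees(angles),
                span = label)
  class(out) <- c("rotation_series", class(out))
  out
}

# make an angle series continuous: consecutive frames are assumed to
# differ by < 90 deg, so any +-360 jump introduced by atan2 is removed
unwrap_degrees <- function(angles) {
  if (length(angles) < 2) return(angles)
  d <- diff(angles)
  d <- d - 360 * round(d / 360)
  cumsum(c(angles[1], d))
}

#' Summary of a rotation series
#' @param x a `rotation_series` tibble.
#' @param ... unused.
#' @return One-row tibble: span, min, max and range of the angle (degrees).
#' @export
glance.rotation_series <- function(x, ...) {
  tibble(span = x$span[1],
         min_deg = min(x$angle_deg), max_deg = max(x$angle_deg),
         range_deg = max(x$angle_deg) - min(x$angle_deg))
}
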