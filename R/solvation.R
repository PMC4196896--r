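#' Water-occupancy grid
#'
#' Counts water-oxygen observations per voxel of a regular 3D grid over
#' all frames.  Normalisations: `raw_counts` (frames x waters per voxel),
#' `per_frame` (mean waters per voxel per frame) and `bulk_relative`
#' (per-frame occupancy divided by the bulk water number density
#' 0.0334 waters per cubic Angstrom times the voxel volume, so 1.0 means
#' bulk-like hydration).
#'
#' @param traj an [md_trajectory()].
#' @param top a [topology_map()] with identified water oxygens.
#' @param origin grid origin (Angstrom, length 3).
#' @param spacing_A voxel edge length (default 1.0).
#' @param dims number of voxels along x, y, z (length 3).
#' @return Object of class `occupancy_grid`: `counts` (3D array),
#'   `origin`, `spacing_A`, `dims`, `n_frames`.
#' @export
water_occupancy <- function(traj, top, origin, dims, spacing_A = 1.0) {
  stopifnot(length(origin) == 3, length(dims) == 3)
  dims <- as.integer(dims)
  if (spacing_A <= 0 || any(dims < 1)) abort("grid must have positive volume")
  widx <- top$water_o_idx
  counts <- array(0L, dims)
  for (i in seq_len(n_frames(traj))) {
    if (length(widx) == 0) break
    xyz <- matrix(traj$coords[i, widx, ], ncol = 3)
    v <- floor(sweep(xyz, 2, origin) / spacing_A) + 1
    ok <- v[, 1] >= 1 & v[, 1] <= dims[1] &
      v[, 2] >= 1 & v[, 2] <= dims[2] &
      v[, 3] >= 1 & v[, 3] <= dims[3]
    if (any(ok)) {
      lin <- (v[ok, 3] - 1) * dims[1] * dims[2] +
        (v[ok, 2] - 1) * dims[1] + v[ok, 1]
      tab <- tabulate(lin, nbins = prod(dims))
      counts <- counts + array(tab, dims)
    }
  }
  structure(list(counts = counts, origin = as.numeric(origin),
                 spacing_A = spacing_A, dims = dims,
                 n_frames = n_frames(traj)),
            class = "occupancy_grid")
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat("<occupancy_grid>", paste(x$dims, collapse = " x "), "voxels,",
      x$spacing_A, "A spacing;", sum(x$counts), "water observations over",
      x$n_frames, "frames\n")
  invisible(x)
}

#' Normalised occupancy values of a grid
#'
#' @param grid an `occupancy_grid`.
#' @param normalization `"raw_counts"`, `"per_frame"` or `"bulk_relative"`.
#' @return 3D array of the normalised occupancy.
#' @export
grid_values <- function(grid, normalization = c("raw_counts", "per_frame",
                                                "bulk_relative")) {
  normalization <- match.arg(normalization)
  switch(normalization,
         raw_counts = grid$counts,
         per_frame = grid$counts / grid$n_frames,
         bulk_relative = grid$counts /
           (grid$n_frames * BULK_WATER_DENSITY * grid$spacing_A^3))
}

#' @rdname grid_values
#' @param x an `occupancy_grid`.
#' @param ... passed on (normalization).
#' @return `tidy()`: a tibble with voxel centres `x`, `y`, `z` (Angstrom)
#'   and `occupancy`.
#' @export
tidy.occupancy_grid <- function(x, ...) {
  vals <- grid_values(x, ...)
  ix <- expand.grid(i = seq_len(x$dims[1]), j = seq_len(x$dims[2]),
                    k = seq_len(x$dims[3]))
  tibble(x = x$origin[1] + (ix$i - 0.5) * x$spacing_A,
         y = x$origin[2] + (ix$j - 0.5) * x$spacing_A,
         z = x$origin[3] + (ix$k - 0.5) * x$spacing_A,
         occupancy = as.vector(vals))
}

#' Export an occupancy grid in OpenDX format
#'
#' Plain-text OpenDX scalar field, readable by common molecular viewers.
#'
#' @inheritParams grid_values
#' @param path output `.dx` path.
#' @export
write_dx <- function(grid, path, normalization = "bulk_relative") {
  vals <- grid_values(grid, normalization)
  d <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.4f %.4f %.4f", grid$origin[1], grid$origin[2],
            grid$origin[3]),
    sprintf("delta %.4f 0 0", grid$spacing_A),
    sprintf("delta 0 %.4f 0", grid$spacing_A),
    sprintf("delta 0 0 %.4f", grid$spacing_A),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # OpenDX runs z fastest
  flat <- as.vector(aperm(vals, c(3, 2, 1)))
  pad <- c(flat, rep(NA_real_, (3 - length(flat) %% 3) %% 3))
  m <- matrix(pad, ncol = 3, byrow = TRUE)
  lines <- apply(m, 1, function(r) paste(sprintf("%.6g", r[!is.na(r)]),
                                         collapse = " "))
  writeLines(lines, con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}

#' Mean number of waters near a residue atom
#'
#' Average over frames of the count of water oxygens within `cutoff_A` of
#' the atom selected by (BW index, role) — e.g. waters within 2 Angstrom
#' of the C-alpha of G5.36.
#'
#' @param traj an [md_trajectory()].
#' @param top a [topology_map()].
#' @param bw BW index of the probe residue.
#' @param atom_role selection role (see [select_atom()]).
#' @param cutoff_A distance cutoff (default 2).
#' @return Mean count per frame (numeric scalar).
#' @export
waters_near <- function(traj, top, bw, atom_role = "CA", cutoff_A = 2.0) {
  probe <- select_atom(top, bw, atom_role)[1]
  widx <- top$water_o_idx
  if (length(widx) == 0) return(0)
  counts <- vapply(seq_len(n_frames(traj)), function(i) {
    d2 <- (traj$coords[i, widx, 1] - traj$coords[i, probe, 1])^2 +
      (traj$coords[i, widx, 2] - traj$coords[i, probe, 2])^2 +
      (traj$coords[i, widx, 3] - traj$coords[i, probe, 3])^2
    sum(d2 <= cutoff_A^2)
  }, numeric(1))
  mean(counts)
}

#' Ligand-residue contact frequencies
#'
#' For every protein residue, the fraction of frames in which any ligand
#' heavy atom comes within `cutoff_A` of any residue heavy atom
#' (hydrogens excluded; a distance exactly at the cutoff counts as a
#' contact).  Residues are returned sorted by descending frequency with
#' their BW index where the numbering table covers them.
#'
#' @param traj an [md_trajectory()].
#' @param top a [topology_map()] with a ligand selection.
#' @param cutoff_A heavy-atom contact cutoff (default 3).
#' @param top_n keep the `top_n` highest-frequency residues (default 10,
#'   the usual binding-pocket report); `Inf` keeps all.
#' @return Tibble of class `contact_table`: `resseq`, `resname`, `bw`,
#'   `frequency`, with attribute `cutoff_A`.
#' @export
contact_frequency <- function(traj, top, cutoff_A = 3.0, top_n = 10) {
  if (length(top$ligand_idx) == 0) abort("topology has no ligand atoms")
  heavy <- top$atoms$element != "H"
  lig <- intersect(top$ligand_idx, which(heavy))
  prot <- top$atoms$atom_index[heavy &
                                 !(top$atoms$resname %in% top$water_resnames)]
  prot <- setdiff(prot, top$ligand_idx)
  if (length(prot) == 0) abort("no protein heavy atoms")
  res_of <- top$atoms$resseq[prot]
  residues <- sort(unique(res_of))
  hit <- matrix(FALSE, n_frames(traj), length(residues))
  for (i in seq_len(n_frames(traj))) {
    lxyz <- matrix(traj$coords[i, lig, ], ncol = 3)
    pxyz <- matrix(traj$coords[i, prot, ], ncol = 3)
    # min distance from each protein atom to any ligand atom
    d2min <- rep(Inf, nrow(pxyz))
    for (l in seq_len(nrow(lxyz))) {
      d2 <- (pxyz[, 1] - lxyz[l, 1])^2 + (pxyz[, 2] - lxyz[l, 2])^2 +
        (pxyz[, 3] - lxyz[l, 3])^2
      d2min <- pmin(d2min, d2)
    }
    in_contact <- d2min <= cutoff_A^2
    hit[i, ] <- vapply(residues,
                       function(r) any(in_contact[res_of == r]),
                       logical(1))
  }
  freq <- colMeans(hit)
  resname <- vapply(residues, function(r) {
    top$atoms$resname[top$atoms$resseq == r &
                        !(top$atoms$resname %in% top$water_resnames)][1]
  }, character(1))
  bw <- rep(NA_character_, length(residues))
  if (!is.null(top$bw)) {
    m <- match(residues, top$bw$resseq)
    bw[!is.na(m)] <- top$bw$bw[m[!is.na(m)]]
  }
  out <- tibble(resseq = residues, resname = resname, bw = bw,
                frequency = freq) %>%
    arrange(desc(.data$frequency), .data$resseq) %>%
    head(n = top_n)
  attr(out, "cutoff_A") <- cutoff_A
  class(out) <- c("contact_table", class(out))
  out
}

#' Ligand RMSD after receptor superposition
#'
#' Each frame is least-squares superposed onto the reference using the
#' receptor C-alpha set; the ligand heavy-atom RMSD is then computed
#' without re-fitting the ligand, so it reports motion of the ligand in
#' the receptor frame (binding-pose stability).
#'
#' @param traj an [md_trajectory()].
#' @param top a [topology_map()] with ligand atoms.
#' @param reference `n_atoms x 3` reference coordinates (defaults to the
#'   topology reference).
#' @return Tibble of class `rmsd_series`: `time_ps`, `rmsd_A`; mean RMSD
#'   via [glance()].
#' @export
ligand_rmsd <- function(traj, top, reference = NULL) {
  if (length(top$ligand_idx) == 0) abort("topology has no ligand atoms")
  if (is.null(reference)) reference <- top$xyz
  if (is.null(reference)) abort("no reference coordinates available")
  reference <- as.matrix(reference)
  if (nrow(reference) != n_atoms(traj)) {
    abort("reference atom count does not match trajectory")
  }
  heavy <- top$atoms$element != "H"
  lig <- intersect(top$ligand_idx, which(heavy))
  ca <- top$atoms$atom_index[top$atoms$name == "CA" &
                               !(top$atoms$resname %in% top$water_resnames)]
  ca <- setdiff(ca, top$ligand_idx)
  if (length(ca) < 3) abort("need >= 3 receptor C-alpha atoms to superpose")
  rmsd <- vapply(seq_len(n_frames(traj)), function(i) {
    xyz <- frame_coords(traj, i)
    fitted <- kabsch_superpose(xyz[ca, , drop = FALSE],
                               reference[ca, , drop = FALSE], apply_to = xyz)
    dev <- fitted[lig, , drop = FALSE] - reference[lig, , drop = FALSE]
    sqrt(mean(rowSums(dev^2)))
  }, numeric(1))
  out <- tibble(time_ps = traj$times, rmsd_A = rmsd)
  class(out) <- c("rmsd_series", class(out))
  out
}

#' @rdname ligand_rmsd
#' @param x an `rmsd_series`.
#' @param ... unused.
#' @export
glance.rmsd_series <- function(x, ...) {
  tibble(n_frames = nrow(x), mean_rmsd_A = mean(x$rmsd_A),
         max_rmsd_A = max(x$rmsd_A))
}
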