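#' Trajectory container
#'
#' Holds ordered frame coordinates as an `n_frames x n_atoms x 3` array in
#' Angstrom, frame times in ps (strictly increasing) and an optional
#' replicate id.  All readers normalise to these units regardless of the
#' source format.
#'
#' @param coords numeric array `n_frames x n_atoms x 3` (Angstrom), or an
#'   `n_atoms x 3` matrix for a single frame.
#' @param times numeric vector of frame times (ps); defaults to
#'   `0, dt, 2 dt, ...`.
#' @param dt_ps frame spacing used when `times` is not given.
#' @param box optional box vectors (Angstrom).
#' @param replicate replicate identifier carried into tidy outputs.
#' @return A list of class `md_trajectory`.
#' @export
md_trajectory <- function(coords, times = NULL, dt_ps = 1,
                          box = NULL, replicate = 1L) {
  if (is.matrix(coords)) coords <- array(coords, c(1L, dim(coords)))
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (dim(coords)[1] < 1L) abort("trajectory needs at least one frame")
  if (!all(is.finite(coords))) abort("trajectory coordinates must be finite")
  n <- dim(coords)[1]
  if (is.null(times)) times <- (seq_len(n) - 1) * dt_ps
  if (length(times) != n) abort("length(times) must equal n_frames")
  if (n > 1L && any(diff(times) <= 0)) {
    abort("frame times must be strictly increasing")
  }
  structure(list(coords = coords, times = as.numeric(times), box = box,
                 replicate = replicate),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat("<md_trajectory>", d[1], "frames x", d[2], "atoms; t =",
      x$times[1], "...", x$times[d[1]], "ps; replicate",
      as.character(x$replicate), "\n")
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]
n_atoms <- function(traj) dim(traj$coords)[2]

#' Extract one frame as an `n_atoms x 3` matrix
#' @param traj an [md_trajectory()].
#' @param i frame number (1-based).
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  matrix(traj$coords[i, , ], ncol = 3)
}

#' Read a trajectory from disk
#'
#' Supports multi-model PDB (`MODEL`/`ENDMDL` blocks) and CHARMM/NAMD
#' binary DCD (read with \pkg{bio3d}).  Coordinates are returned in
#' Angstrom and times in ps; sources that carry no time axis get
#' `0, dt_ps, ...`.  XTC is not supported by the installed readers and is
#' rejected with an explicit error.
#'
#' @param source path to a `.pdb` or `.dcd` file.
#' @param top optional [topology_map()]; when given, the atom count of
#'   every frame must match it.
#' @inheritParams md_trajectory
#' @return An [md_trajectory()].
#' @export
read_trajectory <- function(source, top = NULL, dt_ps = 1, replicate = 1L,
                            times = NULL) {
  ext <- tolower(tools::file_ext(source))
  if (ext == "xtc") {
    abort("XTC input is not supported; convert to DCD or multi-model PDB")
  }
  if (ext == "dcd") {
    xyz <- bio3d::read.dcd(source, verbose = FALSE)
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    coords <- xyz_to_array(xyz)
  } else {
    pdb <- bio3d::read.pdb(source, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    coords <- xyz_to_array(xyz)
  }
  if (!is.null(top) && dim(coords)[2] != nrow(top$atoms)) {
    abort(paste0("atom count mismatch: trajectory has ", dim(coords)[2],
                 ", topology has ", nrow(top$atoms)))
  }
  md_trajectory(coords, times = times, dt_ps = dt_ps, replicate = replicate)
}

#' Write a trajectory to disk
#'
#' Multi-model PDB (plain text) or CHARMM-format DCD.  The DCD writer emits
#' little-endian Fortran unformatted records readable by standard MD
#' tooling; `read_trajectory()` (via `bio3d::read.dcd`) round-trips it
#' within single-precision.
#'
#' @param traj an [md_trajectory()].
#' @param path output path; format chosen by extension (`.pdb` or `.dcd`).
#' @param top optional [topology_map()] supplying atom/residue names for
#'   PDB output; placeholder carbons are written without it.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, top = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "dcd") {
    write_dcd(traj, path)
  } else {
    write_multimodel_pdb(traj, path, top = top)
  }
  invisible(path)
}

# bio3d-style xyz matrix (n_frames x 3N, x1 y1 z1 x2 ...) -> array
xyz_to_array <- function(xyz) {
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3L
  arr <- array(NA_real_, c(nf, na, 3L))
  for (k in 1:3) arr[, , k] <- xyz[, seq(k, by = 3L, length.out = na), drop = FALSE]
  arr
}

array_to_xyz <- function(coords) {
  nf <- dim(coords)[1]; na <- dim(coords)[2]
  xyz <- matrix(NA_real_, nf, 3L * na)
  for (k in 1:3) xyz[, seq(k, by = 3L, length.out = na)] <- coords[, , k]
  xyz
}

write_multimodel_pdb <- function(traj, path, top = NULL) {
  na <- n_atoms(traj)
  if (!is.null(top)) {
    stopifnot(nrow(top$atoms) == na)
    an <- top$atoms$name; rn <- top$atoms$resname; rs <- top$atoms$resseq
    el <- top$atoms$element
  } else {
    an <- rep("C", na); rn <- rep("UNK", na); rs <- seq_len(na)
    el <- rep("C", na)
  }
  # PDB fixed columns: name left-padded to 4 starting in col 13 (short
  # names get a leading blank)
  fmt_name <- ifelse(nchar(an) >= 4, substr(an, 1, 4), sprintf(" %-3s", an))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", i), con)
    xyz <- frame_coords(traj, i)
    writeLines(sprintf(
      "ATOM  %5d %s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(na) %% 100000L, fmt_name, substr(rn, 1, 3), rs %% 10000L,
      xyz[, 1], xyz[, 2], xyz[, 3], el), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# CHARMM-format DCD: 84-byte control record, title record, natom record,
# then one float record per coordinate axis per frame.
write_dcd <- function(traj, path, dt_ps = NULL) {
  nf <- n_frames(traj); na <- n_atoms(traj)
  if (is.null(dt_ps)) {
    dt_ps <- if (nf > 1) diff(traj$times)[1] else 1
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wrec <- function(writer) {
    # fortran unformatted record: length prefix/suffix around payload
    raw_con <- rawConnection(raw(0), "wb")
    writer(raw_con)
    payload <- rawConnectionValue(raw_con)
    close(raw_con)
    writeBin(length(payload), con, size = 4, endian = "little")
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4, endian = "little")
  }
  wrec(function(c2) {
    writeBin(charToRaw("CORD"), c2)
    writeBin(as.integer(c(nf, 1L, 1L, nf, 0L, 0L, 0L, 3L * na, 0L)), c2,
             size = 4, endian = "little")
    writeBin(dt_ps / 0.04888821, c2, size = 4, endian = "little")  # AKMA time
    writeBin(integer(9), c2, size = 4, endian = "little")
    writeBin(as.integer(c(24L)), c2, size = 4, endian = "little")  # CHARMM tag
  })
  wrec(function(c2) {
    writeBin(1L, c2, size = 4, endian = "little")
    writeBin(charToRaw(sprintf("%-80s", "written by microswitchr")), c2)
  })
  wrec(function(c2) writeBin(as.integer(na), c2, size = 4, endian = "little"))
  for (i in seq_len(nf)) {
    xyz <- frame_coords(traj, i)
    for (k in 1:3) {
      wrec(function(c2) writeBin(xyz[, k], c2, size = 4, endian = "little"))
    }
  }
  invisible(path)
}
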