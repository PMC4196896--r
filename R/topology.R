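#' Topology map: atoms, BW numbering, ligand and solvent selections
#'
#' A `topology_map` ties together an atom table, a Ballesteros-Weinstein
#' lookup table, reference coordinates and the ligand / water-oxygen
#' selections every analysis selects atoms through.  `load_topology()`
#' builds one from a PDB file (via \pkg{bio3d}); `topology_map()` builds one
#' from an in-memory atom tibble (used by the synthetic generators).
#'
#' Waters are detected by residue name (`HOH`, `WAT`, `TIP3`, `SOL` by
#' default) keeping the oxygen atom only.  Ligands are detected by an
#' explicit residue-name set.  Atom indices are 1-based row numbers of the
#' atom table.
#'
#' @param atoms tibble with columns `name`, `resname`, `resseq`, `element`
#'   (element may be `NA`; it is then inferred from the atom name).
#' @param bw a [bw_table()] whose entries must all resolve to at least one
#'   atom, or `NULL` when no protein numbering applies.
#' @param xyz optional reference coordinates, `n_atoms x 3` matrix (Angstrom).
#' @param ligand_resnames residue names treated as the ligand.
#' @param water_resnames residue names treated as water.
#' @param receptor receptor label carried through to outputs.
#' @return A list of class `topology_map` with elements `atoms` (tibble,
#'   plus `atom_index`), `bw`, `xyz`, `ligand_idx`, `water_o_idx`,
#'   `receptor`.
#' @export
topology_map <- function(atoms, bw = NULL, xyz = NULL,
                         ligand_resnames = character(),
                         water_resnames = c("HOH", "WAT", "TIP3", "SOL"),
                         receptor = NA_character_) {
  atoms <- as_tibble(atoms)
  stopifnot(all(c("name", "resname", "resseq") %in% names(atoms)))
  if (!"element" %in% names(atoms)) atoms$element <- NA_character_
  atoms <- atoms %>%
    mutate(name = toupper(.data$name),
           resname = toupper(.data$resname),
           resseq = as.integer(.data$resseq),
           element = ifelse(is.na(.data$element) | .data$element == "",
                            substr(gsub("[0-9']", "", .data$name), 1, 1),
                            toupper(.data$element)),
           atom_index = row_number())
  if (!is.null(xyz)) {
    xyz <- as.matrix(xyz)
    stopifnot(nrow(xyz) == nrow(atoms), ncol(xyz) == 3)
  }
  ligand_idx <- which(atoms$resname %in% toupper(ligand_resnames))
  water_o_idx <- which(atoms$resname %in% toupper(water_resnames) &
                         atoms$element == "O")
  top <- structure(
    list(atoms = atoms, bw = bw, xyz = xyz,
         ligand_idx = ligand_idx, water_o_idx = water_o_idx,
         water_resnames = toupper(water_resnames),
         receptor = receptor),
    class = "topology_map")
  if (!is.null(bw)) {
    stopifnot(inherits(bw, "bw_table"))
    for (i in seq_len(nrow(bw))) {
      n_at <- sum(atoms$resseq == bw$resseq[i] &
                    !(atoms$resname %in% top$water_resnames))
      if (n_at == 0L) {
        abort(paste0("BW anchor ", bw$bw[i], " (resseq ", bw$resseq[i],
                     ") has no atoms in the topology"))
      }
    }
  }
  top
}

#' @rdname topology_map
#' @param pdb_source path to a PDB file.
#' @param bw_table_source a [bw_table()] or path to a BW TSV
#'   (columns `bw_index`, `resseq`, `resname`).
#' @export
load_topology <- function(pdb_source, bw_table_source = NULL,
                          ligand_resnames = character(),
                          water_resnames = c("HOH", "WAT", "TIP3", "SOL"),
                          receptor = NA_character_) {
  pdb <- bio3d::read.pdb(pdb_source, verbose = FALSE)
  at <- pdb$atom
  atoms <- tibble(name = at$elety, resname = at$resid,
                  resseq = as.integer(at$resno),
                  element = if ("elesy" %in% names(at)) at$elesy else NA)
  xyz <- cbind(at$x, at$y, at$z)
  bw <- bw_table_source
  if (is.character(bw)) bw <- read_bw_table(bw, receptor = receptor)
  topology_map(atoms, bw = bw, xyz = xyz,
               ligand_resnames = ligand_resnames,
               water_resnames = water_resnames, receptor = receptor)
}

#' @export
print.topology_map <- function(x, ...) {
  cat("<topology_map>", nrow(x$atoms), "atoms;",
      if (is.null(x$bw)) "no BW table" else paste(nrow(x$bw), "BW entries"),
      ";", length(x$ligand_idx), "ligand atoms;",
      length(x$water_o_idx), "water oxygens\n")
  invisible(x)
}

# atom-name sets per selection role; names are PDB v3 conventions
.role_spec <- list(
  CA = list(names = "CA", resnames = NULL, multi = FALSE),
  # "C-4" of the Phe ring: the para ring carbon, PDB name CZ
  # (ring numbering C1 = CG ... C4 = CZ from the attachment carbon)
  ring_C4 = list(names = "CZ", resnames = "PHE", multi = FALSE),
  arg_CE = list(names = "CE", resnames = "ARG", multi = FALSE),
  glu_CD = list(names = "CD", resnames = "GLU", multi = FALSE),
  tyr_OH = list(names = "OH", resnames = "TYR", multi = FALSE),
  carboxylate_O_pair = list(names = c("OD1", "OD2", "OE1", "OE2"),
                            resnames = c("ASP", "GLU"), multi = TRUE),
  guanidinium_N_set = list(names = c("NE", "NH1", "NH2"),
                           resnames = "ARG", multi = TRUE)
)

#' Select atoms of a residue by Ballesteros-Weinstein index and role
#'
#' Deterministically maps a (BW index, chemical role) pair to atom indices
#' of the topology.  Roles restricted to a residue type (for example
#' `arg_CE`) raise an error when the residue at that position is of another
#' type, so a mutation such as F6.41L is caught rather than silently
#' mismeasured.
#'
#' @param top a [topology_map()].
#' @param bw a BW index string, e.g. `"6.44"`.
#' @param atom_role one of `"CA"`, `"ring_C4"`, `"arg_CE"`, `"glu_CD"`,
#'   `"tyr_OH"`, `"carboxylate_O_pair"`, `"guanidinium_N_set"`.
#' @return Integer vector of atom indices (length 1 for single-atom roles).
#' @examples
#' \dontrun{select_atom(top, "3.50", "arg_CE")}
#' @export
select_atom <- function(top, bw, atom_role) {
  stopifnot(inherits(top, "topology_map"))
  if (is.null(top$bw)) abort("topology has no BW table")
  atom_role <- match.arg(atom_role, names(.role_spec))
  spec <- .role_spec[[atom_role]]
  resseq <- bw_resolve(top$bw, bw)
  res_at <- top$atoms %>%
    filter(.data$resseq == !!resseq,
           !(.data$resname %in% top$water_resnames))
  if (nrow(res_at) == 0L) {
    abort(paste0("no atoms for BW ", bw, " (resseq ", resseq, ")"))
  }
  restype <- res_at$resname[1]
  if (!is.null(spec$resnames) && !restype %in% spec$resnames) {
    abort(paste0("role ", atom_role, " not applicable to residue ",
                 restype, resseq, " at BW ", bw))
  }
  idx <- res_at$atom_index[res_at$name %in% spec$names]
  if (length(idx) == 0L) {
    abort(paste0("residue ", restype, resseq, " at BW ", bw,
                 " has no atom named ", paste(spec$names, collapse = "/")))
  }
  if (!spec$multi && length(idx) > 1L) idx <- idx[1]
  sort(idx)
}
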