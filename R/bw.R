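#' Ballesteros-Weinstein generic residue indices
#'
#' GPCR residues are addressed by the generic Ballesteros-Weinstein (BW)
#' scheme `H.PP`: helix number `H` (1-8) and a position `PP` relative to the
#' most conserved residue of that helix, which is defined as position 50.
#' `bw_index()` parses one or more `"H.PP"` strings into a validated tibble;
#' `format()` on that tibble round-trips the string form.
#'
#' @param x character vector of BW indices, e.g. `c("6.44", "3.50")`.
#' @return A tibble with integer columns `helix` and `position` and the
#'   canonical string form in `bw`.
#' @examples
#' bw_index(c("6.44", "5.50"))
#' @export
bw_index <- function(x) {
  stopifnot(is.character(x) | is.numeric(x))
  x <- as.character(x)
  m <- regmatches(x, regexec("^([1-8])\\.([0-9]{1,2})$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    abort(paste0("not a valid Ballesteros-Weinstein index: ",
                 paste(x[bad], collapse = ", ")))
  }
  helix <- vapply(m, function(g) as.integer(g[2]), 1L)
  position <- vapply(m, function(g) as.integer(g[3]), 1L)
  if (any(position < 1L | position > 99L)) {
    abort("BW position must be in [1, 99]")
  }
  tibble(bw = sprintf("%d.%d", helix, position),
         helix = helix, position = position)
}

#' Build or read a Ballesteros-Weinstein lookup table
#'
#' A BW table maps generic indices to the residue sequence numbers (and
#' names) of one receptor.  Within a helix, PDB sequence numbers must run
#' parallel to the BW positions (consecutive numbering: the offset
#' `resseq - position` is constant per helix), and no BW index may appear
#' twice.  Both invariants are checked on construction.
#'
#' @param bw character vector of BW indices (`"H.PP"`).
#' @param resseq integer vector of residue sequence numbers (author/PDB
#'   numbering).
#' @param resname character vector of three-letter residue names.
#' @param receptor optional receptor label, e.g. `"5-HT2B"`.
#' @return A tibble of class `bw_table` with columns `bw`, `helix`,
#'   `position`, `resseq`, `resname` and attribute `receptor`.
#' @examples
#' bw_table(c("5.36", "5.37", "5.50"), c(215, 216, 229),
#'          c("GLY", "ASP", "PRO"), receptor = "5-HT2B")
#' @export
bw_table <- function(bw, resseq, resname, receptor = NA_character_) {
  idx <- bw_index(bw)
  stopifnot(length(resseq) == nrow(idx), length(resname) == nrow(idx))
  tab <- idx %>%
    mutate(resseq = as.integer(resseq),
           resname = toupper(as.character(resname)))
  if (anyDuplicated(tab$bw) > 0) {
    abort(paste0("duplicate BW index in table: ",
                 paste(unique(tab$bw[duplicated(tab$bw)]), collapse = ", ")))
  }
  # consecutive numbering: within a helix resseq - position is constant
  offsets <- tab %>%
    group_by(.data$helix) %>%
    summarise(n_off = length(unique(.data$resseq - .data$position)),
              .groups = "drop")
  if (any(offsets$n_off != 1L)) {
    bad <- offsets$helix[offsets$n_off != 1L]
    abort(paste0("BW table violates consecutive numbering in helix ",
                 paste(bad, collapse = ", "),
                 ": resseq(p2) - resseq(p1) must equal p2 - p1"))
  }
  tab <- arrange(tab, .data$helix, .data$position)
  attr(tab, "receptor") <- receptor
  class(tab) <- c("bw_table", class(tab))
  tab
}

#' @rdname bw_table
#' @param path TSV file with columns `bw_index`, `resseq`, `resname`.
#' @export
read_bw_table <- function(path, receptor = NA_character_) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    bw_index = readr::col_character(),
    resseq = readr::col_integer(),
    resname = readr::col_character()
  ))
  bw_table(raw$bw_index, raw$resseq, raw$resname, receptor = receptor)
}

#' @rdname bw_table
#' @param tab a `bw_table`.
#' @export
write_bw_table <- function(tab, path) {
  stopifnot(inherits(tab, "bw_table"))
  readr::write_tsv(
    tibble(bw_index = tab$bw, resseq = tab$resseq, resname = tab$resname),
    path)
  invisible(path)
}

#' Resolve a BW index to a residue sequence number
#'
#' Exact entries are looked up directly; positions missing from the table
#' but bracketed by entries of the same helix are filled in by the
#' consecutive-numbering rule (constant `resseq - position` offset).
#'
#' @param tab a [bw_table()].
#' @param bw a single BW index string.
#' @return Integer residue sequence number.
#' @export
bw_resolve <- function(tab, bw) {
  stopifnot(inherits(tab, "bw_table"))
  q <- bw_index(bw)
  if (nrow(q) != 1L) abort("bw_resolve() takes a single BW index")
  hit <- tab[tab$bw == q$bw, ]
  if (nrow(hit) == 1L) return(hit$resseq)
  same <- tab[tab$helix == q$helix, ]
  if (nrow(same) == 0L) {
    abort(paste0("BW index ", q$bw, " unresolvable: no helix ", q$helix,
                 " anchor in table"))
  }
  same$resseq[1] + (q$position - same$position[1])
}
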