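#' Enumerate candidate restraints between two pre-aligned molecules
#'
#' A candidate restraint is a cross-molecule atom pair whose inter-atom
#' distance in the common (pre-aligned) frame is at most `d_res`. By default
#' only ring atoms are eligible, since restraining flexible atoms would
#' distort conformational sampling; bond-free molecules bypass the ring
#' filter. Each candidate is represented by the midpoint of its two atoms,
#' which becomes a node of the selection graph.
#'
#' @param mol_a,mol_b Two [molecule()] objects in a common frame.
#' @param d_res Distance cutoff in nm (default 0.1).
#' @param restrict_to_rings Restrict eligible atoms to ring atoms when bond
#'   information is available (default `TRUE`).
#' @return A tibble of class `rst_candidates`, one row per candidate, in
#'   ascending (`atom_id_a`, `atom_id_b`) order, with midpoint coordinates
#'   (`mx`, `my`, `mz`) and `pair_distance` in nm. Molecule ids, atom counts
#'   and `d_res` are carried as attributes.
#' @export
candidate_restraints <- function(mol_a, mol_b, d_res = 0.1, restrict_to_rings = TRUE) {
  stopifnot(inherits(mol_a, "rst_molecule"), inherits(mol_b, "rst_molecule"))
  if (identical(mol_a$molecule_id, mol_b$molecule_id)) {
    rst_abort("candidate generation needs two distinct molecules", "rst_input_error")
  }
  if (d_res <= 0) rst_abort("d_res must be positive", "rst_input_error")
  ea <- eligible_atoms(mol_a, restrict_to_rings)
  eb <- eligible_atoms(mol_b, restrict_to_rings)
  grid <- tidyr::expand_grid(ia = seq_len(nrow(ea)), ib = seq_len(nrow(eb)))
  dx <- ea$x[grid$ia] - eb$x[grid$ib]
  dy <- ea$y[grid$ia] - eb$y[grid$ib]
  dz <- ea$z[grid$ia] - eb$z[grid$ib]
  dist <- sqrt(dx^2 + dy^2 + dz^2)
  keep <- dist <= d_res
  cand <- tibble::tibble(
    atom_id_a = ea$atom_id[grid$ia][keep],
    name_a = ea$name[grid$ia][keep],
    element_a = ea$element[grid$ia][keep],
    xa = ea$x[grid$ia][keep], ya = ea$y[grid$ia][keep], za = ea$z[grid$ia][keep],
    atom_id_b = eb$atom_id[grid$ib][keep],
    name_b = eb$name[grid$ib][keep],
    element_b = eb$element[grid$ib][keep],
    xb = eb$x[grid$ib][keep], yb = eb$y[grid$ib][keep], zb = eb$z[grid$ib][keep],
    pair_distance = dist[keep]
  )
  cand$mx <- (cand$xa + cand$xb) / 2
  cand$my <- (cand$ya + cand$yb) / 2
  cand$mz <- (cand$za + cand$zb) / 2
  cand <- dplyr::arrange(cand, .data$atom_id_a, .data$atom_id_b)
  new_candidates(cand,
    molecule_pair = c(mol_a$molecule_id, mol_b$molecule_id),
    n_atoms = c(nrow(mol_a$atoms), nrow(mol_b$atoms)),
    d_res = d_res
  )
}

new_candidates <- function(tbl, molecule_pair, n_atoms, d_res) {
  structure(
    tbl,
    molecule_pair = molecule_pair,
    n_atoms = n_atoms,
    d_res = d_res,
    class = c("rst_candidates", class(tibble::as_tibble(tbl)))
  )
}

midpoints_of <- function(candidates) {
  cbind(candidates$mx, candidates$my, candidates$mz)
}

# candidates i and j conflict when they share an atom on either molecule
conflict_matrix <- function(candidates) {
  a <- candidates$atom_id_a
  b <- candidates$atom_id_b
  outer(a, a, "==") | outer(b, b, "==")
}
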