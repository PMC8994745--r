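#' Generate a random two-entity toy system
#'
#' Emulates the validation setting for the restraint selector: `n_particles`
#' labelled points are placed i.i.d. uniformly inside a cube and split at
#' random into two balanced entities standing in for two strongly
#' overlapping, pre-aligned molecules. The entities carry no bonds, so ring
#' filtering is bypassed and every particle is an eligible restraint atom.
#'
#' The default box edge of 0.2 nm makes the clouds overlap strongly on the
#' scale of the default 0.1 nm restraint cutoff, so that a 12-particle
#' system typically yields around ten candidate pairs and brute-force
#' enumeration stays tractable up to 30 particles.
#'
#' @param n_particles Total particle count (>= 8 recommended for four
#'   atom-disjoint restraints).
#' @param seed Integer seed; the system is fully reproducible from it.
#' @param box_edge Edge of the sampling cube in nm (default 0.2).
#' @return A list of two bond-free [molecule()] objects (`"A"`, `"B"`) with
#'   attributes `n_particles`, `seed`, `box_edge`.
#' @export
toy_system <- function(n_particles, seed, box_edge = 0.2) {
  if (n_particles < 2) rst_abort("need at least 2 particles", "rst_input_error")
  if (box_edge <= 0) rst_abort("box_edge must be positive", "rst_input_error")
  if (n_particles < 8) {
    rst_warn("fewer than 8 particles: four atom-disjoint restraints may be infeasible",
             "rst_small_system_warning")
  }
  mols <- withr::with_seed(as.integer(seed), {
    pos <- matrix(stats::runif(3 * n_particles, 0, box_edge), ncol = 3)
    n_a <- floor(n_particles / 2)
    if (n_particles %% 2 == 1 && stats::runif(1) < 0.5) n_a <- n_a + 1L
    in_a <- sort(sample.int(n_particles, n_a))
    make_entity <- function(rows, id) {
      molecule(
        tibble::tibble(
          atom_id = seq_along(rows), element = "X",
          name = paste0("X", seq_along(rows)),
          x = pos[rows, 1], y = pos[rows, 2], z = pos[rows, 3]
        ),
        bonds = NULL, molecule_id = id
      )
    }
    list(make_entity(in_a, "A"), make_entity(setdiff(seq_len(n_particles), in_a), "B"))
  })
  structure(mols, n_particles = n_particles, seed = as.integer(seed),
            box_edge = box_edge, class = c("rst_toy_system", "list"))
}

#' Generate an ensemble of aligned synthetic molecules
#'
#' Produces `n_molecules` bond-free point clouds sharing a common template:
#' each molecule is the template cloud plus isotropic Gaussian jitter. This
#' mimics a series of pre-aligned end-states whose every pair overlaps, as
#' needed to exercise multi-state ring construction.
#'
#' @param n_molecules Number of molecules (>= 3 for ring building).
#' @param n_atoms Atoms per molecule (default 10).
#' @param seed Integer seed.
#' @param box_edge Edge of the template sampling cube in nm (default 0.3).
#' @param jitter Standard deviation of the per-atom displacement in nm
#'   (default 0.01, well inside the default 0.1 nm cutoff).
#' @return A list of [molecule()] objects with ids `"m01"`, `"m02"`, ...
#' @export
toy_ensemble <- function(n_molecules, n_atoms = 10, seed = 1, box_edge = 0.3,
                         jitter = 0.01) {
  if (n_molecules < 2) rst_abort("need at least 2 molecules", "rst_input_error")
  withr::with_seed(as.integer(seed), {
    template <- matrix(stats::runif(3 * n_atoms, 0, box_edge), ncol = 3)
    purrr::map(seq_len(n_molecules), function(i) {
      pos <- template + matrix(stats::rnorm(3 * n_atoms, 0, jitter), ncol = 3)
      molecule(
        tibble::tibble(
          atom_id = seq_len(n_atoms), element = "X",
          name = paste0("X", seq_len(n_atoms)),
          x = pos[, 1], y = pos[, 2], z = pos[, 3]
        ),
        bonds = NULL, molecule_id = sprintf("m%02d", i)
      )
    })
  })
}
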