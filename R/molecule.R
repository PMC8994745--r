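#' Construct a molecule
#'
#' A molecule is a set of atoms with 3-D coordinates in nm and an optional
#' bond list. Bonds drive ring perception, which restricts the restraint
#' search space to conformationally rigid atoms; bond-free molecules (toy
#' particle clouds) bypass ring filtering entirely.
#'
#' @param atoms A data frame with columns `atom_id` (positive integers,
#'   unique), `x`, `y`, `z` (nm) and optionally `element` and `name`.
#' @param bonds A data frame with columns `from`, `to` (atom ids), or `NULL`
#'   for a bond-free molecule.
#' @param molecule_id Identifier of the molecule (coerced to character).
#' @return An object of class `rst_molecule`.
#' @export
molecule <- function(atoms, bonds = NULL, molecule_id = "mol") {
  atoms <- tibble::as_tibble(atoms)
  if (nrow(atoms) < 1L) rst_abort("molecule must contain at least one atom", "rst_empty_input")
  if (!all(c("x", "y", "z") %in% names(atoms))) {
    rst_abort("atoms need x, y, z columns (nm)", "rst_input_error")
  }
  if (!"atom_id" %in% names(atoms)) atoms$atom_id <- seq_len(nrow(atoms))
  if (!"element" %in% names(atoms)) atoms$element <- "X"
  if (!"name" %in% names(atoms)) atoms$name <- paste0(atoms$element, atoms$atom_id)
  atoms <- atoms[, c("atom_id", "element", "name", "x", "y", "z")]
  atoms$atom_id <- as.integer(atoms$atom_id)
  if (anyDuplicated(atoms$atom_id) || any(atoms$atom_id < 1L)) {
    rst_abort("atom_id must be unique positive integers", "rst_input_error")
  }
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    rst_abort("atom coordinates must be finite", "rst_input_error")
  }
  if (!is.null(bonds) && nrow(as.data.frame(bonds)) > 0L) {
    bonds <- tibble::as_tibble(as.data.frame(bonds))
    names(bonds)[1:2] <- c("from", "to")
    bonds <- tibble::tibble(
      from = pmin(as.integer(bonds$from), as.integer(bonds$to)),
      to   = pmax(as.integer(bonds$from), as.integer(bonds$to))
    )
    bonds <- dplyr::distinct(bonds)
    if (any(bonds$from == bonds$to)) rst_abort("bond endpoints must differ", "rst_input_error")
    if (!all(c(bonds$from, bonds$to) %in% atoms$atom_id)) {
      rst_abort("bond references an unknown atom_id", "rst_input_error")
    }
  } else {
    bonds <- tibble::tibble(from = integer(), to = integer())
  }
  mol <- structure(
    list(molecule_id = as.character(molecule_id), atoms = atoms, bonds = bonds),
    class = "rst_molecule"
  )
  mol$ring_atom_ids <- ring_atoms(mol)
  mol
}

#' @export
print.rst_molecule <- function(x, ...) {
  cat(sprintf(
    "<rst_molecule '%s': %d atoms, %d bonds, %d ring atoms>\n",
    x$molecule_id, nrow(x$atoms), nrow(x$bonds), length(x$ring_atom_ids)
  ))
  print(x$atoms, n = 5)
  invisible(x)
}

#' Atoms lying on a ring of the bond graph
#'
#' Returns the atoms that lie on at least one simple cycle of the bond
#' graph, i.e. the endpoints of non-bridge edges (the 2-edge-connected
#' core). Fused and bridged ring systems are therefore fully included.
#' An acyclic or bond-free molecule yields an empty set.
#'
#' @param mol An `rst_molecule`.
#' @return Sorted integer vector of atom ids.
#' @export
ring_atoms <- function(mol) {
  bonds <- mol$bonds
  if (is.null(bonds) || nrow(bonds) == 0L) return(integer())
  g <- igraph::graph_from_edgelist(
    cbind(as.character(bonds$from), as.character(bonds$to)),
    directed = FALSE
  )
  br <- igraph::bridges(g)
  keep <- igraph::E(g)[setdiff(seq_len(igraph::ecount(g)), as.integer(br))]
  if (length(keep) == 0L) return(integer())
  ids <- unique(as.integer(names(igraph::V(g))[unique(as.vector(igraph::ends(g, keep, names = FALSE)))]))
  sort(ids)
}

coords <- function(mol) {
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

eligible_atoms <- function(mol, restrict_to_rings = TRUE) {
  if (!restrict_to_rings) return(mol$atoms)
  if (nrow(mol$bonds) == 0L) {
    rst_warn(sprintf(
      "molecule '%s' has no bond information; ring filtering bypassed, all atoms eligible",
      mol$molecule_id
    ), "rst_no_bonds_warning")
    return(mol$atoms)
  }
  mol$atoms[mol$atoms$atom_id %in% mol$ring_atom_ids, , drop = FALSE]
}

#' Read molecular structures
#'
#' Reads pre-aligned small-molecule structures from SDF (V2000), PDB
#' (ATOM/HETATM + CONECT) or a plain whitespace toy format
#' (`entity_id atom_id x y z`, coordinates already in nm). PDB and SDF
#' coordinates are converted from Angstrom to nm. Atoms are renumbered
#' contiguously from 1 preserving file order; multi-record SDF files and
#' multi-model PDB files yield one molecule per record/model.
#'
#' @param path Path to the structure file.
#' @param format One of `"auto"`, `"pdb"`, `"sdf"`, `"toy"`. `"auto"` keys
#'   on the file extension.
#' @return A list of [molecule()] objects.
#' @export
read_structures <- function(path, format = c("auto", "pdb", "sdf", "toy")) {
  format <- match.arg(format)
  if (!file.exists(path)) rst_abort(sprintf("file not found: %s", path), "rst_input_error")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      pdb = "pdb", ent = "pdb", sdf = "sdf", sd = "sdf", mol = "sdf",
      "toy"
    )
  }
  switch(format,
    sdf = read_sdf_molecules(path),
    pdb = read_pdb_molecules(path),
    toy = read_toy_molecules(path)
  )
}

read_sdf_molecules <- function(path) {
  sdfs <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(path)),
    error = function(e) rst_abort(sprintf("cannot parse SDF '%s': %s", path, conditionMessage(e)), "rst_format_error")
  )
  ids <- ChemmineR::sdfid(sdfs)
  records <- unname(ChemmineR::SDFset2SDF(sdfs))
  purrr::map(seq_along(records), function(i) {
    sdf <- records[[i]]
    ab <- ChemmineR::atomblock(sdf)
    if (nrow(ab) < 1L) rst_abort(sprintf("SDF record %s has no atoms", i), "rst_empty_input")
    elem <- sub("_.*$", "", rownames(ab))
    atoms <- tibble::tibble(
      atom_id = seq_len(nrow(ab)),
      element = elem,
      name = paste0(elem, seq_len(nrow(ab))),
      x = unname(ab[, 1]) * 0.1, y = unname(ab[, 2]) * 0.1, z = unname(ab[, 3]) * 0.1
    )
    bb <- ChemmineR::bondblock(sdf)
    bonds <- if (is.matrix(bb) && nrow(bb) > 0L) {
      tibble::tibble(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]))
    } else NULL
    mid <- ids[i]
    if (is.na(mid) || !nzchar(mid)) mid <- paste0("sdf_", i)
    molecule(atoms, bonds, molecule_id = mid)
  })
}

read_pdb_molecules <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) rst_abort(sprintf("cannot parse PDB '%s': %s", path, conditionMessage(e)), "rst_format_error")
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) < 1L) rst_abort(sprintf("PDB '%s' has no atoms", path), "rst_empty_input")
  elem <- trimws(at$elesy)
  elem[is.na(elem) | !nzchar(elem)] <- substr(trimws(at$elety[is.na(elem) | !nzchar(elem)]), 1, 1)
  serial_to_id <- stats::setNames(seq_len(nrow(at)), at$eleno)
  bonds <- read_pdb_conect(path, serial_to_id)
  n_models <- max(1L, nrow(pdb$xyz))
  base <- tools::file_path_sans_ext(basename(path))
  lapply(seq_len(n_models), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE)
    atoms <- tibble::tibble(
      atom_id = seq_len(nrow(at)),
      element = elem,
      name = trimws(at$elety),
      x = xyz[, 1] * 0.1, y = xyz[, 2] * 0.1, z = xyz[, 3] * 0.1
    )
    mid <- if (n_models > 1L) sprintf("%s_model%d", base, m) else base
    molecule(atoms, bonds, molecule_id = mid)
  })
}

# CONECT records are not exposed by bio3d; extract the serial lists directly.
read_pdb_conect <- function(path, serial_to_id) {
  lines <- grep("^CONECT", readLines(path, warn = FALSE), value = TRUE)
  if (length(lines) == 0L) return(NULL)
  pairs <- purrr::map(lines, function(ln) {
    f <- suppressWarnings(as.integer(strsplit(trimws(sub("^CONECT", "", ln)), "\\s+")[[1]]))
    f <- f[!is.na(f)]
    if (length(f) < 2L) return(NULL)
    cbind(f[1], f[-1])
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) return(NULL)
  known <- pairs[, 1] %in% names(serial_to_id) & pairs[, 2] %in% names(serial_to_id)
  pairs <- pairs[known, , drop = FALSE]
  if (nrow(pairs) == 0L) return(NULL)
  tibble::tibble(
    from = unname(serial_to_id[as.character(pairs[, 1])]),
    to = unname(serial_to_id[as.character(pairs[, 2])])
  )
}

read_toy_molecules <- function(path) {
  df <- tryCatch(
    utils::read.table(path, header = FALSE, comment.char = "#",
                      col.names = c("entity_id", "atom_id", "x", "y", "z")),
    error = function(e) rst_abort(sprintf("cannot parse toy file '%s': %s", path, conditionMessage(e)), "rst_format_error")
  )
  if (nrow(df) < 1L) rst_abort(sprintf("toy file '%s' is empty", path), "rst_empty_input")
  split(df, df$entity_id) |>
    purrr::imap(function(d, id) {
      molecule(
        tibble::tibble(
          atom_id = seq_len(nrow(d)), element = "X",
          name = paste0("X", seq_len(nrow(d))),
          x = d$x, y = d$y, z = d$z
        ),
        bonds = NULL, molecule_id = id
      )
    }) |>
    unname()
}

#' Write molecules in the plain toy point-cloud format
#'
#' One line per atom: `entity_id atom_id x y z`, coordinates in nm.
#'
#' @param molecules A list of [molecule()] objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_toy <- function(molecules, path) {
  if (inherits(molecules, "rst_molecule")) molecules <- list(molecules)
  lines <- purrr::map(molecules, function(m) {
    sprintf("%s %d %.9f %.9f %.9f", m$molecule_id, m$atoms$atom_id,
            m$atoms$x, m$atoms$y, m$atoms$z)
  })
  writeLines(unlist(lines), path)
  invisible(path)
}
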