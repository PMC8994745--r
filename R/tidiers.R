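#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a restraint set
#'
#' @param x An `rst_restraint_set`.
#' @param ... Unused.
#' @return A tibble with one row per selected restraint: selection `step`,
#'   the two atoms, the inter-atom distance and the midpoint coordinates.
#' @export
tidy.rst_restraint_set <- function(x, ...) {
  mol <- attr(x, "molecule_pair") %||% c(NA_character_, NA_character_)
  tibble::tibble(
    step = x$step,
    mol_a = mol[1], atom_id_a = x$atom_id_a, name_a = x$name_a,
    mol_b = mol[2], atom_id_b = x$atom_id_b, name_b = x$name_b,
    pair_distance = x$pair_distance,
    mx = x$mx, my = x$my, mz = x$mz
  )
}

#' One-row summary of a restraint set
#'
#' @param x An `rst_restraint_set`.
#' @param ... Unused.
#' @return A one-row tibble with the number of restraints, the sum of
#'   midpoint distances (nm) and the convex-hull volume (nm^3), recomputed
#'   from the stored midpoints.
#' @export
glance.rst_restraint_set <- function(x, ...) {
  sc <- score_restraints(x)
  mol <- attr(x, "molecule_pair") %||% c(NA_character_, NA_character_)
  tibble::tibble(
    mol_a = mol[1], mol_b = mol[2],
    n_restraints = nrow(x),
    sum_midpoint_distance = sc$sum_midpoint_distance,
    chv = sc$chv,
    d_res = attr(x, "d_res") %||% NA_real_
  )
}

#' Tidy a multi-state restraint ring
#'
#' @param x An `rst_ring`.
#' @param ... Unused.
#' @return A tibble with one row per ring edge (closure edge last), its
#'   molecule pair, restraint count and metrics.
#' @export
tidy.rst_ring <- function(x, ...) {
  purrr::imap(x$edge_sets, function(s, nm) {
    g <- glance(s)
    g$edge <- nm
    g$is_closure <- identical(sort(c(g$mol_a, g$mol_b)), x$closure_pair)
    g
  }) |>
    purrr::list_rbind() |>
    dplyr::relocate("edge")
}

#' One-row summary of a multi-state restraint ring
#'
#' @param x An `rst_ring`.
#' @param ... Unused.
#' @return A one-row tibble: molecule count, total restraints, and the
#'   minimum/mean CHV over ring edges.
#' @export
glance.rst_ring <- function(x, ...) {
  ed <- tidy(x)
  tibble::tibble(
    n_molecules = length(x$order),
    n_edges = nrow(ed),
    n_restraints = sum(ed$n_restraints),
    min_chv = min(ed$chv),
    mean_chv = mean(ed$chv),
    closure_pair = paste(x$closure_pair, collapse = "-")
  )
}
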