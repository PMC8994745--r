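#' Greedy max-min selection of distance restraints
#'
#' Selects up to `n_res` atom-disjoint restraints from a candidate table
#' with a max-min dispersion scheme on the graph of restraint midpoints:
#'
#' 1. the pair of candidates with the largest midpoint separation is taken
#'    first (two restraints at once);
#' 2. candidates sharing an atom with the selection are removed;
#' 3. each survivor is weighted by its minimal midpoint distance to the
#'    selection, and the candidate with the largest weight is added;
#' 4. steps 2-3 repeat until `n_res` restraints are selected or no
#'    candidates remain.
#'
#' When several top weights lie within `tie_tolerance` of the best, the
#' candidate farthest from the centre of geometry (COG) of the selected
#' midpoints wins; residual exact ties fall back to ascending
#' (`atom_id_a`, `atom_id_b`). The initial pair is maximised exactly; ties
#' at the exact maximum are broken by proximity of the pair's own COG to
#' the COG of all candidate midpoints, then lexicographically.
#'
#' @param candidates An `rst_candidates` table from [candidate_restraints()].
#' @param n_res Number of restraints to select (default 4).
#' @param tie_tolerance Width of the tie window on the min-distance weights,
#'   in nm (default 0.02).
#' @return An `rst_restraint_set`: the selected candidate rows with a `step`
#'   column giving selection order, plus metric attributes
#'   (`sum_midpoint_distance` in nm, `chv` in nm^3).
#' @export
select_restraints <- function(candidates, n_res = 4, tie_tolerance = 0.02) {
  candidates <- check_candidates(candidates)
  if (n_res < 1) rst_abort("n_res must be >= 1", "rst_input_error")
  m <- nrow(candidates)
  if (m == 0L) {
    rst_abort(
      "no candidate restraints: increase d_res or improve the alignment",
      "rst_no_candidates_error"
    )
  }
  M <- midpoints_of(candidates)
  if (m == 1L) return(new_restraint_set(candidates, sel = 1L))

  D <- as.matrix(stats::dist(M))
  conf <- conflict_matrix(candidates)
  eps <- sqrt(.Machine$double.eps)

  w <- D
  w[conf | lower.tri(w, diag = TRUE)] <- -Inf
  if (!any(is.finite(w))) {
    # every candidate pair shares an atom: at most one restraint is feasible
    rst_warn("all candidates share atoms; returning a single restraint", "rst_short_set_warning")
    return(new_restraint_set(candidates, sel = 1L))
  }
  best <- max(w)
  tied <- which(w >= best - eps, arr.ind = TRUE)
  if (nrow(tied) > 1L) {
    g <- colMeans(M)
    pair_cog_d <- sqrt(rowSums((cbind(
      (M[tied[, 1], 1] + M[tied[, 2], 1]) / 2 - g[1],
      (M[tied[, 1], 2] + M[tied[, 2], 2]) / 2 - g[2],
      (M[tied[, 1], 3] + M[tied[, 2], 3]) / 2 - g[3]
    ))^2))
    ord <- order(pair_cog_d, pmin(tied[, 1], tied[, 2]), pmax(tied[, 1], tied[, 2]))
    tied <- tied[ord[1], , drop = FALSE]
  }
  sel <- sort(c(tied[1, 1], tied[1, 2]))
  if (n_res == 1L) sel <- sel[1L]

  while (length(sel) < n_res) {
    in_conflict <- Reduce(`|`, lapply(sel, function(s) conf[, s]))
    remaining <- which(!in_conflict)
    if (length(remaining) == 0L) break
    wr <- apply(D[remaining, sel, drop = FALSE], 1, min)
    top <- max(wr)
    tied_idx <- remaining[wr >= top - tie_tolerance]
    pick <- if (length(tied_idx) > 1L) break_tie_idx(tied_idx, M, sel) else tied_idx
    sel <- c(sel, pick)
  }
  if (length(sel) < n_res) {
    rst_warn(sprintf(
      "only %d of %d requested restraints are feasible under atom-disjointness",
      length(sel), n_res
    ), "rst_short_set_warning")
  }
  new_restraint_set(candidates, sel = sel)
}

break_tie_idx <- function(tied_idx, M, sel) {
  g <- colMeans(M[sel, , drop = FALSE])
  d <- sqrt(rowSums(sweep(M[tied_idx, , drop = FALSE], 2, g)^2))
  # farthest from the selected-set COG; residual ties -> lowest candidate
  # index, which is ascending (atom_id_a, atom_id_b) by construction
  tied_idx[order(-d, tied_idx)][1L]
}

#' Resolve a tie between candidate restraints
#'
#' Among tied candidates, returns the one whose midpoint is farthest from
#' the COG of the already-selected restraint midpoints; residual exact ties
#' are broken by ascending (`atom_id_a`, `atom_id_b`).
#'
#' @param tied An `rst_candidates` (or compatible) table of tied candidates.
#' @param selected An `rst_restraint_set` with at least one restraint.
#' @return The single winning candidate row.
#' @export
break_tie <- function(tied, selected) {
  if (nrow(tied) < 1L) rst_abort("no tied candidates", "rst_input_error")
  if (nrow(selected) < 1L) rst_abort("need at least one selected restraint", "rst_input_error")
  tied <- dplyr::arrange(tibble::as_tibble(tied), .data$atom_id_a, .data$atom_id_b)
  g <- colMeans(midpoints_of(selected))
  d <- sqrt((tied$mx - g[1])^2 + (tied$my - g[2])^2 + (tied$mz - g[3])^2)
  tied[order(-d, tied$atom_id_a, tied$atom_id_b)[1L], , drop = FALSE]
}

new_restraint_set <- function(candidates, sel) {
  rows <- tibble::as_tibble(candidates)[sel, , drop = FALSE]
  rows$step <- seq_along(sel)
  M <- cbind(rows$mx, rows$my, rows$mz)
  structure(
    rows,
    molecule_pair = attr(candidates, "molecule_pair"),
    n_atoms = attr(candidates, "n_atoms"),
    d_res = attr(candidates, "d_res"),
    sum_midpoint_distance = if (nrow(rows) > 1L) sum(stats::dist(M)) else 0,
    chv = if (nrow(rows) >= 1L) convex_hull_volume(M) else 0,
    class = c("rst_restraint_set", class(tibble::as_tibble(rows)))
  )
}

#' Recompute the quality metrics of a restraint set
#'
#' @param set An `rst_restraint_set`.
#' @return A named list with `sum_midpoint_distance` (nm), the sum of
#'   midpoint distances over all unordered restraint pairs, and `chv`
#'   (nm^3), the convex-hull volume of the midpoints.
#' @export
score_restraints <- function(set) {
  if (nrow(set) < 1L) rst_abort("restraint set is empty", "rst_input_error")
  M <- midpoints_of(set)
  list(
    sum_midpoint_distance = if (nrow(set) > 1L) sum(stats::dist(M)) else 0,
    chv = convex_hull_volume(M)
  )
}

# validate and put candidates in canonical ascending (atom_id_a, atom_id_b)
# order so that selection is invariant to the input row ordering
check_candidates <- function(candidates) {
  need <- c("atom_id_a", "atom_id_b", "mx", "my", "mz", "pair_distance")
  if (!all(need %in% names(candidates))) {
    rst_abort("not a candidate-restraint table (see candidate_restraints())", "rst_input_error")
  }
  ord <- order(candidates$atom_id_a, candidates$atom_id_b)
  new_candidates(
    tibble::as_tibble(candidates)[ord, , drop = FALSE],
    molecule_pair = attr(candidates, "molecule_pair"),
    n_atoms = attr(candidates, "n_atoms"),
    d_res = attr(candidates, "d_res")
  )
}
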