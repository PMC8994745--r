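#' Pairwise restraint sets for a collection of aligned molecules
#'
#' Runs candidate generation and greedy selection for every unordered pair
#' of molecules, building the weighted graph used for multi-state chaining:
#' each feasible pair gets a restraint set and a weight equal to the
#' convex-hull volume (CHV) of its restraint midpoints. Pairs producing no
#' candidates are omitted (absent edges, not zero-weight edges).
#'
#' @param molecules A list of at least three [molecule()] objects in a
#'   common frame.
#' @inheritParams select_restraints
#' @inheritParams candidate_restraints
#' @return A tibble of class `rst_pair_matrix` with columns `mol_a`,
#'   `mol_b`, `n_candidates`, `n_restraints`, `chv` and a list-column `set`
#'   holding the `rst_restraint_set` of each pair.
#' @export
pair_matrix <- function(molecules, n_res = 4, d_res = 0.1, tie_tolerance = 0.02,
                        restrict_to_rings = TRUE) {
  ids <- purrr::map_chr(molecules, "molecule_id")
  if (length(molecules) < 3L) rst_abort("need at least 3 molecules", "rst_input_error")
  if (anyDuplicated(ids)) rst_abort("molecule ids must be unique", "rst_input_error")
  pairs <- utils::combn(length(molecules), 2L)
  rows <- purrr::map(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    cand <- candidate_restraints(molecules[[i]], molecules[[j]], d_res = d_res,
                                 restrict_to_rings = restrict_to_rings)
    if (nrow(cand) == 0L) return(NULL)
    set <- suppressWarnings(select_restraints(cand, n_res = n_res,
                                              tie_tolerance = tie_tolerance))
    tibble::tibble(
      mol_a = ids[i], mol_b = ids[j],
      n_candidates = nrow(cand), n_restraints = nrow(set),
      chv = attr(set, "chv"), set = list(set)
    )
  })
  out <- purrr::list_rbind(purrr::compact(rows))
  structure(out, molecule_ids = ids, n_res = n_res, d_res = d_res,
            tie_tolerance = tie_tolerance,
            class = c("rst_pair_matrix", class(out)))
}

#' Chain molecules into a maximum-weight open path
#'
#' Kruskal-style greedy construction of a branchless maximum spanning tree:
#' edges are visited by descending CHV weight (ties lexicographic on the
#' molecule-id pair) and accepted unless an endpoint already has two
#' neighbours or the edge would close a cycle before all molecules are
#' connected. The result is a Hamiltonian path over the molecule set.
#'
#' If the greedy order dead-ends (possible on adversarial weight patterns),
#' an exhaustive search over Hamiltonian paths maximising total weight is
#' used for up to 8 molecules; larger stuck instances raise a chaining
#' error.
#'
#' @param pairs An `rst_pair_matrix`, or any data frame with columns
#'   `mol_a`, `mol_b`, `chv`.
#' @return Character vector of molecule ids (the path), with attribute
#'   `accepted_weights` giving the weights in acceptance order.
#' @export
chain_molecules <- function(pairs) {
  edges <- tibble::as_tibble(pairs)[, c("mol_a", "mol_b", "chv")]
  ids <- attr(pairs, "molecule_ids") %||% sort(unique(c(edges$mol_a, edges$mol_b)))
  m_tot <- length(ids)
  if (m_tot < 3L) rst_abort("need at least 3 molecules to chain", "rst_input_error")
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    rst_abort(sprintf(
      "pair graph is disconnected; isolated group(s): %s",
      paste(ids[comp$membership != comp$membership[1]], collapse = ", ")
    ), "rst_chaining_error")
  }
  edges <- edges[order(-edges$chv, edges$mol_a, edges$mol_b), ]
  parent <- stats::setNames(ids, ids)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  degree <- stats::setNames(integer(m_tot), ids)
  accepted <- integer(0)
  for (k in seq_len(nrow(edges))) {
    a <- edges$mol_a[k]; b <- edges$mol_b[k]
    if (degree[[a]] >= 2L || degree[[b]] >= 2L) next
    ra <- find(a); rb <- find(b)
    if (ra == rb) next # would close a cycle before spanning
    parent[[ra]] <- rb
    degree[[a]] <- degree[[a]] + 1L
    degree[[b]] <- degree[[b]] + 1L
    accepted <- c(accepted, k)
    if (length(accepted) == m_tot - 1L) break
  }
  if (length(accepted) < m_tot - 1L) {
    path <- exhaustive_chain(edges, ids)
    if (is.null(path)) {
      rst_abort(sprintf(
        "greedy chaining dead-ended with %d of %d edges and no Hamiltonian path exists (or > 8 molecules)",
        length(accepted), m_tot - 1L
      ), "rst_chaining_error")
    }
    attr(path, "accepted_weights") <- path_weights(path, edges)
    return(path)
  }
  path <- walk_path(edges[accepted, ], ids)
  attr(path, "accepted_weights") <- edges$chv[accepted]
  path
}

walk_path <- function(acc_edges, ids) {
  adj <- split(c(acc_edges$mol_b, acc_edges$mol_a), c(acc_edges$mol_a, acc_edges$mol_b))
  deg <- lengths(adj)
  endpoints <- sort(names(deg)[deg == 1L])
  cur <- endpoints[1L]
  path <- cur
  prev <- ""
  while (length(path) < length(ids)) {
    nxt <- setdiff(adj[[cur]], prev)[1L]
    prev <- cur
    cur <- nxt
    path <- c(path, cur)
  }
  path
}

path_weights <- function(path, edges) {
  purrr::map_dbl(seq_len(length(path) - 1L), function(i) {
    a <- min(path[i], path[i + 1L]); b <- max(path[i], path[i + 1L])
    hit <- edges$chv[edges$mol_a == a & edges$mol_b == b]
    if (length(hit) == 0L) NA_real_ else hit[1L]
  })
}

# exact fallback: all Hamiltonian paths over available edges, max total weight
exhaustive_chain <- function(edges, ids) {
  if (length(ids) > 8L) return(NULL)
  w <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(edges))) {
    assign(paste(edges$mol_a[k], edges$mol_b[k], sep = "|"), edges$chv[k], envir = w)
  }
  edge_w <- function(a, b) {
    key <- paste(min(a, b), max(a, b), sep = "|")
    if (exists(key, envir = w)) get(key, envir = w) else NA_real_
  }
  best <- NULL; best_w <- -Inf
  perms <- all_permutations(sort(ids))
  for (p in perms) {
    ws <- purrr::map_dbl(seq_len(length(p) - 1L), function(i) edge_w(p[i], p[i + 1L]))
    if (anyNA(ws)) next
    tot <- sum(ws)
    if (tot > best_w + 1e-15) { best_w <- tot; best <- p }
  }
  best
}

all_permutations <- function(x) {
  if (length(x) == 1L) return(list(x))
  purrr::list_flatten(purrr::map(seq_along(x), function(i) {
    purrr::map(all_permutations(x[-i]), function(rest) c(x[i], rest))
  }))
}

#' Close a molecule chain into a restraint ring
#'
#' Adds the edge between the two endpoints of a Hamiltonian path so that
#' every molecule is restrained to exactly two neighbours. The endpoint
#' pair reuses its precomputed restraint set when available; otherwise it
#' is computed afresh, retrying once with the distance cutoff doubled. This
#' closure pair may carry the weakest restraint set of the ring.
#'
#' @param path Character vector of molecule ids from [chain_molecules()].
#' @param pairs The `rst_pair_matrix` the chain was built from.
#' @param molecules Optional list of [molecule()] objects, needed only when
#'   the closure pair is absent from `pairs`.
#' @return An object of class `rst_ring`: list with `order` (cyclic id
#'   sequence), `edge_sets` (one `rst_restraint_set` per adjacent pair,
#'   closure last) and `closure_pair`.
#' @export
close_ring <- function(path, pairs, molecules = NULL) {
  ids <- attr(pairs, "molecule_ids") %||% sort(unique(c(pairs$mol_a, pairs$mol_b)))
  if (!setequal(path, ids) || anyDuplicated(path)) {
    rst_abort("path must visit every molecule exactly once", "rst_input_error")
  }
  ends <- c(path[length(path)], path[1L])
  get_set <- function(a, b) {
    lo <- min(a, b); hi <- max(a, b)
    hit <- which(pairs$mol_a == lo & pairs$mol_b == hi)
    if (length(hit) == 1L) pairs$set[[hit]] else NULL
  }
  closure_set <- get_set(ends[1L], ends[2L])
  if (is.null(closure_set)) {
    if (is.null(molecules)) {
      rst_abort("closure pair has no precomputed set; supply `molecules`", "rst_ring_closure_error")
    }
    mols <- stats::setNames(molecules, purrr::map_chr(molecules, "molecule_id"))
    d_res <- attr(pairs, "d_res") %||% 0.1
    n_res <- attr(pairs, "n_res") %||% 4
    closure_set <- tryCatch(
      compute_pair_set(mols[[ends[1L]]], mols[[ends[2L]]], n_res, d_res),
      rst_error = function(e) NULL
    )
    if (is.null(closure_set)) {
      # the closure pair may be the worst-aligned pair; relax the cutoff once
      closure_set <- tryCatch(
        compute_pair_set(mols[[ends[1L]]], mols[[ends[2L]]], n_res, 2 * d_res),
        rst_error = function(e) NULL
      )
    }
    if (is.null(closure_set)) {
      rst_abort(sprintf(
        "cannot close ring: no candidates between '%s' and '%s' even at doubled d_res",
        ends[1L], ends[2L]
      ), "rst_ring_closure_error")
    }
  }
  edge_sets <- purrr::map(seq_len(length(path) - 1L), function(i) {
    s <- get_set(path[i], path[i + 1L])
    if (is.null(s)) rst_abort(sprintf(
      "missing restraint set for chain edge %s-%s", path[i], path[i + 1L]
    ), "rst_input_error")
    s
  })
  edge_sets <- c(edge_sets, list(closure_set))
  names(edge_sets) <- c(
    paste(path[-length(path)], path[-1L], sep = "-"),
    paste(ends[1L], ends[2L], sep = "-")
  )
  structure(
    list(order = path, edge_sets = edge_sets, closure_pair = sort(ends)),
    class = "rst_ring"
  )
}

compute_pair_set <- function(mol_a, mol_b, n_res, d_res) {
  cand <- candidate_restraints(mol_a, mol_b, d_res = d_res, restrict_to_rings = FALSE)
  suppressWarnings(select_restraints(cand, n_res = n_res))
}

#' Select a multi-state restraint ring
#'
#' End-to-end wrapper: pairwise greedy selections ([pair_matrix()]),
#' CHV-weighted branchless maximum spanning chain ([chain_molecules()]),
#' and ring closure ([close_ring()]).
#'
#' @inheritParams pair_matrix
#' @return An `rst_ring`.
#' @export
select_ring <- function(molecules, n_res = 4, d_res = 0.1, tie_tolerance = 0.02,
                        restrict_to_rings = TRUE) {
  pm <- pair_matrix(molecules, n_res = n_res, d_res = d_res,
                    tie_tolerance = tie_tolerance,
                    restrict_to_rings = restrict_to_rings)
  path <- chain_molecules(pm)
  close_ring(path, pm, molecules = molecules)
}

#' @export
print.rst_ring <- function(x, ...) {
  cat(sprintf("<rst_ring: %d molecules>\n", length(x$order)))
  cat("order:", paste(c(x$order, x$order[1L]), collapse = " - "), "\n")
  cat("closure pair:", paste(x$closure_pair, collapse = " - "), "\n")
  invisible(x)
}
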