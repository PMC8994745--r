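# Fixture builders shared across test files. All geometry is constructed in
# code; no binary fixtures.

coords_of <- function(mol) {
  unname(as.matrix(mol$atoms[, c("x", "y", "z")]))
}

make_mol <- function(coords, bonds = NULL, id = "mol") {
  coords <- matrix(coords, ncol = 3, byrow = FALSE)
  molecule(
    tibble::tibble(
      atom_id = seq_len(nrow(coords)),
      x = coords[, 1], y = coords[, 2], z = coords[, 3]
    ),
    bonds = bonds, molecule_id = id
  )
}

# regular hexagon of edge `edge` in the xy plane, optionally with an
# exocyclic substituent atom, with ring bonds
benzene_mol <- function(id = "bz", edge = 0.14, substituent = TRUE) {
  ang <- 2 * pi * (0:5) / 6
  r <- edge # circumradius equals edge for a regular hexagon
  coords <- cbind(r * cos(ang), r * sin(ang), 0)
  bonds <- data.frame(from = 1:6, to = c(2:6, 1))
  if (substituent) {
    coords <- rbind(coords, c(2 * r, 0, 0))
    bonds <- rbind(bonds, data.frame(from = 1, to = 7))
  }
  make_mol(coords, bonds, id)
}

# candidates whose midpoints sit at the given x positions, pairwise
# atom-disjoint: both molecules have an atom at each position, and a small
# cutoff admits only the coincident identity pairs
line_candidates <- function(xs, d_res = 0.01) {
  a <- make_mol(cbind(xs, 0, 0), id = "A")
  b <- make_mol(cbind(xs, 0, 0), id = "B")
  suppressWarnings(candidate_restraints(a, b, d_res = d_res))
}

# candidates with midpoints at arbitrary 3-D points (identity pairs)
point_candidates <- function(pts, d_res = 1e-6) {
  pts <- matrix(pts, ncol = 3, byrow = FALSE)
  a <- make_mol(pts, id = "A")
  b <- make_mol(pts, id = "B")
  suppressWarnings(candidate_restraints(a, b, d_res = d_res))
}

random_toy_candidates <- function(n_particles, seed, box_edge = 0.2, d_res = 0.1) {
  sys <- toy_system(n_particles, seed = seed, box_edge = box_edge)
  candidate_restraints(sys[[1]], sys[[2]], d_res = d_res, restrict_to_rings = FALSE)
}

# independent oracle: all simple cycles of a small undirected graph by DFS,
# returning the union of cycle vertices
cycle_atoms_bruteforce <- function(n_atoms, bonds) {
  adj <- lapply(seq_len(n_atoms), function(i) {
    sort(unique(c(bonds$to[bonds$from == i], bonds$from[bonds$to == i])))
  })
  on_cycle <- rep(FALSE, n_atoms)
  walk <- function(start, current, visited) {
    for (nb in adj[[current]]) {
      if (nb == start && length(visited) >= 3) {
        on_cycle[visited] <<- TRUE
      } else if (!(nb %in% visited) && nb > start) {
        walk(start, nb, c(visited, nb))
      }
    }
  }
  for (s in seq_len(n_atoms)) walk(s, s, s)
  which(on_cycle)
}

# independent oracle: exhaustive max-weight selection over all atom-disjoint
# k-subsets, plain loops (no shared code with the package implementation)
bf_oracle <- function(cand, k, objective = c("distance", "chv")) {
  objective <- match.arg(objective)
  m <- nrow(cand)
  subsets <- utils::combn(m, k, simplify = FALSE)
  best <- NULL
  best_score <- -Inf
  for (s in subsets) {
    if (anyDuplicated(cand$atom_id_a[s]) || anyDuplicated(cand$atom_id_b[s])) next
    pts <- cbind(cand$mx[s], cand$my[s], cand$mz[s])
    score <- if (objective == "distance") sum(dist(pts)) else convex_hull_volume(pts)
    if (score > best_score + 1e-12) {
      best_score <- score
      best <- s
    }
  }
  list(subset = best, score = best_score)
}

# independent oracle: best Hamiltonian path by total weight over explicit
# permutation enumeration
hamiltonian_best_path <- function(edges) {
  ids <- sort(unique(c(edges$mol_a, edges$mol_b)))
  wt <- function(a, b) {
    hit <- edges$chv[(edges$mol_a == a & edges$mol_b == b) |
                     (edges$mol_a == b & edges$mol_b == a)]
    if (length(hit)) hit[1] else NA_real_
  }
  perms <- function(x) {
    if (length(x) == 1) return(list(x))
    unlist(lapply(seq_along(x), function(i) {
      lapply(perms(x[-i]), function(r) c(x[i], r))
    }), recursive = FALSE)
  }
  best <- NULL; best_w <- -Inf
  for (p in perms(ids)) {
    ws <- mapply(wt, p[-length(p)], p[-1])
    if (anyNA(ws)) next
    if (sum(ws) > best_w + 1e-12) { best_w <- sum(ws); best <- p }
  }
  list(path = best, weight = best_w)
}

sdf_fixture_text <- function() {
  # two V2000 records: a 4-atom ring + substituent (5 atoms) and a 3-atom chain
  c(
    "ring_mol", "  test", "",
    "  5  5  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.0000    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "  2  3  1  0  0  0  0",
    "  3  4  1  0  0  0  0",
    "  4  1  1  0  0  0  0",
    "  2  5  1  0  0  0  0",
    "M  END",
    "$$$$",
    "chain_mol", "  test", "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    3.0000    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "  2  3  1  0  0  0  0",
    "M  END",
    "$$$$"
  )
}

pdb_fixture_text <- function() {
  c(
    "ATOM      1  C1  LIG A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  C2  LIG A   1       2.400   2.000   3.000  1.00  0.00           C",
    "ATOM      3  C3  LIG A   1       2.400   3.400   3.000  1.00  0.00           C",
    "ATOM      4  C4  LIG A   1       1.000   3.400   3.000  1.00  0.00           C",
    "ATOM      5  O1  LIG A   1       3.800   2.000   3.000  1.00  0.00           O",
    "CONECT    1    2    4",
    "CONECT    2    3    5",
    "CONECT    3    4",
    "END"
  )
}
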