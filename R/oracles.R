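#' Brute-force restraint selection oracles
#'
#' Exhaustive reference selectors that enumerate every `n_res`-subset of the
#' candidates and return the atom-disjoint subset maximising either the sum
#' of midpoint distances (`bf_max_distance`, "BF-maxD") or the convex-hull
#' volume of the midpoints (`bf_max_chv`, "BF-maxCHV"). Both scale as
#' O(N^4) for four restraints, which is what makes the greedy selector
#' necessary for real molecules; a subset cap guards against accidental
#' combinatorial blow-up.
#'
#' Ties are broken lexicographically on the subsets' sorted atom-id tuples.
#' The exact number of enumerated subsets, `choose(m, n_res)`, is attached
#' as attribute `n_enumerated`.
#'
#' @param candidates An `rst_candidates` table.
#' @param n_res Subset size (default 4).
#' @param cap Maximum number of subsets to enumerate (default 2e6).
#' @return An `rst_restraint_set` (selection order = lexicographic).
#' @export
bf_max_distance <- function(candidates, n_res = 4, cap = 2e6) {
  bf_enumerate(candidates, n_res, objective = "distance", cap = cap)
}

#' @rdname bf_max_distance
#' @export
bf_max_chv <- function(candidates, n_res = 4, cap = 2e6) {
  bf_enumerate(candidates, n_res, objective = "chv", cap = cap)
}

# all k-subsets of 1..m as columns, in lexicographic order (vectorised
# equivalent of utils::combn(m, k) indices, much faster for large counts)
enumerate_subsets <- function(m, k) {
  m <- as.integer(m); k <- as.integer(k)
  idx <- matrix(seq_len(m - k + 1L), nrow = 1L)
  for (row in seq_len(k - 1L)) {
    last <- idx[nrow(idx), ]
    cnt <- (m - (k - row - 1L)) - last
    rep_idx <- rep.int(seq_len(ncol(idx)), cnt)
    nxt <- sequence(cnt) + rep.int(last, cnt)
    idx <- rbind(idx[, rep_idx, drop = FALSE], nxt)
  }
  unname(idx)
}

bf_enumerate <- function(candidates, n_res, objective, cap) {
  candidates <- check_candidates(candidates)
  m <- nrow(candidates)
  if (m < n_res) {
    rst_abort(sprintf("only %d candidates for %d restraints", m, n_res), "rst_infeasible_error")
  }
  n_subsets <- choose(m, n_res)
  if (n_subsets > cap) {
    rst_abort(sprintf(
      "brute force would enumerate %.0f subsets of m = %d candidates (cap %.0f); brute-force approaches scale as O(N^%d)",
      n_subsets, m, cap, n_res
    ), "rst_complexity_error")
  }
  idx <- enumerate_subsets(m, n_res)
  K <- ncol(idx)
  conf <- conflict_matrix(candidates)
  pr <- utils::combn(n_res, 2L)
  feas <- rep(TRUE, K)
  for (col in seq_len(ncol(pr))) {
    feas <- feas & !conf[cbind(idx[pr[1, col], ], idx[pr[2, col], ])]
  }
  if (!any(feas)) {
    rst_abort("no atom-disjoint subset of the requested size exists", "rst_infeasible_error")
  }
  M <- midpoints_of(candidates)
  score <- rep(-Inf, K)
  if (objective == "distance") {
    D <- as.matrix(stats::dist(M))
    s <- rep(0, K)
    for (col in seq_len(ncol(pr))) {
      s <- s + D[cbind(idx[pr[1, col], ], idx[pr[2, col], ])]
    }
    score[feas] <- s[feas]
  } else if (n_res == 4L) {
    # hull of 4 points is a tetrahedron: |det| / 6, vectorised over subsets
    v1 <- M[idx[2, ], ] - M[idx[1, ], ]
    v2 <- M[idx[3, ], ] - M[idx[1, ], ]
    v3 <- M[idx[4, ], ] - M[idx[1, ], ]
    cx <- v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]
    cy <- v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3]
    cz <- v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1]
    vol <- abs(v1[, 1] * cx + v1[, 2] * cy + v1[, 3] * cz) / 6
    score[feas] <- vol[feas]
  } else {
    for (k in which(feas)) {
      score[k] <- convex_hull_volume(M[idx[, k], , drop = FALSE])
    }
  }
  # combn emits subsets in lexicographic order of candidate indices, which is
  # lexicographic in sorted atom-id tuples; the first maximum is the tie rule
  best <- which.max(score)
  out <- new_restraint_set(candidates, sel = idx[, best])
  attr(out, "n_enumerated") <- n_subsets
  out
}

#' Random baseline selection of restraints
#'
#' Draws `trials` atom-disjoint `n_res`-subsets uniformly at random by
#' rejection sampling, as a negative control for the greedy selector.
#'
#' @inheritParams bf_max_distance
#' @param trials Number of random selections (default 100).
#' @param seed Optional integer seed; the draw sequence is reproducible.
#' @param max_reject Rejections allowed per trial before declaring the
#'   instance infeasible (default 1e4).
#' @return A list of `rst_restraint_set` objects of length `trials`.
#' @export
random_restraints <- function(candidates, n_res = 4, trials = 100, seed = NULL,
                              max_reject = 1e4) {
  candidates <- check_candidates(candidates)
  if (trials < 1) rst_abort("trials must be >= 1", "rst_input_error")
  m <- nrow(candidates)
  if (m < n_res) {
    rst_abort(sprintf("only %d candidates for %d restraints", m, n_res), "rst_infeasible_error")
  }
  conf <- conflict_matrix(candidates)
  pr <- utils::combn(n_res, 2L)
  draw_one <- function() {
    for (r in seq_len(max_reject)) {
      s <- sort(sample.int(m, n_res))
      if (!any(conf[cbind(s[pr[1, ]], s[pr[2, ]])])) {
        return(new_restraint_set(candidates, sel = s))
      }
    }
    rst_abort(sprintf(
      "no atom-disjoint %d-subset found after %d rejections", n_res, max_reject
    ), "rst_infeasible_error")
  }
  draw_all <- function() lapply(seq_len(trials), function(t) draw_one())
  if (is.null(seed)) draw_all() else withr::with_seed(seed, draw_all())
}
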