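test_that("greedy follows the min-max update rule on the worked line instance", {
  cand <- line_candidates(c(0, 0.1, 0.2, 0.4, 0.5))
  set <- select_restraints(cand, n_res = 3)
  # initial pair: extremes at 0 and 0.5 (largest separation); third pick:
  # min-distances are 0.1 -> 0.1, 0.2 -> 0.2, 0.4 -> 0.1, so 0.2 wins
  expect_equal(set$mx, c(0, 0.5, 0.2))
  expect_equal(set$step, 1:3)
  expect_equal(attr(set, "sum_midpoint_distance"), 0.5 + 0.2 + 0.3)
})

test_that("selection exhausts gracefully below n_res", {
  cand <- line_candidates(c(0, 0.3))
  expect_warning(set <- select_restraints(cand, n_res = 4),
                 class = "rst_short_set_warning")
  expect_equal(nrow(set), 2)
  cand1 <- line_candidates(0.2)
  expect_equal(nrow(select_restraints(cand1, n_res = 4)), 1)
})

test_that("selected restraints satisfy feasibility invariants on random instances", {
  withr::with_seed(505, {
    for (rep in 1:40) {
      n <- sample(10:22, 1)
      cand <- random_toy_candidates(n, seed = sample.int(1e6, 1))
      if (nrow(cand) < 2) next
      set <- suppressWarnings(select_restraints(cand, n_res = 4))
      expect_true(all(set$pair_distance <= 0.1))
      expect_equal(anyDuplicated(set$atom_id_a), 0)
      expect_equal(anyDuplicated(set$atom_id_b), 0)
      expect_lte(nrow(set), 4)
      if (nrow(set) >= 2) {
        # first two selected realize the true max separation over
        # atom-disjoint candidate pairs (O(m^2) enumeration)
        M <- cbind(cand$mx, cand$my, cand$mz)
        D <- as.matrix(dist(M))
        ok <- outer(cand$atom_id_a, cand$atom_id_a, "!=") &
          outer(cand$atom_id_b, cand$atom_id_b, "!=")
        true_max <- max(D[ok & upper.tri(D)])
        got <- sqrt(sum((unlist(set[1, c("mx", "my", "mz")]) -
                         unlist(set[2, c("mx", "my", "mz")]))^2))
        expect_equal(got, true_max)
      }
    }
  })
})

test_that("selection is invariant to candidate row order", {
  withr::with_seed(606, {
    cand <- random_toy_candidates(18, seed = 77)
    ref <- suppressWarnings(select_restraints(cand, n_res = 4))
    for (rep in 1:20) {
      shuf <- cand[sample(nrow(cand)), ]
      attributes(shuf)[c("molecule_pair", "n_atoms", "d_res")] <-
        attributes(cand)[c("molecule_pair", "n_atoms", "d_res")]
      got <- suppressWarnings(select_restraints(shuf, n_res = 4))
      expect_equal(tibble::as_tibble(got), tibble::as_tibble(ref))
    }
  })
})

test_that("tie-breaking picks the candidate farthest from the selected COG", {
  sel <- line_candidates(c(-0.2, 0.2))
  selected <- select_restraints(sel, n_res = 2) # COG of midpoints at origin
  tied <- point_candidates(rbind(c(0.30, 0, 0), c(0, 0.31, 0)))
  win <- break_tie(tied, selected)
  expect_equal(c(win$mx, win$my), c(0, 0.31))
  # symmetric candidates equidistant from the COG: lowest atom_id_a wins
  tied2 <- point_candidates(rbind(c(0.3, 0, 0), c(-0.3, 0, 0)))
  win2 <- break_tie(tied2, selected)
  expect_equal(win2$atom_id_a, min(tied2$atom_id_a))
  # single tied candidate is returned unchanged
  one <- point_candidates(c(0.1, 0.2, 0.3))
  expect_equal(break_tie(one, selected)$mx, 0.1)
})

test_that("near-tied weights trigger the COG tie-breaker inside selection", {
  # initial pair spans x in {0, 1}; two further candidates have min-distance
  # weights 0.583 and 0.585 (within the 0.02 nm window); the COG rule picks
  # the one farther from the selected midpoints' COG at (0.5, 0, 0)
  pts <- rbind(
    c(0, 0, 0), c(1, 0, 0),
    c(0.5, 0.30, 0),   # weight sqrt(0.25 + 0.09)  = 0.5831, COG dist 0.300
    c(0.5, -0.305, 0)  # weight sqrt(0.25 + 0.093) = 0.5857, COG dist 0.305
  )
  cand <- point_candidates(pts)
  set <- select_restraints(cand, n_res = 3)
  expect_equal(set$my[3], -0.305)

  # geometry where the tie window flips the outcome: the higher-weight
  # candidate sits close to the selected COG, the slightly lower-weight one
  # (within 0.02 nm) sits far from it
  pts2 <- rbind(
    c(0, 0, 0), c(2, 0, 0),        # initial pair, separation 2
    c(1, 0.30, 0),                 # weight 1.0440, COG distance 0.30
    c(0.62, 0.83, 0)               # weight 1.0360, COG distance 0.9129
  )
  cand2 <- point_candidates(pts2)
  with_tie <- select_restraints(cand2, n_res = 3, tie_tolerance = 0.02)
  no_tie <- select_restraints(cand2, n_res = 3, tie_tolerance = 0)
  expect_equal(with_tie[3, c("mx", "my")], tibble::tibble(mx = 0.62, my = 0.83),
               ignore_attr = TRUE)
  expect_equal(no_tie[3, c("mx", "my")], tibble::tibble(mx = 1, my = 0.30),
               ignore_attr = TRUE)
})

test_that("restraint-set metrics recompute from midpoints", {
  a <- 0.1
  reg <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * a / (2 * sqrt(2))
  cand <- point_candidates(reg)
  set <- select_restraints(cand, n_res = 4)
  sc <- score_restraints(set)
  expect_equal(sc$sum_midpoint_distance, 6 * a)
  expect_equal(sc$chv, a^3 / (6 * sqrt(2)))
  expect_equal(attr(set, "sum_midpoint_distance"), sc$sum_midpoint_distance)
  expect_equal(attr(set, "chv"), sc$chv)
  # one and two restraints
  one <- select_restraints(point_candidates(c(0, 0, 0)), n_res = 1)
  expect_equal(unlist(score_restraints(one), use.names = FALSE), c(0, 0))
  two <- select_restraints(point_candidates(rbind(c(0, 0, 0), c(0.3, 0, 0))), n_res = 2)
  expect_equal(score_restraints(two)$sum_midpoint_distance, 0.3)
  expect_equal(score_restraints(two)$chv, 0)
})

test_that("tidy and glance summarise a selection", {
  cand <- line_candidates(c(0, 0.1, 0.2, 0.4, 0.5))
  set <- select_restraints(cand, n_res = 3)
  td <- tidy(set)
  expect_equal(nrow(td), 3)
  expect_equal(td$step, 1:3)
  gl <- glance(set)
  expect_equal(gl$n_restraints, 3)
  expect_equal(gl$sum_midpoint_distance, 1.0)
  expect_equal(gl$chv, 0)
})
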