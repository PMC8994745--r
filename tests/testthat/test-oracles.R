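test_that("toy systems are reproducible and balanced", {
  s1 <- toy_system(20, seed = 7)
  s2 <- toy_system(20, seed = 7)
  expect_equal(coords_of(s1[[1]]), coords_of(s2[[1]]))
  expect_equal(coords_of(s1[[2]]), coords_of(s2[[2]]))
  expect_false(isTRUE(all.equal(coords_of(s1[[1]]),
                                coords_of(toy_system(20, seed = 8)[[1]]))))
  even <- toy_system(12, seed = 3)
  expect_equal(sort(c(nrow(even[[1]]$atoms), nrow(even[[2]]$atoms))), c(6, 6))
  odd <- toy_system(13, seed = 3)
  expect_equal(sort(c(nrow(odd[[1]]$atoms), nrow(odd[[2]]$atoms))), c(6, 7))
  expect_warning(toy_system(6, seed = 1), class = "rst_small_system_warning")
  # all particles inside the box
  expect_true(all(coords_of(s1[[1]]) >= 0 & coords_of(s1[[1]]) <= 0.2))
})

test_that("brute force matches an independent exhaustive oracle", {
  cand <- line_candidates(c(0, 0.1, 0.2, 0.4, 0.5))
  got <- bf_max_distance(cand, n_res = 3)
  oracle <- bf_oracle(cand, 3, "distance")
  expect_equal(sum(dist(cbind(got$mx, got$my, got$mz))), oracle$score)
  # every 3-subset containing both extremes scores 1.0; the lexicographic
  # tie rule picks candidates {1, 2, 5}
  expect_equal(oracle$score, 1.0)
  expect_equal(got$atom_id_a, c(1L, 2L, 5L))

  withr::with_seed(707, {
    for (rep in 1:5) {
      rc <- random_toy_candidates(12, seed = sample.int(1e6, 1))
      if (nrow(rc) < 4) next
      d_got <- tryCatch(bf_max_distance(rc, 4), rst_infeasible_error = function(e) NULL)
      if (is.null(d_got)) next
      expect_equal(sum(dist(cbind(d_got$mx, d_got$my, d_got$mz))),
                   bf_oracle(rc, 4, "distance")$score)
      c_got <- bf_max_chv(rc, 4)
      expect_equal(convex_hull_volume(cbind(c_got$mx, c_got$my, c_got$mz)),
                   bf_oracle(rc, 4, "chv")$score)
    }
  })
})

test_that("oracles dominate greedy and each other on their own metric", {
  withr::with_seed(808, {
    for (rep in 1:6) {
      rc <- random_toy_candidates(sample(14:20, 1), seed = sample.int(1e6, 1))
      greedy <- suppressWarnings(select_restraints(rc, n_res = 4))
      k <- nrow(greedy)
      if (k < 2) next
      maxd <- bf_max_distance(rc, k)
      maxchv <- bf_max_chv(rc, k)
      expect_lte(attr(greedy, "sum_midpoint_distance"),
                 attr(maxd, "sum_midpoint_distance") + 1e-12)
      expect_lte(attr(greedy, "chv"), attr(maxchv, "chv") + 1e-12)
      expect_gte(attr(maxchv, "chv") + 1e-12, attr(maxd, "chv"))
    }
  })
})

test_that("BF-maxCHV must use the only off-plane candidate", {
  pts <- rbind(
    c(0, 0, 0), c(0.3, 0, 0), c(0, 0.3, 0), c(0.3, 0.3, 0), c(0.15, 0.15, 0),
    c(0.15, 0.15, 0.2)
  )
  cand <- point_candidates(pts)
  got <- bf_max_chv(cand, n_res = 4)
  expect_true(any(abs(got$mz - 0.2) < 1e-12))
  expect_gt(attr(got, "chv"), 0)
})

test_that("m equal to n_res leaves a unique subset", {
  cand <- line_candidates(c(0, 0.2, 0.5))
  for (set in list(bf_max_distance(cand, 3), bf_max_chv(cand, 3))) {
    expect_equal(nrow(set), 3)
    expect_equal(sort(set$mx), c(0, 0.2, 0.5))
  }
  trials <- random_restraints(cand, n_res = 3, trials = 5, seed = 1)
  for (t in trials) expect_equal(sort(t$mx), c(0, 0.2, 0.5))
})

test_that("the enumeration counter equals choose(m, n_res) exactly", {
  for (seed in c(21, 22, 23)) {
    cand <- random_toy_candidates(14, seed = seed)
    if (nrow(cand) < 4) next
    got <- tryCatch(bf_max_distance(cand, 4), rst_infeasible_error = function(e) NULL)
    if (is.null(got)) next
    expect_identical(attr(got, "n_enumerated"), choose(nrow(cand), 4))
  }
  cand5 <- line_candidates(c(0, 0.1, 0.2, 0.4, 0.5))
  expect_identical(attr(bf_max_distance(cand5, 3), "n_enumerated"), choose(5, 3))
})

test_that("the complexity guard refuses oversized enumerations", {
  cand <- line_candidates(seq(0, 1, length.out = 12))
  err <- expect_error(bf_max_distance(cand, 4, cap = 100), class = "rst_complexity_error")
  expect_match(conditionMessage(err), "12")
  expect_match(conditionMessage(err), "100")
})

test_that("random baseline is uniform-feasible and seed-reproducible", {
  cand <- random_toy_candidates(16, seed = 9)
  sets1 <- random_restraints(cand, n_res = 3, trials = 20, seed = 42)
  sets2 <- random_restraints(cand, n_res = 3, trials = 20, seed = 42)
  expect_equal(lapply(sets1, tibble::as_tibble), lapply(sets2, tibble::as_tibble))
  for (s in sets1) {
    expect_equal(nrow(s), 3)
    expect_equal(anyDuplicated(s$atom_id_a), 0)
    expect_equal(anyDuplicated(s$atom_id_b), 0)
  }
  # an instance where every candidate shares atom 1 of molecule A
  a <- make_mol(matrix(0, 1, 3), id = "a")
  b <- make_mol(rbind(c(0.01, 0, 0), c(0, 0.01, 0), c(0, 0, 0.01)), id = "b")
  shared <- suppressWarnings(candidate_restraints(a, b, d_res = 0.1))
  expect_error(random_restraints(shared, n_res = 2, trials = 1, seed = 1),
               class = "rst_infeasible_error")
})
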