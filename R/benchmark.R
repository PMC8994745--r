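#' Benchmark restraint-selection strategies on toy systems
#'
#' Reproduces the toy validation protocol for the greedy selector: for each
#' system size and replicate a fresh two-entity toy system is generated,
#' candidates are enumerated once (ring filter bypassed, distance cutoff
#' applied), and all requested strategies run on the same candidate set.
#' The random baseline row reports metrics averaged over its `trials`
#' draws. Strategy failures (e.g. infeasible instances) are flagged per
#' cell, not propagated.
#'
#' @param sizes Integer vector of total particle counts (default `12:30`).
#' @param replicates Independent systems per size (default 20).
#' @param n_res Restraints per selection (default 4).
#' @param d_res Candidate distance cutoff in nm (default 0.1).
#' @param trials Random-baseline repetitions per instance (default 100).
#' @param seed Master seed; the whole sweep is reproducible from it.
#' @param box_edge Toy-system box edge in nm (default 0.2).
#' @param algorithms Subset of `c("greedy", "bf_maxd", "bf_maxchv", "random")`.
#' @param cap Brute-force subset cap (see [bf_max_distance()]).
#' @return A tibble of class `rst_benchmark`: one row per (size, replicate,
#'   algorithm) with columns `n_candidates`, `n_restraints`,
#'   `sum_midpoint_distance` (nm), `chv` (nm^3), `runtime_s`, `ok`, `note`.
#' @export
run_benchmark <- function(sizes = 12:30, replicates = 20, n_res = 4,
                          d_res = 0.1, trials = 100, seed = 1,
                          box_edge = 0.2,
                          algorithms = c("greedy", "bf_maxd", "bf_maxchv", "random"),
                          cap = 2e6) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  grid <- tidyr::expand_grid(n_particles = as.integer(sizes),
                             replicate = seq_len(replicates))
  sub_seeds <- withr::with_seed(as.integer(seed), {
    matrix(sample.int(.Machine$integer.max - 1L, 2L * nrow(grid)), ncol = 2L)
  })

  rows <- purrr::pmap(list(grid$n_particles, grid$replicate, seq_len(nrow(grid))),
    function(np, rep_i, cell) {
      sys <- toy_system(np, seed = sub_seeds[cell, 1L], box_edge = box_edge)
      cand <- candidate_restraints(sys[[1]], sys[[2]], d_res = d_res,
                                   restrict_to_rings = FALSE)
      purrr::map(algorithms, function(alg) {
        t0 <- proc.time()[["elapsed"]]
        res <- tryCatch(
          switch(alg,
            greedy = {
              s <- suppressWarnings(select_restraints(cand, n_res = n_res))
              bench_metrics(s)
            },
            bf_maxd = bench_metrics(bf_max_distance(cand, n_res = n_res, cap = cap)),
            bf_maxchv = bench_metrics(bf_max_chv(cand, n_res = n_res, cap = cap)),
            random = {
              sets <- random_restraints(cand, n_res = n_res, trials = trials,
                                        seed = sub_seeds[cell, 2L])
              sc <- purrr::map(sets, score_restraints)
              list(
                n_restraints = n_res,
                sum_midpoint_distance = mean(purrr::map_dbl(sc, "sum_midpoint_distance")),
                chv = mean(purrr::map_dbl(sc, "chv"))
              )
            }
          ),
          error = function(e) {
            list(n_restraints = NA_integer_, sum_midpoint_distance = NA_real_,
                 chv = NA_real_, note = conditionMessage(e))
          }
        )
        tibble::tibble(
          algorithm = alg, n_particles = np, replicate = rep_i,
          system_seed = sub_seeds[cell, 1L],
          n_candidates = nrow(cand),
          n_restraints = res$n_restraints,
          sum_midpoint_distance = res$sum_midpoint_distance,
          chv = res$chv,
          runtime_s = proc.time()[["elapsed"]] - t0,
          ok = is.null(res$note),
          note = res$note %||% NA_character_
        )
      }) |> purrr::list_rbind()
    })
  out <- purrr::list_rbind(rows)
  structure(out, seed = as.integer(seed), n_res = n_res, d_res = d_res,
            trials = trials, box_edge = box_edge,
            class = c("rst_benchmark", class(out)))
}

bench_metrics <- function(set) {
  sc <- score_restraints(set)
  list(n_restraints = nrow(set),
       sum_midpoint_distance = sc$sum_midpoint_distance,
       chv = sc$chv)
}
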