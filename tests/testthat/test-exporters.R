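# deterministic 4-restraint selection used by all writer tests
fixed_selection <- function() {
  a <- make_mol(rbind(
    c(0, 0, 0), c(0.3, 0, 0), c(0, 0.3, 0), c(0, 0, 0.3), c(0.15, 0.15, 0)
  ), id = "ligA")
  b <- make_mol(rbind(
    c(0.01, 0, 0), c(0.3, 0.01, 0), c(0, 0.31, 0), c(0, 0, 0.29), c(0.16, 0.15, 0)
  ), id = "ligB")
  cand <- suppressWarnings(candidate_restraints(a, b, d_res = 0.05))
  select_restraints(cand, n_res = 4)
}

test_that("GROMOS writer emits the documented block byte-stably", {
  set <- fixed_selection()
  path <- withr::local_tempfile(fileext = ".dsr")
  write_gromos(set, path)
  lines <- readLines(path)
  expect_equal(lines[1], "TITLE")
  expect_equal(lines[4], "DISTANCERESSPEC")
  expect_equal(lines[6], "0.100000 0.153000")
  body <- lines[8:11]
  expect_length(grep("0\\.000000\\s+1\\.000000\\s+0$", body), 4)
  # golden layout, frozen from the documented column widths
  expect_equal(
    body[1],
    "    3    0    0    0    0      8    0    0    0    0     0.000000     1.000000    0"
  )
  expect_equal(lines[12], "END")
  # byte-stable across writes
  path2 <- withr::local_tempfile(fileext = ".dsr")
  write_gromos(set, path2)
  expect_identical(readLines(path2), lines)
})

test_that("GROMOS output round-trips through the companion reader", {
  set <- fixed_selection()
  path <- withr::local_tempfile(fileext = ".dsr")
  write_gromos(set, path, export_params(r0 = 0.05))
  back <- read_gromos(path)
  expect_equal(back$atom_i, set$atom_id_a)
  expect_equal(back$atom_j, set$atom_id_b + 5) # molecule A has 5 atoms
  expect_equal(back$r0, rep(0.05, 4))
  expect_equal(back$w0, rep(1, 4))
  expect_equal(back$rah, rep(0L, 4))
})

test_that("GROMACS writer labels restraints in selection order and round-trips", {
  set <- fixed_selection()
  path <- withr::local_tempfile(fileext = ".itp")
  write_gromacs(set, path)
  lines <- readLines(path)
  expect_equal(lines[4], "[ distance_restraints ]")
  data <- lines[!startsWith(lines, ";") & !startsWith(lines, "[")]
  expect_length(data, 4)
  back <- read_gromacs(path)
  expect_equal(back$ai, set$atom_id_a)
  expect_equal(back$aj, set$atom_id_b + 5)
  expect_equal(back$label, 0:3)
  expect_equal(back$low, rep(0, 4))
  expect_equal(back$up1, rep(0 + 0.05, 4)) # r0 + d_res of the selection
  expect_equal(back$up2, back$up1 + 0.1)
  expect_equal(back$fac, rep(1, 4)) # force_constant / disre_fc
  # byte stability
  path2 <- withr::local_tempfile(fileext = ".itp")
  write_gromacs(set, path2)
  expect_identical(readLines(path2), lines)
})

test_that("all writers emit the same atom pairs in the same order", {
  set <- fixed_selection()
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile(); p3 <- withr::local_tempfile()
  write_gromos(set, p1)
  write_gromacs(set, p2)
  write_restraint_json(set, p3)
  g <- read_gromos(p1)
  m <- read_gromacs(p2)
  j <- read_restraint_json(p3)$sets[[1]]
  expect_equal(g$atom_i, m$ai)
  expect_equal(g$atom_j, m$aj)
  expect_equal(j$atom_id_a, g$atom_i)
  expect_equal(j$atom_id_b + 5, g$atom_j)
})

test_that("JSON round-trip is lossless and a fixed point", {
  set <- fixed_selection()
  p1 <- withr::local_tempfile(fileext = ".json")
  write_restraint_json(set, p1)
  txt1 <- readLines(p1)
  # default force constant appears verbatim
  expect_true(any(grepl("\"force_constant\": 5000", txt1)))
  back <- read_restraint_json(p1)
  expect_length(back$sets, 1)
  rec <- back$sets[[1]]
  expect_equal(rec$atom_id_a, set$atom_id_a)
  expect_equal(rec$atom_id_b, set$atom_id_b)
  expect_equal(rec$xa, set$xa)
  expect_equal(rec$zb, set$zb)
  expect_equal(back$params$force_constant, 5000)
  expect_equal(back$params$r0, 0)
  # midpoints recomputed, not stored: still exact
  expect_equal(rec$mx, set$mx)
  # write(read(write(x))) == write(x)
  p2 <- withr::local_tempfile(fileext = ".json")
  write_restraint_json(back$sets, p2, back$params)
  expect_identical(readLines(p2), txt1)
})

test_that("empty restraint lists and schema violations are handled", {
  p <- withr::local_tempfile(fileext = ".json")
  write_restraint_json(list(), p)
  back <- read_restraint_json(p)
  expect_length(back$sets, 0)

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"meta": {}, "restraints": [{"m1": {"atom_id": 1}}]}', bad)
  err <- expect_error(read_restraint_json(bad), class = "rst_json_error")
  expect_match(conditionMessage(err), "restraints\\[1\\]")
  writeLines('{"restraints": []}', bad)
  expect_error(read_restraint_json(bad), class = "rst_json_error")
  writeLines("not json at all {", bad)
  expect_error(read_restraint_json(bad), class = "rst_json_error")
})

test_that("export parameter validation and merged-index injectivity", {
  expect_error(export_params(force_constant = -1), class = "rst_input_error")
  expect_error(export_params(r0 = -0.1), class = "rst_input_error")
  set <- fixed_selection()
  # offset 0 collides molecule-B indices with molecule-A indices
  expect_error(write_gromos(set, withr::local_tempfile(),
                            export_params(atom_offset_b = 0)),
               class = "rst_index_error")
  # a ring export covers every edge of the ring
  mols <- toy_ensemble(3, n_atoms = 8, seed = 61)
  ring <- suppressWarnings(select_ring(mols, restrict_to_rings = FALSE))
  p <- withr::local_tempfile(fileext = ".dsr")
  write_gromos(ring, p)
  expect_equal(nrow(read_gromos(p)),
               sum(purrr::map_int(ring$edge_sets, nrow)))
})
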