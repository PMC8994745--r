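#' Export parameters for restraint writers
#'
#' @param force_constant Harmonic force constant in kJ/(mol nm^2)
#'   (default 5000).
#' @param r0 Reference distance in nm (default 0: the selected atom pairs
#'   overlap within the cutoff by construction, so a full harmonic about
#'   zero keeps them together).
#' @param atom_offset_b Index offset added to molecule-B atom ids in the
#'   merged dual-topology numbering; defaults to the atom count of molecule
#'   A stored on the restraint set.
#' @param dish,disc GROMOS DISH/DISC constants in nm (defaults 0.1, 0.153).
#' @param w0 GROMOS per-restraint weight (default 1.0).
#' @param rah GROMOS restraint shape code (default 0, full harmonic).
#' @param disre_fc Run-level GROMACS `disre-fc` the per-restraint factor is
#'   expressed against (default equal to `force_constant`, giving `fac` 1).
#' @return A list of class `rst_export_params`.
#' @export
export_params <- function(force_constant = 5000, r0 = 0, atom_offset_b = NULL,
                          dish = 0.1, disc = 0.153, w0 = 1.0, rah = 0L,
                          disre_fc = force_constant) {
  if (force_constant <= 0) rst_abort("force_constant must be positive", "rst_input_error")
  if (r0 < 0) rst_abort("r0 must be >= 0", "rst_input_error")
  structure(
    list(force_constant = force_constant, r0 = r0, atom_offset_b = atom_offset_b,
         dish = dish, disc = disc, w0 = w0, rah = as.integer(rah),
         disre_fc = disre_fc),
    class = "rst_export_params"
  )
}

as_set_list <- function(sets) {
  if (inherits(sets, "rst_ring")) return(sets$edge_sets)
  if (inherits(sets, "rst_restraint_set")) return(list(sets))
  if (is.list(sets)) return(sets)
  rst_abort("expected a restraint set, a list of sets, or an rst_ring", "rst_input_error")
}

merged_indices <- function(set, params) {
  off <- params$atom_offset_b %||% attr(set, "n_atoms")[1]
  if (is.null(off) || is.na(off)) {
    rst_abort("atom_offset_b not set and molecule-A atom count unknown", "rst_index_error")
  }
  i <- set$atom_id_a
  j <- set$atom_id_b + off
  if (any(duplicated(c(i, j)))) {
    rst_abort("merged-index mapping is not injective for this restraint set", "rst_index_error")
  }
  list(i = as.integer(i), j = as.integer(j))
}

write_atomically <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Write restraints as a GROMOS distance-restraint specification file
#'
#' Emits a `TITLE` block and a `DISTANCERESSPEC` block. The first data line
#' carries the DISH/DISC constants; each restraint line is
#' `i 0 0 0 0  j 0 0 0 0  r0 w0 rah` with virtual-atom type code 0 (real
#' atoms), unit weight and `rah = 0` (attractive and repulsive harmonic).
#' Reals are fixed-point with six decimals.
#'
#' @param sets An `rst_restraint_set`, a list of them, or an [select_ring()]
#'   result.
#' @param path Output file path.
#' @param params An [export_params()] object.
#' @return `path`, invisibly.
#' @export
write_gromos <- function(sets, path, params = export_params()) {
  sets <- as_set_list(sets)
  lines <- c(
    "TITLE",
    "distance restraints generated by restraintr",
    "END",
    "DISTANCERESSPEC",
    "# DISH  DISC",
    sprintf("%.6f %.6f", params$dish, params$disc),
    "# i  j  k  l  type    i  j  k  l  type    r0    w0    rah"
  )
  for (set in sets) {
    ix <- merged_indices(set, params)
    lines <- c(lines, sprintf(
      "%5d %4d %4d %4d %4d %6d %4d %4d %4d %4d %12.6f %12.6f %4d",
      ix$i, 0L, 0L, 0L, 0L, ix$j, 0L, 0L, 0L, 0L,
      params$r0, params$w0, params$rah
    ))
  }
  lines <- c(lines, "END")
  write_atomically(lines, path)
}

#' Read a GROMOS distance-restraint specification file
#'
#' Companion reader for [write_gromos()] output.
#'
#' @param path File path.
#' @return A tibble with columns `atom_i`, `atom_j`, `r0`, `w0`, `rah`.
#' @export
read_gromos <- function(path) {
  lines <- readLines(path, warn = FALSE)
  start <- which(lines == "DISTANCERESSPEC")
  if (length(start) != 1L) rst_abort("no DISTANCERESSPEC block found", "rst_format_error")
  stop_at <- which(lines == "END")
  stop_at <- min(stop_at[stop_at > start])
  body <- lines[(start + 1L):(stop_at - 1L)]
  body <- body[!startsWith(trimws(body), "#")]
  fields <- purrr::map(body, ~ as.numeric(strsplit(trimws(.x), "\\s+")[[1]]))
  fields <- fields[lengths(fields) == 13L]
  if (length(fields) == 0L) return(tibble::tibble(
    atom_i = integer(), atom_j = integer(), r0 = double(), w0 = double(), rah = integer()
  ))
  mat <- do.call(rbind, fields)
  tibble::tibble(
    atom_i = as.integer(mat[, 1]), atom_j = as.integer(mat[, 6]),
    r0 = mat[, 11], w0 = mat[, 12], rah = as.integer(mat[, 13])
  )
}

#' Write restraints as a GROMACS `[ distance_restraints ]` fragment
#'
#' One line per restraint: `ai aj 1 label 1 low up1 up2 fac`, with
#' `low = 0`, `up1 = r0 + d_res`, `up2 = up1 + 0.1` and
#' `fac = force_constant / disre_fc`. The flat region up to `up1` reflects
#' that selected pairs already lie within the cutoff; the convention is
#' documented in the leading comment of the written file. Labels enumerate
#' restraints in selection order starting at 0.
#'
#' @inheritParams write_gromos
#' @return `path`, invisibly.
#' @export
write_gromacs <- function(sets, path, params = export_params()) {
  sets <- as_set_list(sets)
  lines <- c(
    "; distance restraints generated by restraintr",
    "; convention: type 1 (harmonic flat-bottom); low = 0, up1 = r0 + d_res,",
    ";             up2 = up1 + 0.1 nm; fac = force_constant / disre-fc",
    "[ distance_restraints ]",
    ";  ai    aj type label type'      low      up1      up2      fac"
  )
  label <- 0L
  for (set in sets) {
    ix <- merged_indices(set, params)
    d_res <- attr(set, "d_res") %||% 0.1
    up1 <- params$r0 + d_res
    k <- nrow(set)
    lines <- c(lines, sprintf(
      "%5d %5d %5d %5d %5d %8.4f %8.4f %8.4f %8.4f",
      ix$i, ix$j, 1L, label + seq_len(k) - 1L, 1L,
      0, up1, up1 + 0.1, params$force_constant / params$disre_fc
    ))
    label <- label + k
  }
  write_atomically(lines, path)
}

#' Read a GROMACS `[ distance_restraints ]` fragment
#'
#' Companion reader for [write_gromacs()] output.
#'
#' @param path File path.
#' @return A tibble with columns `ai`, `aj`, `label`, `low`, `up1`, `up2`,
#'   `fac`.
#' @export
read_gromacs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), ";")]
  lines <- lines[trimws(lines) != "" & !grepl("^\\[", trimws(lines))]
  fields <- purrr::map(lines, ~ as.numeric(strsplit(trimws(.x), "\\s+")[[1]]))
  fields <- fields[lengths(fields) == 9L]
  if (length(fields) == 0L) {
    return(tibble::tibble(ai = integer(), aj = integer(), label = integer(),
                          low = double(), up1 = double(), up2 = double(), fac = double()))
  }
  mat <- do.call(rbind, fields)
  tibble::tibble(
    ai = as.integer(mat[, 1]), aj = as.integer(mat[, 2]),
    label = as.integer(mat[, 4]),
    low = mat[, 6], up1 = mat[, 7], up2 = mat[, 8], fac = mat[, 9]
  )
}

#' Write restraints as JSON
#'
#' Engine-neutral interchange format: a top-level object with `meta` (tool,
#' version, units, export parameters) and `restraints`, an array of objects
#' `{m1: {molecule_id, atom_id, name, element, x, y, z}, m2: {...}, r0,
#' force_constant}`. Coordinates are in nm; midpoints are not stored and
#' are recomputed on reading.
#'
#' @inheritParams write_gromos
#' @return `path`, invisibly.
#' @export
write_restraint_json <- function(sets, path, params = export_params()) {
  sets <- as_set_list(sets)
  atom_obj <- function(set, side, k) {
    mol_ids <- attr(set, "molecule_pair") %||% c(NA_character_, NA_character_)
    s <- if (side == 1L) "a" else "b"
    list(
      molecule_id = mol_ids[side],
      atom_id = set[[paste0("atom_id_", s)]][k],
      name = set[[paste0("name_", s)]][k],
      element = set[[paste0("element_", s)]][k],
      x = set[[paste0("x", s)]][k], y = set[[paste0("y", s)]][k],
      z = set[[paste0("z", s)]][k]
    )
  }
  restraints <- purrr::list_flatten(purrr::map(sets, function(set) {
    purrr::map(seq_len(nrow(set)), function(k) {
      list(m1 = atom_obj(set, 1L, k), m2 = atom_obj(set, 2L, k),
           r0 = params$r0, force_constant = params$force_constant)
    })
  }))
  obj <- list(
    meta = list(
      tool = "restraintr",
      version = as.character(utils::packageVersion("restraintr")),
      units = "nm",
      parameters = list(force_constant = params$force_constant, r0 = params$r0)
    ),
    restraints = restraints
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  write_atomically(json, path)
}

#' Read restraints from the JSON interchange format
#'
#' Validates the schema written by [write_restraint_json()] and
#' reconstructs one `rst_restraint_set` per molecule pair (midpoints
#' recomputed from the stored coordinates).
#'
#' @param path File path.
#' @return A list with elements `sets` (list of `rst_restraint_set`) and
#'   `params` (an [export_params()]).
#' @export
read_restraint_json <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) rst_abort(
                    sprintf("invalid JSON in '%s': %s", path, conditionMessage(e)),
                    "rst_json_error"))
  for (fld in c("meta", "restraints")) {
    if (is.null(obj[[fld]])) rst_abort(sprintf("missing '$%s'", fld), "rst_json_error")
  }
  atom_fields <- c("molecule_id", "atom_id", "name", "element", "x", "y", "z")
  rows <- purrr::imap(obj$restraints, function(r, i) {
    for (side in c("m1", "m2")) {
      if (is.null(r[[side]])) {
        rst_abort(sprintf("missing '$restraints[%d]$%s'", i, side), "rst_json_error")
      }
      missing <- setdiff(atom_fields, names(r[[side]]))
      if (length(missing) > 0L) {
        rst_abort(sprintf("missing '$restraints[%d]$%s$%s'", i, side, missing[1]),
                  "rst_json_error")
      }
    }
    tibble::tibble(
      mol_a = as.character(r$m1$molecule_id), mol_b = as.character(r$m2$molecule_id),
      atom_id_a = as.integer(r$m1$atom_id), name_a = r$m1$name, element_a = r$m1$element,
      xa = r$m1$x, ya = r$m1$y, za = r$m1$z,
      atom_id_b = as.integer(r$m2$atom_id), name_b = r$m2$name, element_b = r$m2$element,
      xb = r$m2$x, yb = r$m2$y, zb = r$m2$z,
      r0 = r$r0 %||% 0, force_constant = r$force_constant %||% NA_real_
    )
  }) |> purrr::list_rbind()
  params <- export_params(
    force_constant = obj$meta$parameters$force_constant %||% 5000,
    r0 = obj$meta$parameters$r0 %||% 0
  )
  sets <- if (nrow(rows) == 0L) list() else {
    key <- paste(rows$mol_a, rows$mol_b, sep = "|")
    split(rows, factor(key, levels = unique(key))) |>
      purrr::map(function(d) {
        d$pair_distance <- sqrt((d$xa - d$xb)^2 + (d$ya - d$yb)^2 + (d$za - d$zb)^2)
        d$mx <- (d$xa + d$xb) / 2
        d$my <- (d$ya + d$yb) / 2
        d$mz <- (d$za + d$zb) / 2
        cand <- new_candidates(
          d[, setdiff(names(d), c("mol_a", "mol_b", "r0", "force_constant"))],
          molecule_pair = c(d$mol_a[1], d$mol_b[1]),
          n_atoms = c(NA_integer_, NA_integer_),
          d_res = NA_real_
        )
        new_restraint_set(cand, sel = seq_len(nrow(d)))
      }) |> unname()
  }
  list(sets = sets, params = params)
}
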