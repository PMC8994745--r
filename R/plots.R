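#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a restraint selection
#'
#' Projects the two molecules and the selected restraints onto a pair of
#' coordinate axes: atoms as points coloured by molecule, selected atom
#' pairs connected by dashed segments, restraint midpoints as crosses.
#'
#' @param object An `rst_restraint_set`.
#' @param axes Two of `"x"`, `"y"`, `"z"` to project onto (default x, y).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rst_restraint_set <- function(object, axes = c("x", "y"), ...) {
  mol <- attr(object, "molecule_pair") %||% c("A", "B")
  a1 <- axes[1]; a2 <- axes[2]
  atoms <- dplyr::bind_rows(
    tibble::tibble(molecule = mol[1], h = object[[paste0(a1, "a")]], v = object[[paste0(a2, "a")]]),
    tibble::tibble(molecule = mol[2], h = object[[paste0(a1, "b")]], v = object[[paste0(a2, "b")]])
  )
  segs <- tibble::tibble(
    h = object[[paste0(a1, "a")]], v = object[[paste0(a2, "a")]],
    hend = object[[paste0(a1, "b")]], vend = object[[paste0(a2, "b")]]
  )
  mids <- tibble::tibble(h = object[[paste0("m", a1)]], v = object[[paste0("m", a2)]])
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$h, y = .data$v, xend = .data$hend, yend = .data$vend),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::geom_point(
      data = atoms,
      ggplot2::aes(x = .data$h, y = .data$v, colour = .data$molecule), size = 2
    ) +
    ggplot2::geom_point(
      data = mids, ggplot2::aes(x = .data$h, y = .data$v),
      shape = 4, size = 3, stroke = 1.2
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste0(a1, " (nm)"), y = paste0(a2, " (nm)"),
                  colour = "molecule") +
    ggplot2::theme_minimal()
}

#' Plot benchmark results
#'
#' Distance metric, CHV or runtime as a function of system size, one line
#' per selection strategy with a mean and a spread ribbon across
#' replicates.
#'
#' @param object An `rst_benchmark` table from [run_benchmark()].
#' @param metric One of `"sum_midpoint_distance"`, `"chv"`, `"runtime_s"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rst_benchmark <- function(object, metric = c("sum_midpoint_distance", "chv", "runtime_s"), ...) {
  metric <- match.arg(metric)
  lab <- c(sum_midpoint_distance = "sum of midpoint distances (nm)",
           chv = "convex-hull volume (nm³)",
           runtime_s = "runtime (s)")[[metric]]
  summ <- object |>
    dplyr::filter(.data$ok) |>
    dplyr::group_by(.data$algorithm, .data$n_particles) |>
    dplyr::summarise(
      mid = mean(.data[[metric]], na.rm = TRUE),
      lo = stats::quantile(.data[[metric]], 0.25, na.rm = TRUE),
      hi = stats::quantile(.data[[metric]], 0.75, na.rm = TRUE),
      .groups = "drop"
    )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$n_particles, y = .data$mid,
                                     colour = .data$algorithm, fill = .data$algorithm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "number of particles", y = lab,
                  colour = "strategy", fill = "strategy") +
    ggplot2::theme_minimal()
}
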