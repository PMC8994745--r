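#' Center of geometry of a point set
#'
#' Unweighted arithmetic mean of 3-D coordinates, the COG used by the
#' tie-breaking rule of the restraint selector.
#'
#' @param points A matrix or data frame with three columns (x, y, z), in nm.
#' @return A numeric vector of length 3 (nm).
#' @export
#' @examples
#' center_of_geometry(rbind(c(0, 0, 0), c(0, 0, 0.1)))
center_of_geometry <- function(points) {
  p <- as_coord_matrix(points)
  if (nrow(p) < 1L) rst_abort("need at least one point", "rst_input_error")
  colMeans(p)
}

#' Midpoint of two atom positions
#'
#' @param a,b Numeric vectors of length 3 (nm).
#' @return Numeric vector of length 3 (nm).
#' @export
midpoint <- function(a, b) {
  (as.numeric(a) + as.numeric(b)) / 2
}

#' Volume of the 3-D convex hull of a point set
#'
#' Computes the convex-hull volume (CHV) spanned by a set of points, the
#' quality metric used to score restraint sets and to weight molecule pairs
#' when chaining multiple end-states. Degenerate sets (fewer than four
#' points, or all points collinear/coplanar within `tol`) have volume 0.
#'
#' The hull is built by supporting-plane enumeration: every plane through
#' three points that has all remaining points on one side is a hull facet;
#' coplanar facets are merged and triangulated via their planar 2-D hull.
#' This is exact and robust for the small point sets arising here (restraint
#' midpoints, typically 4-10 points).
#'
#' @param points A matrix or data frame with three columns (x, y, z), in nm.
#' @param tol Absolute degeneracy tolerance in nm (default 1e-9).
#' @return Hull volume in nm^3 (0 for degenerate input).
#' @export
#' @examples
#' convex_hull_volume(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
convex_hull_volume <- function(points, tol = 1e-9) {
  p <- unique(as_coord_matrix(points))
  n <- nrow(p)
  if (n < 1L) rst_abort("need at least one point", "rst_input_error")
  if (n < 4L) return(0)
  if (n == 4L) {
    return(abs(det(rbind(p[2, ] - p[1, ], p[3, ] - p[1, ], p[4, ] - p[1, ]))) / 6)
  }
  ctr <- colMeans(p)
  q <- sweep(p, 2, ctr)
  if (svd(q, nu = 0, nv = 0)$d[3] <= tol) return(0)

  vol <- 0
  seen <- character()
  idx <- utils::combn(n, 3L)
  for (col in seq_len(ncol(idx))) {
    i <- idx[1, col]; j <- idx[2, col]; k <- idx[3, col]
    nrm <- cross3(q[j, ] - q[i, ], q[k, ] - q[i, ])
    nn <- sqrt(sum(nrm^2))
    if (nn <= tol) next
    nrm <- nrm / nn
    d <- as.numeric(q %*% nrm) - sum(q[i, ] * nrm)
    if (max(d) > tol && min(d) < -tol) next # not a supporting plane
    if (max(d) > tol) nrm <- -nrm # orient outward (centroid is interior)
    off <- sum(q[i, ] * nrm)
    on_plane <- which(abs(as.numeric(q %*% nrm) - off) <= tol)
    key <- paste(on_plane, collapse = "/") # facet identity = its vertex set
    if (key %in% seen) next
    seen <- c(seen, key)
    # triangulate the facet polygon in its own plane
    e1 <- (q[j, ] - q[i, ]) / sqrt(sum((q[j, ] - q[i, ])^2))
    e2 <- cross3(nrm, e1)
    uv <- cbind(q[on_plane, , drop = FALSE] %*% e1, q[on_plane, , drop = FALSE] %*% e2)
    hull2 <- grDevices::chull(uv[, 1], uv[, 2])
    verts <- on_plane[hull2]
    nv <- length(verts)
    if (nv < 3L) next
    # divergence theorem: V = sum over facets of area * outward offset / 3
    # (centroid is at the origin, so off > 0 for every facet)
    area <- 0
    for (t in 2:(nv - 1L)) {
      a <- q[verts[1L], ]; b <- q[verts[t], ]; cc <- q[verts[t + 1L], ]
      area <- area + sqrt(sum(cross3(b - a, cc - a)^2)) / 2
    }
    vol <- vol + area * off / 3
  }
  vol
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

as_coord_matrix <- function(points) {
  if (is.data.frame(points)) {
    cols <- intersect(c("x", "y", "z"), names(points))
    if (length(cols) == 3L) points <- points[, cols] else points <- points[, 1:3]
    points <- as.matrix(points)
  } else if (is.numeric(points) && is.null(dim(points))) {
    points <- matrix(points, ncol = 3L, byrow = TRUE)
  }
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) rst_abort("points must have 3 coordinate columns", "rst_input_error")
  if (!all(is.finite(points))) rst_abort("coordinates must be finite", "rst_input_error")
  dimnames(points) <- NULL
  points
}
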