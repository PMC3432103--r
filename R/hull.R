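## Convex-hull volume in 1-3 dimensions, used for multivariate
## functional richness in principal-coordinates trait space.

#' Convex-hull volume of a point set
#'
#' Computes the volume (length in 1-D, area in 2-D, volume in 3-D) of
#' the convex hull of a set of points.  Degenerate inputs — fewer than
#' `d + 1` distinct points, or affinely dependent points (collinear in
#' 2-D, coplanar in 3-D) — return 0 with attribute
#' `degenerate = TRUE` rather than an error, so species-poor
#' communities remain mappable.
#'
#' 2-D areas use the convex-hull vertex cycle and the shoelace
#' formula; 3-D volumes enumerate supporting facets (every plane
#' through point triples with all remaining points on one side),
#' fan-triangulate coplanar facets, and sum signed tetrahedron volumes
#' around an interior point.
#'
#' @param points Numeric matrix, one row per point, 1-3 columns.
#' @return Non-negative volume, with logical attribute `degenerate`.
#' @examples
#' convex_hull_volume(rbind(c(0, 0), c(1, 0), c(0, 1)))  # 0.5
#' @export
convex_hull_volume <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (any(!is.finite(points))) stop("points must be finite")
  points <- unique(points)
  d <- ncol(points)
  if (d < 1 || d > 3) stop("only 1-3 dimensional point sets are supported")
  degenerate <- function(v = 0) structure(v, degenerate = TRUE)
  if (nrow(points) < d + 1) return(degenerate())
  vol <- switch(d, hull_length(points), hull_area(points),
                hull_volume_3d(points))
  if (vol <= 0) degenerate() else structure(vol, degenerate = FALSE)
}

hull_length <- function(points) {
  max(points[, 1]) - min(points[, 1])
}

hull_area <- function(points) {
  h <- grDevices::chull(points[, 1], points[, 2])
  if (length(h) < 3) return(0)
  x <- points[h, 1]; y <- points[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

hull_volume_3d <- function(points) {
  n <- nrow(points)
  scale <- max(abs(points), 1)
  tol <- 1e-10 * scale
  idx <- utils::combn(n, 3)
  p1 <- points[idx[1, ], , drop = FALSE]
  v1 <- points[idx[2, ], , drop = FALSE] - p1
  v2 <- points[idx[3, ], , drop = FALSE] - p1
  nx <- v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2]
  ny <- v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3]
  nz <- v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1]
  nrm <- sqrt(nx^2 + ny^2 + nz^2)
  ok <- nrm > tol                      # non-degenerate triangles
  if (!any(ok)) return(0)              # all points collinear
  normals <- cbind(nx, ny, nz)[ok, , drop = FALSE] / nrm[ok]
  offs <- rowSums(normals * p1[ok, , drop = FALSE])
  ## signed distance of every point to every candidate plane
  s <- points %*% t(normals) - rep(offs, each = n)
  ptol <- 1e-9 * scale
  supporting <- colSums(s > ptol) == 0 | colSums(s < -ptol) == 0
  if (!any(supporting)) return(0)
  normals <- normals[supporting, , drop = FALSE]
  offs <- offs[supporting]
  ## orient outward relative to the centroid of all points
  ctr <- colMeans(points)
  flip <- as.numeric(normals %*% ctr) - offs > 0
  normals[flip, ] <- -normals[flip, , drop = FALSE]
  offs[flip] <- -offs[flip]
  ## fan-triangulate each distinct supporting plane exactly once,
  ## identifying planes by the set of points lying on them
  seen <- character(0)
  vol <- 0
  for (i in seq_along(offs)) {
    nrm_k <- normals[i, ]
    on_plane <- which(abs(points %*% nrm_k - offs[i]) <= ptol)
    if (length(on_plane) < 3) next
    key <- paste(on_plane, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    face <- points[on_plane, , drop = FALSE]
    ## orthonormal basis in the plane for 2-D ordering
    u <- face[2, ] - face[1, ]
    u <- u / sqrt(sum(u^2))
    w <- c(nrm_k[2] * u[3] - nrm_k[3] * u[2],
           nrm_k[3] * u[1] - nrm_k[1] * u[3],
           nrm_k[1] * u[2] - nrm_k[2] * u[1])
    xy <- cbind((face - rep(face[1, ], each = nrow(face))) %*% u,
                (face - rep(face[1, ], each = nrow(face))) %*% w)
    h <- grDevices::chull(xy[, 1], xy[, 2])
    if (length(h) < 3) next
    for (j in 2:(length(h) - 1)) {
      a <- face[h[1], ] - ctr
      b <- face[h[j], ] - ctr
      cc <- face[h[j + 1], ] - ctr
      vol <- vol + abs(a[1] * (b[2] * cc[3] - b[3] * cc[2]) -
                         a[2] * (b[1] * cc[3] - b[3] * cc[1]) +
                         a[3] * (b[1] * cc[2] - b[2] * cc[1])) / 6
    }
  }
  vol
}
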