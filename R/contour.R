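#' Cross-sectional contour
#'
#' A contour is one closed, ordered loop of lumen boundary points sampled in
#' a plane approximately orthogonal to the vessel course. The centroid is the
#' arithmetic mean of the boundary points (not the area centroid: for
#' nonuniformly sampled boundaries the two differ, and the arithmetic mean is
#' what anchors the centerline here). The contour plane is the least-squares
#' best-fit plane of the points; its normal is oriented later, when the stack
#' context fixes the proximal-to-distal direction.
#'
#' @param points ordered boundary points: an m x 3 matrix (x, y, z in mm),
#'   data frame, or list of length-3 vectors; m >= 3. The loop is closed
#'   implicitly (last point connects back to the first).
#' @param index integer position of the contour in its stack (1-based).
#' @return an object of class `tc_contour` with elements `points` (m x 3),
#'   `centroid`, `plane_normal` (unit vector, provisional orientation),
#'   `plane_dev` (max out-of-plane deviation, mm), `index`.
#' @examples
#' t <- seq(0, 2 * pi, length.out = 97)[-97]
#' ring <- cbind(10 * cos(t), 10 * sin(t), 0)
#' ct <- contour3d(ring, index = 1)
#' ct$centroid
#' @export
contour3d <- function(points, index = 1L) {
  pts <- as_point_matrix(points)
  if (nrow(pts) < 3L)
    stop("invalid contour: fewer than 3 boundary points")
  pl <- fit_plane(pts)
  structure(
    list(points = pts,
         centroid = compute_centroid(pts),
         plane_normal = pl$normal,
         plane_dev = pl$max_dev,
         index = as.integer(index)),
    class = "tc_contour")
}

#' Centroid of a boundary point loop
#'
#' Arithmetic mean of the boundary points, the quantity whose sequence over
#' contours defines the centerline.
#'
#' @param points m x 3 matrix (or coercible), m >= 3.
#' @return length-3 numeric (mm).
#' @export
compute_centroid <- function(points) {
  pts <- as_point_matrix(points)
  if (nrow(pts) < 3L)
    stop("invalid contour: fewer than 3 boundary points")
  colMeans(pts)
}

#' Ordered stack of cross-sectional contours
#'
#' Contours are ordered proximal to distal. Consecutive centroids must be
#' distinct (they become centerline nodes). As a sanity check, a warning is
#' emitted if the planes of two consecutive contours intersect between their
#' centroids, which indicates contours that cross each other inside the
#' lumen.
#'
#' @param contours list of [contour3d()] objects (or raw point matrices).
#' @return object of class `tc_stack`: list with `contours`, `n`.
#' @export
contour_stack <- function(contours) {
  if (length(contours) < 2L)
    stop("a contour stack needs at least 2 contours")
  contours <- lapply(seq_along(contours), function(i) {
    ci <- contours[[i]]
    if (!inherits(ci, "tc_contour")) ci <- contour3d(ci, index = i)
    ci$index <- as.integer(i)
    ci
  })
  cent <- t(vapply(contours, `[[`, numeric(3L), "centroid"))
  seg <- diff(cent)
  seglen <- sqrt(rowSums(seg^2))
  if (any(seglen < 1e-12))
    stop("degenerate centerline: coincident consecutive centroids")
  # orient each plane normal along the local proximal->distal direction
  n <- length(contours)
  for (i in seq_len(n)) {
    d <- if (i < n) cent[i + 1L, ] - cent[i, ] else cent[i, ] - cent[i - 1L, ]
    if (sum(contours[[i]]$plane_normal * d) < 0)
      contours[[i]]$plane_normal <- -contours[[i]]$plane_normal
  }
  # consecutive planes should not cross between the two centroids
  for (i in seq_len(n - 1L)) {
    a <- contours[[i]]; b <- contours[[i + 1L]]
    d <- cent[i + 1L, ] - cent[i, ]
    # signed distances of both centroids to the other plane; a sign flip of
    # the segment within a plane means the segment pierces it (expected),
    # but the two planes cutting the segment at inverted order is the
    # pathological case.
    ta <- sum((cent[i, ] - b$centroid) * b$plane_normal) *
      sum((cent[i + 1L, ] - b$centroid) * b$plane_normal)
    tb <- sum((cent[i, ] - a$centroid) * a$plane_normal) *
      sum((cent[i + 1L, ] - a$centroid) * a$plane_normal)
    if (ta > 0 && tb > 0 && sum(a$plane_normal * b$plane_normal) < 0)
      warning(sprintf("contour planes %d and %d intersect between centroids",
                      i, i + 1L))
  }
  structure(list(contours = contours, n = n), class = "tc_stack")
}

#' @export
print.tc_stack <- function(x, ...) {
  m <- vapply(x$contours, function(c) nrow(c$points), integer(1L))
  cat(sprintf("contour stack: %d contours, %d-%d points each\n",
              x$n, min(m), max(m)))
  invisible(x)
}

#' @export
print.tc_contour <- function(x, ...) {
  cat(sprintf("contour %d: %d points, centroid (%.2f, %.2f, %.2f) mm, planarity %.2g mm\n",
              x$index, nrow(x$points), x$centroid[1L], x$centroid[2L],
              x$centroid[3L], x$plane_dev))
  invisible(x)
}

stack_centroids <- function(stack) {
  t(vapply(stack$contours, `[[`, numeric(3L), "centroid"))
}
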