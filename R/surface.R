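#' Angular coordinate of boundary points
#'
#' Assigns theta to every boundary point of a contour: the polar angle of
#' (b_ij - C_i) about the centroid within the contour plane, measured from
#' the Greenwich direction (gamma_i - C_i), right-handed about the distal
#' centerline tangent. theta(gamma_i) = 0 and all values lie in [0, 2*pi).
#'
#' @param contour a `tc_contour`.
#' @param greenwich_point the contour's Greenwich point gamma_i; must be one
#'   of its boundary points.
#' @param distal_tangent unit vector pointing proximal -> distal; fixes the
#'   handedness of theta.
#' @return numeric vector of theta values, one per boundary point, in the
#'   contour's stored point order.
#' @export
assign_theta <- function(contour, greenwich_point, distal_tangent) {
  stopifnot(inherits(contour, "tc_contour"))
  g <- as_point3(greenwich_point)
  d2 <- rowSums(sweep(contour$points, 2L, g)^2)
  gi <- which.min(d2)
  if (d2[gi] > 1e-18)
    stop("greenwich_point must be one of the contour's boundary points")
  nhat <- contour$plane_normal
  if (sum(nhat * distal_tangent) < 0) nhat <- -nhat
  v <- sweep(contour$points, 2L, contour$centroid)
  # in-plane components only
  vp <- v - outer(drop(v %*% nhat), nhat)
  r <- sqrt(rowSums(vp^2))
  if (any(r < 1e-12))
    stop("zero-radius boundary point: point coincides with the centroid")
  e1 <- unit(vp[gi, ])
  e2 <- cross3(nhat, e1)
  th <- wrap_2pi(atan2(drop(vp %*% e2), drop(vp %*% e1)))
  th[gi] <- 0
  th
}

#' Lagrangian cylindrical surface r(sigma, theta)
#'
#' Samples the radial surface function on the (sigma, theta) grid defined by
#' the contour stack and a Greenwich frame, and carries everything needed to
#' interpolate the surface bilinearly (circular-linear in theta along each
#' contour polygon, then linear in sigma between contours).
#'
#' Within each contour, points are re-ordered to start at the Greenwich
#' point and run counterclockwise about the distal tangent, so theta is
#' strictly increasing from 0. Contours whose stored ordering is clockwise
#' are reversed; contours that are not star-shaped about their centroid
#' (theta not monotone along the polygon) are rejected.
#'
#' @param stack a `tc_stack`.
#' @param frame a `tc_greenwich` frame covering the stack (see
#'   [greenwich_frame()]).
#' @param centerline optional `tc_centerline`; built from the stack with
#'   origin at the frame's Greenwich contour when omitted.
#' @param time_label optional tag identifying the physiological state
#'   (e.g. "systole").
#' @return object of class `tc_surface`: `sigma` (per contour, mm), `theta`
#'   (list of per-point angles), `radii` (list, mm), `points` (list of m x 3
#'   matrices in theta order), `centroids`, `normals`, `centerline`,
#'   `time_label`.
#' @export
cylindrical_surface <- function(stack, frame, centerline = NULL,
                                time_label = NULL) {
  stopifnot(inherits(stack, "tc_stack"), inherits(frame, "tc_greenwich"))
  if (is.null(centerline))
    centerline <- build_centerline(stack, frame$gamma_index)
  n <- stack$n
  theta <- radii <- pts <- perm <- vector("list", n)
  normals <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    ct <- stack$contours[[i]]
    tang <- centerline$tangents[i, ]
    th <- assign_theta(ct, frame$gamma_points[i, ], tang)
    p <- ct$points
    gi <- which(th == 0)[1L]
    idx <- c(gi:nrow(p), seq_len(gi - 1L))[seq_len(nrow(p))]
    th <- th[idx]; p <- p[idx, , drop = FALSE]
    if (any(diff(th) <= 0)) {
      # stored ordering ran clockwise; reverse the loop, keep gamma first
      idx2 <- c(1L, rev(seq_len(nrow(p))[-1L]))
      idx <- idx[idx2]
      th <- th[idx2]; p <- p[idx2, , drop = FALSE]
      if (any(diff(th) <= 0))
        stop(sprintf(
          "contour %d is not star-shaped about its centroid: theta not monotone",
          i))
    }
    perm[[i]] <- idx
    nh <- ct$plane_normal
    if (sum(nh * tang) < 0) nh <- -nh
    normals[i, ] <- nh
    v <- sweep(p, 2L, ct$centroid)
    theta[[i]] <- th
    radii[[i]] <- sqrt(rowSums(v^2))
    pts[[i]] <- p
  }
  structure(list(sigma = centerline$sigma, theta = theta, radii = radii,
                 points = pts, centroids = stack_centroids(stack),
                 normals = normals, centerline = centerline,
                 perm = perm, time_label = time_label),
            class = "tc_surface")
}

#' @export
print.tc_surface <- function(x, ...) {
  cat(sprintf("cylindrical surface: %d contours, sigma in [%.1f, %.1f] mm%s\n",
              length(x$sigma), min(x$sigma), max(x$sigma),
              if (is.null(x$time_label)) "" else paste0(" [t=", x$time_label, "]")))
  invisible(x)
}

# circular-linear interpolation along one contour in theta.
# Returns list(w_lo, w_hi, j_lo, j_hi) usable for both radii and points.
theta_brackets <- function(th, thq) {
  m <- length(th)
  thq <- wrap_2pi(thq)
  j <- findInterval(thq, th)        # th[1] == 0 so j >= 1
  j[j < 1L] <- 1L
  j_hi <- ifelse(j == m, 1L, j + 1L)
  span <- c(diff(th), 2 * pi - th[m])[j]
  t <- (thq - th[j]) / span
  list(j_lo = j, j_hi = j_hi, t = t)
}

contour_radius_at <- function(th, r, thq) {
  b <- theta_brackets(th, thq)
  (1 - b$t) * r[b$j_lo] + b$t * r[b$j_hi]
}

contour_point_at <- function(th, p, thq) {
  b <- theta_brackets(th, thq)
  (1 - b$t) * p[b$j_lo, , drop = FALSE] + b$t * p[b$j_hi, , drop = FALSE]
}

sigma_brackets <- function(surface, sq) {
  s <- surface$sigma
  if (any(sq < s[1L] - 1e-9 | sq > s[length(s)] + 1e-9))
    stop(sprintf("sigma out of domain [%.3f, %.3f] mm", s[1L], s[length(s)]))
  sq <- pmin(pmax(sq, s[1L]), s[length(s)])
  i <- findInterval(sq, s, rightmost.closed = TRUE)
  i[i >= length(s)] <- length(s) - 1L
  f <- (sq - s[i]) / (s[i + 1L] - s[i])
  list(i = i, f = f, sq = sq)
}

#' Evaluate the radial surface function
#'
#' Bilinear interpolation of r(sigma, theta): circular linear interpolation
#' in theta within each of the two bracketing contours, then linear in
#' sigma. Evaluation at a stored sample reproduces the stored radius
#' exactly.
#'
#' @param surface a `tc_surface`.
#' @param sigma,theta numeric vectors (recycled to a common length); sigma
#'   in mm within the surface's sigma range, theta in radians (wrapped
#'   mod 2*pi).
#' @return radius in mm.
#' @export
evaluate_surface <- function(surface, sigma, theta) {
  k <- max(length(sigma), length(theta))
  sigma <- rep_len(sigma, k); theta <- rep_len(theta, k)
  sb <- sigma_brackets(surface, sigma)
  out <- numeric(k)
  for (grp in split(seq_len(k), sb$i)) {
    i <- sb$i[grp[1L]]
    r_lo <- contour_radius_at(surface$theta[[i]], surface$radii[[i]], theta[grp])
    r_hi <- contour_radius_at(surface$theta[[i + 1L]], surface$radii[[i + 1L]],
                              theta[grp])
    out[grp] <- (1 - sb$f[grp]) * r_lo + sb$f[grp] * r_hi
  }
  out
}

#' 3D location of a surface coordinate
#'
#' Maps (sigma, theta) back to Cartesian space: within each bracketing
#' contour the point at angular coordinate theta is found by linear
#' interpolation along the contour polygon (between the two boundary points
#' bracketing theta), and the two in-plane points are blended linearly in
#' sigma. At a stored sample the stored boundary point is returned exactly.
#'
#' @inheritParams evaluate_surface
#' @return k x 3 matrix of points (mm).
#' @export
surface_point <- function(surface, sigma, theta) {
  k <- max(length(sigma), length(theta))
  sigma <- rep_len(sigma, k); theta <- rep_len(theta, k)
  sb <- sigma_brackets(surface, sigma)
  out <- matrix(0, k, 3L)
  for (grp in split(seq_len(k), sb$i)) {
    i <- sb$i[grp[1L]]
    p_lo <- contour_point_at(surface$theta[[i]], surface$points[[i]], theta[grp])
    p_hi <- contour_point_at(surface$theta[[i + 1L]], surface$points[[i + 1L]],
                             theta[grp])
    out[grp, ] <- (1 - sb$f[grp]) * p_lo + sb$f[grp] * p_hi
  }
  dimnames(out) <- list(NULL, c("x", "y", "z"))
  out
}
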