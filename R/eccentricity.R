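# Generalized cross-sectional eccentricity: orthogonal centroid diameters
# minimizing d/D, e = sqrt(1 - d^2/D^2), and the orientation of the major
# diameter relative to the Greenwich direction.

# in-plane orthonormal basis for a contour; e1 from the first boundary point
contour_basis <- function(contour) {
  nhat <- contour$plane_normal
  v1 <- contour$points[1L, ] - contour$centroid
  v1 <- v1 - sum(v1 * nhat) * nhat
  e1 <- unit(v1)
  list(e1 = e1, e2 = cross3(nhat, e1), nhat = nhat)
}

# 2D coordinates of the boundary relative to the centroid
contour_2d <- function(contour, basis = contour_basis(contour)) {
  v <- sweep(contour$points, 2L, contour$centroid)
  cbind(drop(v %*% basis$e1), drop(v %*% basis$e2))
}

# chord lengths through the origin for a vector of direction angles phi,
# on the closed 2D polygon `p2` (m x 2, centroid at origin). For each ray
# the *farthest* boundary intersection is used, so non-convex wiggles do
# not truncate a diameter.
polygon_chords <- function(p2, phi) {
  m <- nrow(p2)
  P1 <- p2
  dd <- p2[c(2:m, 1L), , drop = FALSE] - p2
  cphi <- cos(phi); sphi <- sin(phi)
  # cross(u, P1) and cross(u, d) for every (phi, edge)
  cu_p1 <- outer(cphi, P1[, 2L]) - outer(sphi, P1[, 1L])
  cu_d <- outer(cphi, dd[, 2L]) - outer(sphi, dd[, 1L])
  s <- -cu_p1 / cu_d
  # s tolerance admits rays passing exactly through a polygon vertex
  valid <- is.finite(s) & s >= -1e-9 & s <= 1 + 1e-9 & abs(cu_d) > 1e-14
  px <- matrix(P1[, 1L], length(phi), m, byrow = TRUE) +
    s * matrix(dd[, 1L], length(phi), m, byrow = TRUE)
  py <- matrix(P1[, 2L], length(phi), m, byrow = TRUE) +
    s * matrix(dd[, 2L], length(phi), m, byrow = TRUE)
  t <- cphi * px + sphi * py
  t[!valid] <- NA_real_
  tp <- apply(t, 1L, function(r) suppressWarnings(max(r[r > 1e-12], na.rm = TRUE)))
  tm <- apply(t, 1L, function(r) suppressWarnings(max(-r[r < -1e-12], na.rm = TRUE)))
  if (any(!is.finite(tp)) || any(!is.finite(tm)))
    stop("centroid-outside error: a centroid ray does not hit the boundary")
  tp + tm
}

is_convex_polygon <- function(p2) {
  m <- nrow(p2)
  d <- p2[c(2:m, 1L), ] - p2
  cr <- d[, 1L] * d[c(2:m, 1L), 2L] - d[, 2L] * d[c(2:m, 1L), 1L]
  all(cr >= -1e-9 * max(abs(cr))) || all(cr <= 1e-9 * max(abs(cr)))
}

#' Chord of a contour through its centroid
#'
#' Length of the chord collinear with the centroid along a given in-plane
#' direction: for each of the two opposite rays, the farthest intersection
#' with the closed boundary polygon; the chord is the sum of the two ray
#' distances.
#'
#' @param contour a `tc_contour`.
#' @param direction in-plane direction (length-3; its out-of-plane
#'   component is removed).
#' @return chord length in mm.
#' @export
chord_through_centroid <- function(contour, direction) {
  b <- contour_basis(contour)
  d <- as_point3(direction)
  d <- d - sum(d * b$nhat) * b$nhat
  if (vnorm(d) < 1e-12) stop("direction has no in-plane component")
  phi <- atan2(sum(d * b$e2), sum(d * b$e1))
  polygon_chords(contour_2d(contour, b), phi)
}

#' Generalized eccentricity of a cross section
#'
#' Scans orientation phi over [0, pi) and, for each phi, measures the two
#' orthogonal centroid chords (phi, phi + pi/2). The pair minimizing the
#' ratio d/D defines the major diameter D (the longer chord), minor
#' diameter d, and eccentricity e = sqrt(1 - d^2/D^2). Ties go to the
#' smallest phi. A circle (and any shape whose orthogonal chords are always
#' equal, e.g. a square) has e = 0.
#'
#' @param contour a `tc_contour`.
#' @param angular_step scan resolution in radians (default pi/720).
#' @return list of class `tc_ecc`: `D`, `d` (mm), `e`, `major_direction`
#'   (3D unit vector in the contour plane), `phi` (scan angle of the
#'   minimizing pair), `theta_e` (NA until [orientation()] is applied).
#' @export
eccentricity <- function(contour, angular_step = pi / 720) {
  stopifnot(inherits(contour, "tc_contour"), angular_step > 0,
            angular_step <= pi / 2)
  b <- contour_basis(contour)
  p2 <- contour_2d(contour, b)
  if (!is_convex_polygon(p2))
    warning(sprintf("contour %d is non-convex; farthest-intersection chords used",
                    contour$index))
  phis <- seq(0, pi - angular_step / 2, by = angular_step)
  c1 <- polygon_chords(p2, phis)
  c2 <- polygon_chords(p2, phis + pi / 2)
  D <- pmax(c1, c2); d <- pmin(c1, c2)
  best <- which.min(d / D)           # first minimum = smallest phi
  phi_maj <- if (c1[best] >= c2[best]) phis[best] else phis[best] + pi / 2
  structure(list(D = D[best], d = d[best],
                 e = sqrt(max(0, 1 - (d[best] / D[best])^2)),
                 major_direction = cos(phi_maj) * b$e1 + sin(phi_maj) * b$e2,
                 phi = phis[best], theta_e = NA_real_),
            class = "tc_ecc")
}

#' Orientation of eccentricity
#'
#' The positive angle theta_e between the major diameter and the in-plane
#' Greenwich direction (gamma_i - C_i). A diameter is undirected, so the
#' angle is folded: of the two representatives, the one in [0, pi/2] is
#' reported (e.g. a major axis at 3*pi/4 from the Greenwich direction folds
#' to pi/4). For a contour with numerically zero eccentricity (e below
#' 1e-6, e.g. a sampled circle) the major axis, and hence theta_e, is
#' undefined and NA is returned.
#'
#' @param record a `tc_ecc` from [eccentricity()].
#' @param contour the same contour.
#' @param gamma_i the contour's Greenwich point.
#' @return the record with `theta_e` filled in (radians).
#' @export
orientation <- function(record, contour, gamma_i) {
  stopifnot(inherits(record, "tc_ecc"), inherits(contour, "tc_contour"))
  if (record$e < 1e-6) {
    message(sprintf("contour %d: e = 0, orientation undefined", contour$index))
    record$theta_e <- NA_real_
    return(record)
  }
  nhat <- contour$plane_normal
  g <- as_point3(gamma_i) - contour$centroid
  g <- g - sum(g * nhat) * nhat
  u <- record$major_direction
  ang <- acos(min(1, max(-1, sum(unit(g) * unit(u)))))
  record$theta_e <- min(ang, pi - ang)
  record
}

#' Eccentricity profile along the vessel
#'
#' One eccentricity record per contour, ordered by sigma, with orientation
#' computed against the Greenwich frame.
#'
#' @param stack a `tc_stack`.
#' @param frame matching `tc_greenwich`.
#' @param angular_step scan resolution (radians).
#' @param centerline optional `tc_centerline` (built from the frame when
#'   omitted).
#' @return data frame of class `tc_ecc_profile` with columns `i`, `sigma`
#'   (mm), `D_mm`, `d_mm`, `e`, `theta_e` (rad, NA where undefined);
#'   attribute `major_directions` holds the n x 3 major-axis vectors.
#' @export
eccentricity_profile <- function(stack, frame, angular_step = pi / 720,
                                 centerline = NULL) {
  stopifnot(inherits(stack, "tc_stack"), inherits(frame, "tc_greenwich"))
  if (is.null(centerline))
    centerline <- build_centerline(stack, frame$gamma_index)
  recs <- lapply(seq_len(stack$n), function(i) {
    r <- eccentricity(stack$contours[[i]], angular_step)
    orientation(r, stack$contours[[i]], frame$gamma_points[i, ])
  })
  out <- data.frame(
    i = seq_len(stack$n),
    sigma = centerline$sigma,
    D_mm = vapply(recs, `[[`, numeric(1L), "D"),
    d_mm = vapply(recs, `[[`, numeric(1L), "d"),
    e = vapply(recs, `[[`, numeric(1L), "e"),
    theta_e = vapply(recs, `[[`, numeric(1L), "theta_e"))
  attr(out, "major_directions") <-
    do.call(rbind, lapply(recs, `[[`, "major_direction"))
  class(out) <- c("tc_ecc_profile", "data.frame")
  out
}

#' Spirality of eccentricity
#'
#' Rate of change of the orientation of eccentricity with arc length,
#' d theta_e / d sigma, by central finite differences of the unwrapped
#' orientation (period pi, since a diameter returns to itself after half a
#' turn). Contours with undefined theta_e are skipped; the gap is logged.
#'
#' @param profile a `tc_ecc_profile` with at least 3 defined `theta_e`.
#' @return data frame with `sigma` (mm) and `spirality` (rad/mm) at the
#'   interior contours of the defined set.
#' @export
spirality <- function(profile) {
  ok <- which(!is.na(profile$theta_e))
  if (length(ok) < 3L)
    stop("spirality needs at least 3 contours with defined theta_e")
  if (length(ok) < nrow(profile))
    message(sprintf("spirality: skipping %d contours with undefined theta_e",
                    nrow(profile) - length(ok)))
  s <- profile$sigma[ok]
  y <- profile$theta_e[ok]
  for (i in seq_along(y)[-1L])        # unwrap on period pi
    y[i] <- y[i] + pi * round((y[i - 1L] - y[i]) / pi)
  k <- 2:(length(y) - 1L)
  data.frame(sigma = s[k],
             spirality = (y[k + 1L] - y[k - 1L]) / (s[k + 1L] - s[k - 1L]))
}
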