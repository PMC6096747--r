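# Pointwise surface curvature by windowed three-point circle fitting.
# Curvature magnitude = 1/R of the circle through a surface point and its
# two symmetric window neighbors along sigma (longitudinal) or theta
# (circumferential). Reported in 1/cm by default (coordinates are mm, so
# kappa[1/cm] = 10 * kappa[1/mm]).

unit_scale <- function(units = c("cm", "mm")) {
  units <- match.arg(units)
  if (units == "cm") 10 else 1
}

#' Curvature of the circle through three points
#'
#' The magnitude of curvature at a surface point is the reciprocal of the
#' radius of the unique circle through the point and its two window
#' neighbors, via the circumradius R = (a b c) / (4 A) with a, b, c the
#' triangle side lengths and A its area. Collinear points (area below
#' 1e-12 x max side squared) give curvature 0; coincident points are a
#' degenerate input.
#'
#' @param p1,p2,p3 three distinct points (length-3 numeric).
#' @return curvature in reciprocal input units (1/mm for mm coordinates).
#' @export
circle_fit_curvature <- function(p1, p2, p3) {
  k <- circle_fit_kappa(rbind(as_point3(p1)), rbind(as_point3(p2)),
                        rbind(as_point3(p3)))
  if (is.na(k)) stop("degenerate input: coincident points in circle fit")
  k
}

# vectorized core: rows of P1, P2, P3; coincident rows -> NA, collinear -> 0
circle_fit_kappa <- function(P1, P2, P3) {
  u <- P2 - P1; v <- P3 - P1; w <- P3 - P2
  a <- sqrt(rowSums(u^2)); b <- sqrt(rowSums(v^2)); cc <- sqrt(rowSums(w^2))
  cr <- cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
              u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
              u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  area2 <- sqrt(rowSums(cr^2))            # 2 * triangle area
  mx <- pmax(a, b, cc)
  kappa <- ifelse(area2 / 2 < 1e-12 * mx^2, 0, 2 * area2 / (a * b * cc))
  kappa[pmin(a, b, cc) < 1e-12] <- NA_real_
  kappa
}

#' Longitudinal surface curvature at one coordinate
#'
#' Circle fit through the surface points at (sigma0 - w/2, theta0),
#' (sigma0, theta0), (sigma0 + w/2, theta0). The window is the full span
#' between the two outer points, symmetric about the center.
#'
#' @param surface a `tc_surface`.
#' @param sigma0 center sigma (mm); sigma0 +/- window/2 must lie in the
#'   surface's sigma range.
#' @param theta0 angular coordinate (rad).
#' @param window full longitudinal span in mm (default 30).
#' @param units "cm" (default) or "mm" for the reciprocal-length unit.
#' @return curvature magnitude.
#' @export
longitudinal_curvature <- function(surface, sigma0, theta0, window = 30,
                                   units = c("cm", "mm")) {
  stopifnot(window > 0)
  P <- surface_point(surface,
                     c(sigma0 - window / 2, sigma0, sigma0 + window / 2),
                     theta0)
  circle_fit_curvature(P[1L, ], P[2L, ], P[3L, ]) * unit_scale(units)
}

#' Circumferential surface curvature at one coordinate
#'
#' Circle fit through the points of the interpolated contour at sigma0, at
#' angular coordinates theta0 - w/2, theta0, theta0 + w/2 (theta wraps
#' circularly, so any window in (0, pi) is valid anywhere).
#'
#' @inheritParams longitudinal_curvature
#' @param window full angular span in radians, in (0, pi); default pi/4.
#' @export
circumferential_curvature <- function(surface, sigma0, theta0,
                                      window = pi / 4,
                                      units = c("cm", "mm")) {
  stopifnot(window > 0, window < pi)
  P <- surface_point(surface, sigma0,
                     c(theta0 - window / 2, theta0, theta0 + window / 2))
  circle_fit_curvature(P[1L, ], P[2L, ], P[3L, ]) * unit_scale(units)
}

#' Pointwise curvature field on the surface grid
#'
#' Evaluates the directional curvature at every stored (sigma_i, theta_ij)
#' grid node. Longitudinal nodes whose window would extend beyond either
#' sigma end are masked (NA) rather than computed one-sided; nodes whose
#' circle fit is degenerate (coincident surface points) are masked too.
#'
#' @param surface a `tc_surface`.
#' @param direction "longitudinal" or "circumferential".
#' @param window full window span: mm for longitudinal (default 30),
#'   radians for circumferential (default pi/4).
#' @param units "cm" (default) or "mm".
#' @return object of class `tc_field`: `direction`, `window`, `units`,
#'   `sigma`, `theta` (list), `values` (list of per-contour curvature
#'   vectors, NA where masked).
#' @export
curvature_field <- function(surface,
                            direction = c("longitudinal", "circumferential"),
                            window = NULL, units = c("cm", "mm")) {
  direction <- match.arg(direction)
  units <- match.arg(units)
  if (is.null(window)) window <- if (direction == "longitudinal") 30 else pi / 4
  stopifnot(window > 0)
  n <- length(surface$sigma)
  values <- vector("list", n)
  scale <- unit_scale(units)
  srange <- range(surface$sigma)
  for (i in seq_len(n)) {
    th <- surface$theta[[i]]
    s0 <- surface$sigma[i]
    if (direction == "longitudinal") {
      if (s0 - window / 2 < srange[1L] || s0 + window / 2 > srange[2L]) {
        values[[i]] <- rep(NA_real_, length(th))
        next
      }
      P1 <- surface_point(surface, s0 - window / 2, th)
      P2 <- surface$points[[i]]
      P3 <- surface_point(surface, s0 + window / 2, th)
    } else {
      P1 <- contour_point_at(th, surface$points[[i]], th - window / 2)
      P2 <- surface$points[[i]]
      P3 <- contour_point_at(th, surface$points[[i]], th + window / 2)
    }
    values[[i]] <- circle_fit_kappa(P1, P2, P3) * scale
  }
  structure(list(direction = direction, window = window, units = units,
                 sigma = surface$sigma, theta = surface$theta,
                 values = values),
            class = "tc_field")
}

#' @export
print.tc_field <- function(x, ...) {
  v <- unlist(x$values)
  cat(sprintf(
    "%s curvature field: %d contours, window %.3g %s, range [%.3g, %.3g] %s^-1 (%d masked)\n",
    x$direction, length(x$sigma), x$window,
    if (x$direction == "longitudinal") "mm" else "rad",
    min(v, na.rm = TRUE), max(v, na.rm = TRUE), x$units, sum(is.na(v))))
  invisible(x)
}

same_grid <- function(a, b) {
  length(a$sigma) == length(b$sigma) &&
    all(vapply(a$theta, length, integer(1L)) ==
          vapply(b$theta, length, integer(1L)))
}

#' Gaussian- and mean-curvature proxies
#'
#' The pointwise product and mean of the longitudinal and circumferential
#' curvature magnitudes serve as proxies for the Gaussian and mean
#' curvature. Defined only where both parent fields are defined.
#'
#' @param long_field,circ_field `tc_field` objects on the same grid and in
#'   the same units.
#' @return list of class `tc_proxy`: `gaussian_proxy` and `mean_proxy`
#'   (lists matching the grid), `units` (e.g. "cm" meaning cm^-2 for the
#'   product, cm^-1 for the mean), `sigma`, `theta`.
#' @export
proxy_fields <- function(long_field, circ_field) {
  stopifnot(inherits(long_field, "tc_field"), inherits(circ_field, "tc_field"))
  if (!same_grid(long_field, circ_field) ||
      long_field$units != circ_field$units)
    stop("alignment error: proxy fields need the same grid and units")
  g <- Map(function(a, b) a * b, long_field$values, circ_field$values)
  m <- Map(function(a, b) (a + b) / 2, long_field$values, circ_field$values)
  structure(list(gaussian_proxy = g, mean_proxy = m,
                 units = long_field$units, sigma = long_field$sigma,
                 theta = long_field$theta),
            class = "tc_proxy")
}

#' Pointwise absolute difference between two curvature fields
#'
#' Compares two fields with the same Lagrangian grid topology (same number
#' of contours and points per contour; typically two physiological states
#' of the same vessel). Sigma ranges may differ between states; the
#' difference is restricted to contours whose sigma lies in the overlap of
#' both ranges in both fields.
#'
#' @param field_a,field_b `tc_field` objects, same direction and units.
#' @return `tc_field` (direction tagged "difference of <direction>") of
#'   |kappa_a - kappa_b| on the common grid, with `sigma` from `field_a`.
#' @export
difference_field <- function(field_a, field_b) {
  stopifnot(inherits(field_a, "tc_field"), inherits(field_b, "tc_field"))
  if (!same_grid(field_a, field_b) ||
      field_a$direction != field_b$direction ||
      field_a$units != field_b$units)
    stop("alignment error: fields have incompatible grids")
  lo <- max(min(field_a$sigma), min(field_b$sigma))
  hi <- min(max(field_a$sigma), max(field_b$sigma))
  if (lo > hi) stop("alignment error: sigma ranges are disjoint")
  keep <- which(field_a$sigma >= lo - 1e-9 & field_a$sigma <= hi + 1e-9 &
                  field_b$sigma >= lo - 1e-9 & field_b$sigma <= hi + 1e-9)
  if (!length(keep)) stop("alignment error: sigma ranges are disjoint")
  vals <- Map(function(a, b) abs(a - b),
              field_a$values[keep], field_b$values[keep])
  structure(list(direction = paste("difference of", field_a$direction),
                 window = field_a$window, units = field_a$units,
                 sigma = field_a$sigma[keep], theta = field_a$theta[keep],
                 values = vals),
            class = "tc_field")
}

#' @export
as.data.frame.tc_field <- function(x, ...) {
  n <- length(x$sigma)
  do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(i = i, j = seq_along(x$theta[[i]]), sigma = x$sigma[i],
               theta = x$theta[[i]], value = x$values[[i]])
  }))
}
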