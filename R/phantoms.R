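# Idealized software phantoms with known analytic geometry: a simple tube
# with one 90-degree bend and circular cross sections, and a complex tube
# with two 90-degree bends in different planes, elliptical cross sections,
# and a circular transition where the ellipse axes swap. Both carry a small
# daughter-branch stub so the bifurcation fiducial machinery can be
# exercised end to end.

# --- centerline path machinery -------------------------------------------
# A path is a list of segments, each with an analytic frame: position P,
# tangent T, and cross-section axes U, V (right-handed, T = U x V). Arcs of
# radius R turn toward the in-plane unit direction W = wu*U + wv*V; the
# frame is rotated rigidly with the tangent (no twist).

path_build <- function(segments) {
  P <- c(0, 0, 0)
  Rf <- cbind(U = c(1, 0, 0), V = c(0, 1, 0), T = c(0, 0, 1))
  s0 <- 0
  out <- vector("list", length(segments))
  for (i in seq_along(segments)) {
    sg <- segments[[i]]
    len <- if (sg$type == "straight") sg$length else sg$radius * sg$angle
    out[[i]] <- c(sg, list(P0 = P, R0 = Rf, s0 = s0, s1 = s0 + len))
    if (sg$type == "straight") {
      P <- P + len * Rf[, "T"]
    } else {
      W <- sg$turn[1L] * Rf[, "U"] + sg$turn[2L] * Rf[, "V"]
      A <- cross3(Rf[, "T"], W)
      a <- sg$angle
      P <- P + sg$radius * (W * (1 - cos(a)) + Rf[, "T"] * sin(a))
      Rf <- t(rotate_about(t(Rf), A, a))
    }
    s0 <- s0 + len
  }
  out
}

path_frame <- function(path, s) {
  tot <- path[[length(path)]]$s1
  if (s < -1e-9 || s > tot + 1e-9) stop("arc length outside path")
  s <- min(max(s, 0), tot)
  i <- 1L
  while (i < length(path) && s > path[[i]]$s1 + 1e-12) i <- i + 1L
  sg <- path[[i]]
  ds <- s - sg$s0
  if (sg$type == "straight") {
    list(P = sg$P0 + ds * sg$R0[, "T"], R = sg$R0, segment = sg$name)
  } else {
    W <- sg$turn[1L] * sg$R0[, "U"] + sg$turn[2L] * sg$R0[, "V"]
    A <- cross3(sg$R0[, "T"], W)
    a <- ds / sg$radius
    P <- sg$P0 + sg$radius * (W * (1 - cos(a)) + sg$R0[, "T"] * sin(a))
    list(P = P, R = t(rotate_about(t(sg$R0), A, a)), segment = sg$name)
  }
}

# Stations every `spacing` mm. The cross section at arc length s is an
# ellipse with semi-axis `sb` along the (possibly rotated) minor direction
# N = cos(psi) U - sin(psi) V and `sa` along the major direction
# M = sin(psi) U + cos(psi) V; points are sampled uniformly in the ellipse
# parameter t, with point j = 1 at the minor vertex sb * N (the +U side
# when psi = 0, where the branch stub pins the Greenwich point).
path_stack <- function(path, spacing, mpts, shape_fun, jitter_sd = 0,
                       seed = NULL) {
  tot <- path[[length(path)]]$s1
  svec <- seq(0, tot + 1e-9, by = spacing)
  svec <- svec[svec <= tot + 1e-9]
  t <- 2 * pi * (seq_len(mpts) - 1L) / mpts
  if (jitter_sd > 0 && !is.null(seed)) set.seed(seed)
  contours <- lapply(seq_along(svec), function(i) {
    fr <- path_frame(path, svec[i])
    sh <- shape_fun(svec[i])
    Nv <- cos(sh$psi) * fr$R[, "U"] - sin(sh$psi) * fr$R[, "V"]
    Mv <- sin(sh$psi) * fr$R[, "U"] + cos(sh$psi) * fr$R[, "V"]
    p <- sweep(outer(sh$sb * cos(t), Nv) +
                 outer(sh$sa * sin(t), Mv), 2L, fr$P, "+")
    if (jitter_sd > 0)
      p <- p + matrix(stats::rnorm(length(p), 0, jitter_sd), nrow(p), 3L)
    contour3d(p, index = i)
  })
  list(stack = contour_stack(contours), s = svec,
       segment = vapply(svec, function(s) path_frame(path, s)$segment,
                        character(1L)))
}

# Daughter-branch stub: a tube of radius `radius` whose axis runs along the
# mother's +U direction at station s_touch, positioned so the stub's top
# boundary line is tangent to the mother surface, with an exact point
# coincidence at the mother's theta = 0 boundary point. Mother assumed
# straight (stub sits on a straight leg).
branch_stub <- function(path, s_touch, mother_semi_u, radius = 6,
                        length = 15, spacing = 3, mpts = 48) {
  fr <- path_frame(path, s_touch)
  U <- fr$R[, "U"]; V <- fr$R[, "V"]; Tn <- fr$R[, "T"]
  axis0 <- fr$P + mother_semi_u * U - radius * Tn
  phis <- 2 * pi * (seq_len(mpts) - 1L) / mpts
  xs <- seq(0, length, by = spacing)
  contours <- lapply(seq_along(xs), function(i) {
    ctr <- axis0 + xs[i] * U
    p <- sweep(outer(radius * cos(phis), Tn) +
                 outer(radius * sin(phis), V), 2L, ctr, "+")
    contour3d(p, index = i)
  })
  contour_stack(contours)
}

# curvature of the ellipse (sb along N, sa along M) at parameter t, 1/mm
ellipse_kappa_mm <- function(sa, sb, t) {
  (sa * sb) / ((sb * sin(t))^2 + (sa * cos(t))^2)^1.5
}

# Analytic per-node references, aligned to the generation grid (point j = 1
# at the minor vertex, pinned to theta = 0 by the branch stub proximally).
make_reference <- function(gen, path, mpts, shape_fun) {
  t <- 2 * pi * (seq_len(mpts) - 1L) / mpts
  n <- length(gen$s)
  long <- circ <- vector("list", n)
  e <- th_e <- numeric(n)
  for (i in seq_len(n)) {
    s <- gen$s[i]
    sh <- shape_fun(s)
    sg <- Find(function(g) s >= g$s0 - 1e-9 && s <= g$s1 + 1e-9, path)
    if (sg$type == "straight") {
      long[[i]] <- rep(0, mpts)
    } else {
      # track radius at material point t: R - offset along W (toward center)
      off_u <- sh$sb * cos(t) * cos(sh$psi) + sh$sa * sin(t) * sin(sh$psi)
      off_v <- -sh$sb * cos(t) * sin(sh$psi) + sh$sa * sin(t) * cos(sh$psi)
      rad <- sg$radius - (sg$turn[1L] * off_u + sg$turn[2L] * off_v)
      long[[i]] <- ifelse(rad > 1e-9, 10 / rad, NA_real_)   # cm^-1
    }
    circ[[i]] <- 10 * ellipse_kappa_mm(sh$sa, sh$sb, t)
    mx <- max(sh$sa, sh$sb); mn <- min(sh$sa, sh$sb)
    e[i] <- sqrt(max(0, 1 - (mn / mx)^2))
    # major axis M is at pi/2 - psi from the +U Greenwich track, folded
    th_e[i] <- if (abs(sh$sa - sh$sb) < 1e-9) NA_real_
      else min(abs(pi / 2 - sh$psi), pi - abs(pi / 2 - sh$psi))
  }
  bounds <- do.call(rbind, lapply(path, function(g)
    data.frame(name = g$name, type = g$type, s0 = g$s0, s1 = g$s1)))
  structure(list(s = gen$s, segment = gen$segment, long = long, circ = circ,
                 e = e, theta_e = th_e, segments = bounds, mpts = mpts),
            class = "tc_reference")
}

#' Align analytic reference fields to a surface grid
#'
#' Phantom references are stored in generation point order; a
#' `tc_surface` re-orders each contour's points to start at the Greenwich
#' point. This applies the surface's per-contour permutation to the
#' per-node reference vectors so reference and computed field line up node
#' by node.
#'
#' @param reference a `tc_reference`.
#' @param surface the `tc_surface` built from the same phantom stack.
#' @return the reference with `long` and `circ` permuted to the surface
#'   grid.
#' @export
align_reference <- function(reference, surface) {
  stopifnot(inherits(reference, "tc_reference"), inherits(surface, "tc_surface"))
  if (length(surface$perm) != length(reference$long))
    stop("reference and surface have different contour counts")
  reference$long <- Map(function(v, p) v[p], reference$long, surface$perm)
  reference$circ <- Map(function(v, p) v[p], reference$circ, surface$perm)
  reference
}

#' Longitudinal reference mask for a given window
#'
#' A three-point circle fit with full span `window` only sees the pure
#' analytic geometry when the whole window lies inside one path segment;
#' nodes whose window straddles a segment boundary (bend/straight junction
#' or shape transition) have no closed-form reference and are masked.
#'
#' @param reference a `tc_reference`.
#' @param window longitudinal window (mm).
#' @return logical vector per contour, TRUE where the reference is valid.
#' @export
reference_long_mask <- function(reference, window) {
  vapply(seq_along(reference$s), function(i) {
    s <- reference$s[i]
    seg <- reference$segments[reference$segments$name == reference$segment[i], ]
    s - window / 2 >= seg$s0 - 1e-9 && s + window / 2 <= seg$s1 + 1e-9
  }, logical(1L))
}

#' Simple software phantom
#'
#' A tube with uniform circular cross sections (default radius 10 mm), two
#' straight legs (60 mm) joined by a 90-degree bend of centerline radius
#' 30 mm, so the inner and outer surface tracks have 20 and 40 mm radius of
#' curvature (0.5 and 0.25 cm^-1). Contours are spaced every half radius
#' (5 mm) with 96 points each, exactly orthogonal to the analytic
#' centerline. A 6 mm branch stub on the proximal leg provides the
#' bifurcation fiducial; it pins the Greenwich direction to the inner side
#' of the bend.
#'
#' @param radius cross-section radius (mm).
#' @param bend_radius centerline radius of the bend (mm); must exceed
#'   `radius`.
#' @param straight length of each straight leg (mm).
#' @param spacing contour spacing (mm).
#' @param points_per_contour points per contour (>= 16).
#' @param branch_at arc length of the branch stub on the proximal leg (mm).
#' @param jitter_sd optional Gaussian point jitter (mm, default 0).
#' @param seed RNG seed for the jitter.
#' @return list with `mother` (`tc_stack`), `branch` (`tc_stack`),
#'   `reference` (`tc_reference`), `s` (arc length per contour), `segment`
#'   (segment name per contour).
#' @export
generate_simple <- function(radius = 10, bend_radius = 30, straight = 60,
                            spacing = 5, points_per_contour = 96,
                            branch_at = 30, jitter_sd = 0, seed = NULL) {
  stopifnot(spacing > 0, points_per_contour >= 16L, radius > 0,
            bend_radius > 0, straight > 0)
  if (radius > bend_radius)
    stop("degenerate phantom: cross-section radius exceeds the bend radius")
  if (radius == bend_radius)
    message("inner surface radius is 0: the bend pinches to a point on the inner track")
  path <- path_build(list(
    list(type = "straight", length = straight, name = "proximal"),
    list(type = "arc", radius = bend_radius, angle = pi / 2,
         turn = c(1, 0), name = "bend"),
    list(type = "straight", length = straight, name = "distal")))
  shape <- function(s) list(sa = radius, sb = radius, psi = 0)
  gen <- path_stack(path, spacing, points_per_contour, shape,
                    jitter_sd = jitter_sd, seed = seed)
  list(mother = gen$stack,
       branch = branch_stub(path, branch_at, radius),
       reference = make_reference(gen, path, points_per_contour, shape),
       s = gen$s, segment = gen$segment)
}

#' Complex software phantom
#'
#' A tube with elliptical cross sections (40 mm major, 20 mm minor
#' diameter; minor semi-axis in each bend plane), two 90-degree bends in
#' orthogonal planes, and a smooth shape transition through a circular
#' cross section where the ellipse axes swap (so eccentricity dips toward 0
#' and the orientation of eccentricity flips from pi/2 to 0). The first
#' bend has centerline radius 10 mm (outer surface track 20 mm radius, 0.5
#' cm^-1; the inner track pinches to a point), the second 20 mm (inner
#' surface track 10 mm radius, 1.0 cm^-1). The transition is centered 96 mm
#' distal to the branch stub that anchors the Greenwich frame.
#'
#' @param semi_major,semi_minor ellipse semi-axes (mm).
#' @param bend1_radius,bend2_radius centerline bend radii (mm).
#' @param straight1 proximal straight length (mm).
#' @param branch_at arc length of the branch stub (mm).
#' @param transition_center arc length of the transition center measured
#'   from the branch station (mm); the paper-facing default places it at
#'   sigma = 96.
#' @param transition_length full transition length (mm).
#' @param straight3 distal straight length (mm).
#' @param spacing,points_per_contour,jitter_sd,seed as in
#'   [generate_simple()].
#' @return as [generate_simple()].
#' @export
generate_complex <- function(semi_major = 20, semi_minor = 10,
                             bend1_radius = 10, bend2_radius = 20,
                             straight1 = 40, branch_at = 20,
                             transition_center = 96, transition_length = 10,
                             straight3 = 40, spacing = 5,
                             points_per_contour = 96, jitter_sd = 0,
                             seed = NULL) {
  stopifnot(semi_major > 0, semi_minor > 0, semi_major >= semi_minor,
            spacing > 0, points_per_contour >= 16L)
  if (semi_minor > bend1_radius || semi_minor > bend2_radius)
    stop("degenerate phantom: in-plane semi-axis exceeds a bend radius")
  s_b1 <- straight1
  s_b1e <- s_b1 + bend1_radius * pi / 2
  tc <- branch_at + transition_center          # transition center, arc length
  t0 <- tc - transition_length / 2
  t1 <- tc + transition_length / 2
  if (t0 <= s_b1e + spacing)
    stop("transition overlaps the first bend; lengthen straight1 or move it")
  mid2 <- 2 * spacing                          # straight run after transition
  s_b2 <- t1 + mid2 + (spacing - (t1 + mid2) %% spacing) %% spacing
  path <- path_build(list(
    list(type = "straight", length = s_b1, name = "proximal"),
    list(type = "arc", radius = bend1_radius, angle = pi / 2,
         turn = c(-1, 0), name = "bend1"),
    list(type = "straight", length = t0 - s_b1e, name = "mid_a"),
    list(type = "straight", length = transition_length, name = "transition"),
    list(type = "straight", length = s_b2 - t1, name = "mid_b"),
    list(type = "arc", radius = bend2_radius, angle = pi / 2,
         turn = c(0, 1), name = "bend2"),
    list(type = "straight", length = straight3, name = "distal")))
  # Smooth twist through a circular cross section, in three phases: the
  # section first blends to a circle (orientation fixed), the pi/2 twist
  # happens entirely while the section is circular (the only shape with no
  # defined orientation, so the twist introduces no material ambiguity and
  # Greenwich propagation cannot be dragged along by a rotating major
  # axis), then the section blends back to the full ellipse with the axes
  # swapped. Eccentricity dips to 0 in the circular throat and the
  # orientation flips from pi/2 to 0 across it.
  ramp <- function(x) 0.5 * (1 - cos(pi * min(1, max(0, x))))
  shape <- function(s) {
    u <- (s - t0) / transition_length
    half <- (semi_major - semi_minor) / 2
    if (u <= 0) list(sa = semi_major, sb = semi_minor, psi = 0)
    else if (u >= 1) list(sa = semi_major, sb = semi_minor, psi = pi / 2)
    else if (u < 1 / 3) {
      w <- half * ramp(3 * u)
      list(sa = semi_major - w, sb = semi_minor + w, psi = 0)
    } else if (u <= 2 / 3) {
      list(sa = semi_major - half, sb = semi_minor + half,
           psi = pi / 2 * ramp(3 * u - 1))
    } else {
      w <- half * (1 - ramp(3 * u - 2))
      list(sa = semi_major - w, sb = semi_minor + w, psi = pi / 2)
    }
  }
  gen <- path_stack(path, spacing, points_per_contour, shape,
                    jitter_sd = jitter_sd, seed = seed)
  list(mother = gen$stack,
       branch = branch_stub(path, branch_at, semi_minor),
       reference = make_reference(gen, path, points_per_contour, shape),
       s = gen$s, segment = gen$segment)
}

#' Computed-vs-analytic error summary
#'
#' Order statistics of the pointwise absolute difference between a computed
#' curvature field and its analytic reference, over nodes where both are
#' defined (and, optionally, an extra per-contour mask holds).
#'
#' @param computed a `tc_field` (units cm^-1).
#' @param reference the matching list of per-contour analytic values
#'   (`tc_reference$long` or `$circ`), aligned to the field grid.
#' @param contour_mask optional logical vector per contour (e.g. from
#'   [reference_long_mask()]); FALSE contours are excluded.
#' @return named numeric: `min`, `max`, `median` of |computed - analytic|.
#' @export
error_summary <- function(computed, reference, contour_mask = NULL) {
  stopifnot(inherits(computed, "tc_field"))
  n <- length(computed$values)
  if (length(reference) != n)
    stop("reference does not match the field grid")
  if (is.null(contour_mask)) contour_mask <- rep(TRUE, n)
  diffs <- unlist(Map(function(v, r, ok) if (ok) abs(v - r) else numeric(0L),
                      computed$values, reference, contour_mask))
  diffs <- diffs[is.finite(diffs)]
  if (!length(diffs)) stop("no overlapping defined nodes to compare")
  c(min = min(diffs), max = max(diffs), median = stats::median(diffs))
}

#' Window-size study
#'
#' Recomputes a directional curvature field for each window size and
#' reports the error summary against the analytic reference plus the
#' relative error of the recovered peak curvature on a chosen track.
#'
#' @param surface a `tc_surface`.
#' @param reference a `tc_reference` aligned to the surface grid.
#' @param direction "longitudinal" or "circumferential".
#' @param windows numeric vector of window sizes (mm or rad).
#' @param track_value the analytic curvature of the track whose peak is
#'   scored (cm^-1); defaults to the largest finite reference value.
#' @param track_tol tolerance for selecting track nodes (cm^-1).
#' @return data frame: window, err_min, err_max, err_median, peak_computed,
#'   peak_reference, peak_rel_error.
#' @export
window_sweep <- function(surface, reference,
                         direction = c("longitudinal", "circumferential"),
                         windows, track_value = NULL, track_tol = 1e-6) {
  direction <- match.arg(direction)
  reference <- align_reference(reference, surface)
  ref <- if (direction == "longitudinal") reference$long else reference$circ
  if (is.null(track_value)) {
    v <- unlist(ref); track_value <- max(v[is.finite(v)])
  }
  rows <- lapply(windows, function(w) {
    fld <- curvature_field(surface, direction, window = w)
    mask <- if (direction == "longitudinal")
      reference_long_mask(reference, w) else NULL
    es <- error_summary(fld, ref, mask)
    on_track <- Map(function(v, r) v[abs(r - track_value) <= track_tol],
                    fld$values, ref)
    pk <- suppressWarnings(max(unlist(on_track), na.rm = TRUE))
    data.frame(window = w, err_min = es["min"], err_max = es["max"],
               err_median = es["median"], peak_computed = pk,
               peak_reference = track_value,
               peak_rel_error = abs(pk - track_value) / track_value,
               row.names = NULL)
  })
  do.call(rbind, rows)
}
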