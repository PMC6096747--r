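# Three-point circle-fit curvature, directional fields, proxies,
# differences.

test_that("circle_fit_curvature matches hand examples", {
  expect_equal(circle_fit_curvature(c(0, 1, 0), c(1, 0, 0), c(0, -1, 0)), 1)
  expect_equal(circle_fit_curvature(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), 0)
  # vertex of the a = 2, b = 1 ellipse with symmetric neighbors at polar
  # offsets +/- pi/8: circumcircle center solved on the symmetry axis
  rp <- 1 / sqrt(cos(pi / 8)^2 / 4 + sin(pi / 8)^2)
  p1 <- c(rp * cos(pi / 8), rp * sin(pi / 8), 0); p2 <- c(2, 0, 0)
  p3 <- c(p1[1L], -p1[2L], 0)
  cx <- (p1[1L]^2 + p1[2L]^2 - 4) / (2 * (p1[1L] - 2))  # oracle: center x
  r_oracle <- 2 - cx
  expect_equal(circle_fit_curvature(p1, p2, p3), 1 / r_oracle,
               tolerance = 1e-12)
  expect_equal(circle_fit_curvature(p1, p2, p3), 1.49, tolerance = 0.01)
  expect_error(circle_fit_curvature(c(1, 1, 1), c(1, 1, 1), c(0, 0, 0)),
               "degenerate")
})

test_that("circle fit equals the perpendicular-bisector oracle on random triples", {
  set.seed(7L)
  n <- 10000L
  P1 <- matrix(rnorm(3L * n, sd = 5), n)
  P2 <- P1 + matrix(rnorm(3L * n, sd = 3), n)
  P3 <- P1 + matrix(rnorm(3L * n, sd = 3), n)
  kappa <- tubecoord:::circle_fit_kappa(P1, P2, P3)
  keep <- which(is.finite(kappa) & kappa > 1e-6)   # skip near-collinear
  expect_gt(length(keep), 9000L)
  for (i in keep[seq(1L, length(keep), by = 7L)]) {
    R <- circumradius_oracle(P1[i, ], P2[i, ], P3[i, ])
    expect_equal(1 / kappa[i], R, tolerance = 1e-9)
  }
})

test_that("any three distinct points of a circle return exactly 1/R", {
  set.seed(11L)
  for (rep in 1:50) {
    R <- runif(1L, 0.5, 80)
    t <- runif(1L, 0, 2 * pi) + cumsum(c(0, runif(2L, 0.05, 2)))
    ctr <- rnorm(3L, sd = 20)
    ax <- rnorm(3L); ax <- ax / sqrt(sum(ax^2))
    p <- tubecoord:::rotate_about(
      cbind(R * cos(t), R * sin(t), 0), ax, runif(1L, 0, pi))
    p <- sweep(p, 2L, ctr, "+")
    expect_equal(circle_fit_curvature(p[1L, ], p[2L, ], p[3L, ]), 1 / R,
                 tolerance = 1e-12)
  }
})

test_that("curvature scales inversely with coordinate scale", {
  an <- simple_analysis()
  surf <- an$surface
  ph <- simple_phantom()
  for (s in c(0.5, 2)) {
    st2 <- contour_stack(lapply(ph$mother$contours, function(ct) ct$points * s))
    fr2 <- suppressMessages(greenwich_frame(
      st2, daughter = contour_stack(lapply(ph$branch$contours,
                                           function(ct) ct$points * s)),
      tolerance = s))
    s2 <- cylindrical_surface(st2, fr2)
    k1 <- longitudinal_curvature(surf, 50, 0, window = 20)
    k2 <- longitudinal_curvature(s2, 50 * s, 0, window = 20 * s)
    expect_equal(k2, k1 / s, tolerance = 1e-9)
    c1 <- circumferential_curvature(surf, 10, 1)
    c2 <- circumferential_curvature(s2, 10 * s, 1)
    expect_equal(c2, c1 / s, tolerance = 1e-9)
  }
})

test_that("longitudinal curvature is 0 on straights and 1/(Rc + r cos psi) in a bend", {
  an <- simple_analysis()
  # straight section, any theta
  expect_equal(longitudinal_curvature(an$surface, -10, 2.2), 0)
  # torus: all three points in the bend at angular position psi
  tt <- torus_tube(r = 10, Rc = 30, step = pi / 72)
  fr <- greenwich_frame(tt, fiducial = tt$contours[[1L]]$points[1L, ])
  st <- cylindrical_surface(tt, fr)
  mid <- st$sigma[ceiling(tt$n / 2)]
  for (psi in c(0, pi / 3, pi, 4)) {
    # theta = 0 is the +U (inner) side; material angle psi from inner.
    # The surface is a 96-gon x polyline sampling of the torus, so the
    # three fitted points sit on interpolation chords: allow the
    # corresponding sub-percent discretization error.
    got <- longitudinal_curvature(st, mid, psi, window = 10)
    expect_equal(got, 10 / (30 - 10 * cos(psi)), tolerance = 0.02)
  }
})

test_that("circumferential curvature recovers circles and windowed ellipse values", {
  an <- simple_analysis()
  # circular section radius 1 cm -> 1.0 cm^-1 for any window
  for (w in c(pi / 8, pi / 4, 3 * pi / 8))
    expect_equal(circumferential_curvature(an$surface, 10, 0.7, window = w),
                 1, tolerance = 0.005)
  # ellipse 4 cm x 2 cm diameters, window pi/4: the fitted circle through
  # the polygon points at the vertex +/- pi/8 polar offset (derived oracle)
  ph <- complex_phantom()
  an2 <- complex_analysis()
  surf <- an2$surface
  i0 <- 3L
  ref <- align_reference(ph$reference, surf)
  jv <- which(abs(ref$circ[[i0]] - 2) < 1e-9)[1L]     # major vertex node
  jf <- which(abs(ref$circ[[i0]] - 0.25) < 1e-9)[1L]  # flat node
  kv <- circumferential_curvature(surf, surf$sigma[i0], surf$theta[[i0]][jv])
  kf <- circumferential_curvature(surf, surf$sigma[i0], surf$theta[[i0]][jf])
  # oracle: circle through exact ellipse points at polar angles
  # pi/2, pi/2 +/- pi/8 (the polygon is dense enough to sit on the ellipse)
  th_off <- pi / 2 - pi / 8
  tpar <- atan2(10 * sin(th_off), 20 * cos(th_off))
  pv <- c(10 * cos(tpar), 20 * sin(tpar), 0)
  cy <- (sum(pv^2) - 400) / (2 * (pv[2L] - 20))
  expect_equal(kv, 10 / (20 - cy), tolerance = 0.005)
  expect_equal(kf, 0.25, tolerance = 0.05)
})

test_that("curvature_field masks window overruns and degenerate fits", {
  an <- simple_analysis()
  lf <- an$long_field
  srange <- range(an$surface$sigma)
  for (i in seq_along(lf$sigma)) {
    out <- lf$sigma[i] - 15 < srange[1L] || lf$sigma[i] + 15 > srange[2L]
    expect_identical(all(is.na(lf$values[[i]])), out)
  }
  # complex phantom bend 1 pinches on the inner track: with a window small
  # enough that all three stencil points fall inside the bend, the fit
  # degenerates to coincident points and the node is masked, not an error
  an2 <- complex_analysis()
  ph2 <- complex_phantom()
  ref2 <- align_reference(ph2$reference, an2$surface)
  lf10 <- curvature_field(an2$surface, "longitudinal", window = 8)
  i_mid <- which(ph2$s == 50)        # middle station of bend 1
  j_pinch <- which(is.na(ref2$long[[i_mid]]))
  expect_gt(length(j_pinch), 0L)
  expect_true(all(is.na(lf10$values[[i_mid]][j_pinch])))
})

test_that("fields are invariant under rigid motion of the input", {
  ph <- simple_phantom()
  motion <- rigid_motion(99L)
  st2 <- transform_stack(ph$mother, motion)
  br2 <- transform_stack(ph$branch, motion)
  an <- simple_analysis()
  an2 <- suppressMessages(analyze_stack(st2, branch = br2, tolerance = 1))
  for (i in c(2L, 10L, 25L)) {
    expect_equal(an2$long_field$values[[i]], an$long_field$values[[i]],
                 tolerance = 1e-9)
    expect_equal(an2$circ_field$values[[i]], an$circ_field$values[[i]],
                 tolerance = 1e-9)
  }
})

test_that("proxy fields are the elementwise product and mean", {
  an <- simple_analysis()
  pr <- proxy_fields(an$long_field, an$circ_field)
  # cylinder section: gaussian ~ 0, mean ~ 0.5 on the straight interior
  i <- 4L
  expect_equal(pr$gaussian_proxy[[i]], rep(0, 96L), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(pr$mean_proxy[[i]], rep(0.5, 96L), tolerance = 1e-4,
               ignore_attr = TRUE)
  # masked longitudinal nodes propagate to masked proxies
  expect_true(all(is.na(pr$gaussian_proxy[[1L]])))
  # grid mismatch -> alignment error
  st <- straight_tube(n = 3L, m = 24L)
  fr <- greenwich_frame(st, fiducial = c(10, 0, 0))
  sm <- cylindrical_surface(st, fr)
  f_small <- curvature_field(sm, "circumferential")
  expect_error(proxy_fields(an$long_field, f_small), "alignment")
})

test_that("difference_field subtracts on the common grid", {
  an <- simple_analysis()
  d0 <- difference_field(an$long_field, an$long_field)
  expect_true(all(unlist(d0$values) == 0, na.rm = TRUE))
  # straight tube vs slightly bent variant: nonzero only near the bend
  ph_bent <- generate_simple(bend_radius = 60)
  an_b <- suppressMessages(analyze_stack(ph_bent$mother,
                                         branch = ph_bent$branch,
                                         tolerance = 1))
  # grids differ in contour count between default and bent -> build same-n
  expect_error(difference_field(an$long_field, an_b$long_field), "alignment")
  # two states with identical topology
  ph2 <- generate_simple(bend_radius = 31)
  an2 <- suppressMessages(analyze_stack(ph2$mother, branch = ph2$branch,
                                        tolerance = 1))
  if (length(an2$long_field$sigma) == length(an$long_field$sigma)) {
    dd <- difference_field(an$long_field, an2$long_field)
    v <- unlist(dd$values)
    expect_gt(max(v, na.rm = TRUE), 0.01)
  }
})
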