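# Phantom generators: geometric invariants and analytic references.

test_that("generated contours are planar and orthogonal to the path", {
  for (ph in list(simple_phantom(), complex_phantom())) {
    devs <- vapply(ph$mother$contours, `[[`, numeric(1L), "plane_dev")
    expect_lt(max(devs), 1e-9)
  }
  # normals of the simple phantom align with the analytic tangent
  ph <- simple_phantom()
  cl <- build_centerline(ph$mother, 1L)
  straightp <- which(ph$segment == "proximal")
  for (i in straightp[-length(straightp)]) {
    n <- ph$mother$contours[[i]]$plane_normal
    expect_equal(abs(sum(n * c(0, 0, 1))), 1, tolerance = 1e-9)
  }
})

test_that("generated centroids lie on the analytic centerline", {
  ph <- simple_phantom()
  # proximal straight: centerline is the z axis
  for (i in which(ph$segment == "proximal")) {
    ctr <- ph$mother$contours[[i]]$centroid
    expect_lt(sqrt(sum(ctr[1:2]^2)), 0.1)
    expect_equal(unname(ctr[3L]), ph$s[i], tolerance = 0.1)
  }
  # the whole simple phantom lives in the x-z bend plane
  cents <- t(vapply(ph$mother$contours, `[[`, numeric(3L), "centroid"))
  expect_lt(max(abs(cents[, 2L])), 1e-9)
  # consecutive centroid chords never exceed the arc-length spacing
  seg <- sqrt(rowSums(diff(cents)^2))
  expect_true(all(seg <= 5 + 1e-9 & seg >= 4.9))
  # complex phantom: uniform parameter sampling keeps the mean at the
  # analytic center even for rotated partial ellipses
  ph2 <- complex_phantom()
  for (i in which(ph2$segment == "proximal")) {
    ctr <- ph2$mother$contours[[i]]$centroid
    expect_lt(sqrt(sum((ctr[1:2])^2)), 0.1)
  }
  cents2 <- t(vapply(ph2$mother$contours, `[[`, numeric(3L), "centroid"))
  seg2 <- sqrt(rowSums(diff(cents2)^2))
  expect_true(all(seg2 <= 5 + 1e-9 & seg2 >= 4.9))
})

test_that("simple phantom analytic references carry the printed values", {
  ph <- generate_simple()
  ref <- ph$reference
  ib <- which(ph$segment == "bend")[2L]
  expect_equal(ref$long[[ib]][1L], 0.5)          # inner track (theta = 0)
  expect_equal(ref$long[[ib]][49L], 0.25)        # outer track
  expect_true(all(abs(unlist(ref$circ) - 1) < 1e-12))
  expect_true(all(ref$e < 1e-12))
  istr <- which(ph$segment == "proximal")[1L]
  expect_equal(ref$long[[istr]], rep(0, 96L))
  # halved radius doubles the circumferential reference
  ph5 <- generate_simple(radius = 5, branch_at = 30)
  expect_true(all(abs(unlist(ph5$reference$circ) - 2) < 1e-12))
})

test_that("complex phantom analytic references carry the printed values", {
  ph <- complex_phantom()
  ref <- ph$reference
  i1 <- which(ph$segment == "bend1")[2L]
  expect_equal(ref$long[[i1]][1L], 0.5)          # outer track of bend 1
  expect_true(anyNA(ref$long[[i1]]))             # pinched inner track
  i2 <- which(ph$segment == "bend2")[3L]
  expect_equal(min(ref$long[[i2]], na.rm = TRUE) <= 1/3 + 1e-9, TRUE)
  expect_equal(max(ref$long[[i2]], na.rm = TRUE), 1.0)  # inner track
  ie <- which(ph$segment == "proximal")[1L]
  expect_equal(max(ref$circ[[ie]]), 2.0)         # vertex a/b^2 (1/mm -> cm)
  expect_equal(min(ref$circ[[ie]]), 0.25)        # flats b/a^2
  expect_equal(ref$e[ie], sqrt(3) / 2)
  expect_equal(ref$theta_e[ie], pi / 2)
  expect_equal(ref$theta_e[ph$mother$n], 0)
  # transition throat is circular: e = 0, orientation undefined
  it <- which(ph$segment == "transition")
  expect_true(any(ref$e[it] < 1e-9))
  expect_true(anyNA(ref$theta_e[it]))
})

test_that("degenerate phantom specs are rejected", {
  expect_error(generate_simple(radius = 31, bend_radius = 30), "degenerate")
  expect_error(generate_complex(semi_major = 30, semi_minor = 25),
               "degenerate")
  expect_message(generate_simple(radius = 30, bend_radius = 30,
                                 points_per_contour = 24L, spacing = 10),
                 "pinches")
})

test_that("error_summary reports order statistics of |computed - analytic|", {
  an <- simple_analysis()
  ph <- simple_phantom()
  ref <- align_reference(ph$reference, an$surface)
  # field against itself: all zeros
  self <- an$circ_field
  es0 <- error_summary(self, self$values)
  expect_equal(unname(es0), c(0, 0, 0))
  # reference + constant 0.1
  shifted <- lapply(self$values, function(v) v + 0.1)
  es1 <- error_summary(self, shifted)
  expect_equal(unname(es1), c(0.1, 0.1, 0.1), tolerance = 1e-12)
  # real run: median well below max
  es <- error_summary(an$long_field, ref$long,
                      reference_long_mask(ph$reference, 30))
  expect_lt(es["median"], es["max"] + 1e-15)
  expect_lt(es["max"], 0.01)
  expect_error(error_summary(an$long_field, ref$long,
                             rep(FALSE, length(ref$long))), "no overlapping")
})

test_that("window_sweep reproduces the monotone window-size bias", {
  an <- complex_analysis()
  ph <- complex_phantom()
  sw <- window_sweep(an$surface, ph$reference, "longitudinal",
                     windows = c(30, 40), track_value = 1.0)
  expect_lt(sw$peak_rel_error[1L], 0.005)
  expect_gt(sw$peak_rel_error[2L], sw$peak_rel_error[1L])
  swc <- window_sweep(an$surface, ph$reference, "circumferential",
                      windows = c(pi / 4, 3 * pi / 8), track_value = 2.0)
  # pi/4 underestimates the 2.0 vertex by ~25%; 3*pi/8 by more
  expect_gt(swc$peak_rel_error[2L], swc$peak_rel_error[1L])
  # any window on a circular contour: zero error (simple phantom)
  ans <- simple_analysis()
  sws <- window_sweep(ans$surface, simple_phantom()$reference,
                      "circumferential", windows = c(pi / 8, pi / 4),
                      track_value = 1.0)
  expect_lt(max(sws$err_max), 1e-9)
})

test_that("jittered phantoms are reproducible from the seed", {
  a <- generate_simple(jitter_sd = 0.05, seed = 123L)
  b <- generate_simple(jitter_sd = 0.05, seed = 123L)
  expect_identical(a$mother$contours[[5L]]$points,
                   b$mother$contours[[5L]]$points)
  c2 <- generate_simple(jitter_sd = 0.05, seed = 124L)
  expect_false(identical(a$mother$contours[[5L]]$points,
                         c2$mother$contours[[5L]]$points))
})
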