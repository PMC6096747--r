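# Shared fixtures. Phantom analyses are cached so the suite pays for each
# phantom pipeline once.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .cache)) assign(key, force(expr), .cache)
  get(key, .cache)
}

simple_phantom <- function() cached("simple", generate_simple())

simple_analysis <- function() cached("simple_an", suppressMessages(
  analyze_stack(simple_phantom()$mother, branch = simple_phantom()$branch,
                tolerance = 1)))

complex_phantom <- function() cached("complex", generate_complex())

complex_analysis <- function() cached("complex_an", suppressMessages(
  analyze_stack(complex_phantom()$mother, branch = complex_phantom()$branch,
                tolerance = 1)))

# circle contour of radius r in the z = z0 plane, m points, first point on +x
circle_contour <- function(r = 10, z0 = 0, m = 96L, center = c(0, 0, z0),
                           index = 1L) {
  t <- 2 * pi * (seq_len(m) - 1L) / m
  contour3d(cbind(center[1L] + r * cos(t), center[2L] + r * sin(t),
                  center[3L]), index = index)
}

# straight tube along +z: circular contours every `spacing` mm
straight_tube <- function(r = 10, n = 9L, spacing = 5, m = 96L) {
  contour_stack(lapply(seq_len(n), function(i)
    circle_contour(r, z0 = (i - 1L) * spacing, m = m, index = i)))
}

# torus bend: circular cross sections of radius r on a 90-degree arc of
# centerline radius Rc in the x-z plane (bending toward +x), preceded and
# followed by nothing; contours every `step` radians of bend angle
torus_tube <- function(r = 10, Rc = 30, step = pi / 36, m = 96L) {
  alphas <- seq(0, pi / 2, by = step)
  contour_stack(lapply(seq_along(alphas), function(i) {
    a <- alphas[i]
    C <- c(Rc * (1 - cos(a)), 0, Rc * sin(a))
    U <- c(cos(a), 0, -sin(a))        # transported +x axis
    V <- c(0, 1, 0)
    t <- 2 * pi * (seq_len(m) - 1L) / m
    contour3d(sweep(outer(r * cos(t), U) + outer(r * sin(t), V), 2L, C, "+"),
              index = i)
  }))
}

# random rigid motion (rotation + translation), deterministic given seed
rigid_motion <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3L); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1L, 0, 2 * pi)
  shift <- rnorm(3L, sd = 40)
  list(apply = function(p) {
    p <- if (is.matrix(p)) p else matrix(p, 1L)
    sweep(tubecoord:::rotate_about(p, ax, ang), 2L, shift, "+")
  })
}

transform_stack <- function(stack, motion) {
  contour_stack(lapply(stack$contours, function(ct) motion$apply(ct$points)))
}

# independent circumradius oracle: exact circumcenter of three points via
# the linear system in the triangle plane (perpendicular bisectors)
circumradius_oracle <- function(p1, p2, p3) {
  u <- p2 - p1; v <- p3 - p1
  A <- rbind(u, v) %*% cbind(u, v)
  b <- c(sum(u * u) / 2, sum(v * v) / 2)
  ab <- solve(A, b)
  ctr <- p1 + ab[1L] * u + ab[2L] * v
  sqrt(sum((ctr - p1)^2))
}
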