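# Small 3D vector helpers shared across the package. Points are numeric
# length-3 vectors; point sets are m x 3 matrices (columns x, y, z, mm).

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Rodrigues rotation of row-vectors in m x 3 matrix `p` about unit axis.
rotate_about <- function(p, axis, angle) {
  a <- unit(axis)
  K <- matrix(c(0, -a[3L], a[2L],
                a[3L], 0, -a[1L],
                -a[2L], a[1L], 0), 3L, 3L, byrow = TRUE)
  R <- diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  p %*% t(R)
}

as_point3 <- function(p) {
  p <- as.numeric(p)
  if (length(p) != 3L || any(!is.finite(p)))
    stop("a point must be 3 finite coordinates (mm)")
  p
}

as_point_matrix <- function(points) {
  if (is.matrix(points)) {
    m <- points
  } else if (is.data.frame(points)) {
    m <- as.matrix(points[, 1:3])
  } else if (is.list(points)) {
    m <- do.call(rbind, lapply(points, as_point3))
  } else {
    stop("points must be an m x 3 matrix, data frame, or list of points")
  }
  storage.mode(m) <- "double"
  if (ncol(m) != 3L || any(!is.finite(m)))
    stop("points must be m x 3 with finite coordinates")
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

# Least-squares best-fit plane through rows of `p`: returns list(center,
# normal, max_dev) where max_dev is the largest out-of-plane deviation (mm).
fit_plane <- function(p) {
  ctr <- colMeans(p)
  q <- sweep(p, 2L, ctr)
  sv <- svd(q, nu = 0L, nv = 3L)
  n <- sv$v[, 3L]
  list(center = ctr, normal = unit(n), max_dev = max(abs(q %*% n)))
}

wrap_2pi <- function(theta) {
  out <- theta %% (2 * pi)
  # guard against 2*pi itself from floating point
  out[out >= 2 * pi] <- 0
  out
}
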