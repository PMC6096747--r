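#' Arc-length parameterized centerline
#'
#' Piecewise-linear polyline through the contour centroids. The longitudinal
#' coordinate sigma of node i is the signed cumulative Euclidean length along
#' the polyline from the origin node: zero at `origin_index`, negative for
#' nodes proximal to it, positive distal.
#'
#' @param stack a `tc_stack`.
#' @param origin_index index k of the node where sigma = 0 (normally the
#'   Greenwich contour).
#' @return object of class `tc_centerline`: `nodes` (n x 3, mm), `sigma`
#'   (length n, mm), `origin_index`, `tangents` (n x 3 unit rows: central
#'   differences at interior nodes, one-sided at the ends).
#' @export
build_centerline <- function(stack, origin_index = 1L) {
  stopifnot(inherits(stack, "tc_stack"))
  k <- as.integer(origin_index)
  if (k < 1L || k > stack$n) stop("origin_index out of range")
  nodes <- stack_centroids(stack)
  seg <- sqrt(rowSums(diff(nodes)^2))
  if (any(seg < 1e-12))
    stop("degenerate centerline: coincident consecutive centroids")
  s <- c(0, cumsum(seg))
  sigma <- s - s[k]
  n <- nrow(nodes)
  tang <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    a <- if (i == 1L) 1L else i - 1L
    b <- if (i == n) n else i + 1L
    tang[i, ] <- unit(nodes[b, ] - nodes[a, ])
  }
  structure(list(nodes = nodes, sigma = sigma, origin_index = k,
                 tangents = tang),
            class = "tc_centerline")
}

#' @export
print.tc_centerline <- function(x, ...) {
  cat(sprintf("centerline: %d nodes, sigma in [%.2f, %.2f] mm (origin node %d)\n",
              nrow(x$nodes), min(x$sigma), max(x$sigma), x$origin_index))
  invisible(x)
}

polyline_length <- function(p) sum(sqrt(rowSums(diff(p)^2)))
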