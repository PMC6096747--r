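# Fiducial detection, Greenwich point selection, and propagation of the
# Greenwich curve that anchors theta = 0 on every contour.

flatten_points <- function(stack) {
  m <- vapply(stack$contours, function(c) nrow(c$points), integer(1L))
  list(points = do.call(rbind, lapply(stack$contours, `[[`, "points")),
       contour = rep.int(seq_len(stack$n), m),
       j = unlist(lapply(m, seq_len), use.names = FALSE))
}

# mean spacing between consecutive boundary points, over all contours
mean_point_spacing <- function(stack) {
  sp <- vapply(stack$contours, function(ct) {
    p <- ct$points
    q <- rbind(p, p[1L, ])
    mean(sqrt(rowSums(diff(q)^2)))
  }, numeric(1L))
  mean(sp)
}

min_dist_to_set <- function(p, set) {
  # for each row of p, min distance to rows of set (chunked to bound memory)
  out <- numeric(nrow(p))
  idx <- split(seq_len(nrow(p)), ceiling(seq_len(nrow(p)) / 512))
  s2 <- rowSums(set^2)
  for (g in idx) {
    d2 <- outer(rowSums(p[g, , drop = FALSE]^2), s2, "+") -
      2 * p[g, , drop = FALSE] %*% t(set)
    out[g] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  out
}

#' Locate the bifurcation fiducial point
#'
#' The material landmark delta is the most distal intersection of the mother
#' and daughter lumen boundaries. With discretely sampled boundaries,
#' "intersection" is proximity: among all mother boundary points lying
#' within `tolerance` of any daughter boundary point, the one whose nearest
#' mother-centerline node is most distal (largest sigma) is returned. Ties
#' are broken by lowest contour index, then lowest point index.
#'
#' @param mother,daughter contour stacks (`tc_stack`); the daughter is used
#'   only here, to find the landmark.
#' @param tolerance proximity radius in mm; defaults to half the mean
#'   inter-point spacing of the mother contours.
#' @return the fiducial point delta (length-3, mm).
#' @export
find_fiducial <- function(mother, daughter, tolerance = NULL) {
  stopifnot(inherits(mother, "tc_stack"), inherits(daughter, "tc_stack"))
  if (is.null(tolerance)) tolerance <- mean_point_spacing(mother) / 2
  fm <- flatten_points(mother)
  fd <- flatten_points(daughter)
  d <- min_dist_to_set(fm$points, fd$points)
  hit <- which(d <= tolerance)
  if (!length(hit))
    stop(sprintf(paste0("no mother/daughter boundary points within %.3g mm: ",
                        "branch not adjacent or tolerance too small"),
                 tolerance))
  cl <- build_centerline(mother, 1L)
  # nearest centerline node of each candidate point
  nd2 <- outer(rowSums(fm$points[hit, , drop = FALSE]^2),
               rowSums(cl$nodes^2), "+") -
    2 * fm$points[hit, , drop = FALSE] %*% t(cl$nodes)
  node <- apply(nd2, 1L, which.min)
  key <- order(-cl$sigma[node], fm$contour[hit], fm$j[hit])
  fm$points[hit[key[1L]], ]
}

#' Select the Greenwich point closest to the fiducial
#'
#' @param delta fiducial point (mm).
#' @param stack a `tc_stack`.
#' @return list with `gamma` (the closest boundary point), `k` (its contour
#'   index), `j` (its point index). Ties broken by lowest contour index,
#'   then lowest point index.
#' @export
find_greenwich_point <- function(delta, stack) {
  delta <- as_point3(delta)
  f <- flatten_points(stack)
  d2 <- rowSums(sweep(f$points, 2L, delta)^2)
  best <- order(d2, f$contour, f$j)[1L]
  list(gamma = f$points[best, ], k = f$contour[best], j = f$j[best])
}

closest_on_contour <- function(contour, p) {
  d2 <- rowSums(sweep(contour$points, 2L, p)^2)
  j <- which.min(d2)
  list(point = contour$points[j, ], j = j)
}

#' Propagate the Greenwich point to every contour
#'
#' Starting from gamma on contour k, reference points gamma_i are assigned
#' on every other contour, iterating distally (k -> n) and proximally
#' (k -> 1, by the mirrored construction). Three propagation methods are
#' supported:
#' \describe{
#'   \item{1}{translate gamma_i along the centerline chord C_(i+1) - C_i to
#'     its intersection with the next contour's plane, then snap to the
#'     closest boundary point (default; tracks the centerline most
#'     robustly);}
#'   \item{2}{translate along the current contour's plane normal instead;}
#'   \item{3}{snap directly to the boundary point of the next contour
#'     closest to gamma_i.}
#' }
#' If the translation direction of method 1 or 2 is parallel to the target
#' plane, that step falls back to method 3 and a message is logged.
#'
#' @param stack a `tc_stack`.
#' @param centerline matching `tc_centerline`.
#' @param gamma the seed Greenwich point (a boundary point of contour k).
#' @param k contour index of gamma.
#' @param method 1, 2, or 3.
#' @return n x 3 matrix of Greenwich points, one row per contour; every row
#'   is exactly one of that contour's stored boundary points.
#' @export
propagate_greenwich <- function(stack, centerline, gamma, k, method = 1L) {
  stopifnot(inherits(stack, "tc_stack"))
  method <- as.integer(method)
  if (!method %in% 1:3) stop("method must be 1, 2, or 3")
  k <- as.integer(k)
  if (k < 1L || k > stack$n) stop("k out of range")
  n <- stack$n
  gp <- matrix(NA_real_, n, 3L)
  gp[k, ] <- closest_on_contour(stack$contours[[k]], as_point3(gamma))$point
  step <- function(i_from, i_to) {
    g <- gp[i_from, ]
    ct_to <- stack$contours[[i_to]]
    if (method == 3L) return(closest_on_contour(ct_to, g)$point)
    dir <- if (method == 1L)
      ct_to$centroid - stack$contours[[i_from]]$centroid
    else
      stack$contours[[i_from]]$plane_normal
    nn <- ct_to$plane_normal
    den <- sum(dir * nn)
    if (abs(den) < 1e-9 * vnorm(dir)) {
      message(sprintf(
        "greenwich step %d -> %d: direction parallel to target plane, falling back to method 3",
        i_from, i_to))
      return(closest_on_contour(ct_to, g)$point)
    }
    t <- sum((ct_to$centroid - g) * nn) / den
    closest_on_contour(ct_to, g + t * dir)$point
  }
  if (k < n) for (i in k:(n - 1L)) gp[i + 1L, ] <- step(i, i + 1L)
  if (k > 1L) for (i in k:2L) gp[i - 1L, ] <- step(i, i - 1L)
  dimnames(gp) <- list(NULL, c("x", "y", "z"))
  gp
}

#' Greenwich curve through the per-contour Greenwich points
#'
#' @param gamma_points n x 3 matrix of Greenwich points.
#' @return list with `points` (the polyline) and `length` (mm; 0 for a
#'   single point).
#' @export
greenwich_curve <- function(gamma_points) {
  gp <- as_point_matrix(gamma_points)
  len <- if (nrow(gp) < 2L) 0 else polyline_length(gp)
  list(points = gp, length = len)
}

#' Build a complete Greenwich frame
#'
#' Convenience constructor running fiducial detection (or taking an
#' explicit fiducial), Greenwich point selection, and propagation.
#'
#' @param stack mother-vessel `tc_stack`.
#' @param fiducial explicit fiducial point (length-3, mm); ignored when
#'   `daughter` is given.
#' @param daughter optional daughter-branch `tc_stack` for automatic
#'   fiducial detection via [find_fiducial()].
#' @param method Greenwich propagation method (1, 2, or 3).
#' @param tolerance fiducial detection tolerance (mm), see
#'   [find_fiducial()].
#' @return object of class `tc_greenwich`: `delta`, `gamma`, `gamma_index`
#'   (k), `gamma_points` (n x 3), `curve` (from [greenwich_curve()]),
#'   `method`.
#' @export
greenwich_frame <- function(stack, fiducial = NULL, daughter = NULL,
                            method = 1L, tolerance = NULL) {
  if (!is.null(daughter))
    fiducial <- find_fiducial(stack, daughter, tolerance)
  if (is.null(fiducial))
    stop(paste("no fiducial source: give a daughter branch stack,",
               "an explicit fiducial point, or a (sigma, theta) seed"))
  fiducial <- as_point3(fiducial)
  sel <- find_greenwich_point(fiducial, stack)
  cl <- build_centerline(stack, sel$k)
  gp <- propagate_greenwich(stack, cl, sel$gamma, sel$k, method)
  structure(list(delta = fiducial, gamma = sel$gamma,
                 gamma_index = sel$k, gamma_points = gp,
                 curve = greenwich_curve(gp), method = as.integer(method)),
            class = "tc_greenwich")
}

#' @export
print.tc_greenwich <- function(x, ...) {
  cat(sprintf(
    "greenwich frame: method %d, gamma on contour %d, curve length %.2f mm\n",
    x$method, x$gamma_index, x$curve$length))
  invisible(x)
}
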