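# Contour-set serialization and result export. The primary on-disk format
# is a self-describing JSON document (units, labels, optional fiducial,
# contours as point lists); a flat CSV dialect (contour_id, x, y, z) is
# accepted and written for interoperability. Results go out as CSV tables
# with units in the headers plus a legacy-ASCII VTK polydata surface for
# visualization.

#' Write a contour set to disk
#'
#' @param stack a `tc_stack`.
#' @param path output file; `.json` or `.csv` decides the dialect.
#' @param vessel optional vessel label.
#' @param time_label optional physiological-state tag.
#' @param fiducial optional fiducial point (mm) stored in the metadata.
#' @return the path, invisibly.
#' @export
write_contour_set <- function(stack, path, vessel = NULL, time_label = NULL,
                              fiducial = NULL) {
  stopifnot(inherits(stack, "tc_stack"))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    rows <- do.call(rbind, lapply(stack$contours, function(ct)
      data.frame(contour_id = ct$index, x = ct$points[, 1L],
                 y = ct$points[, 2L], z = ct$points[, 3L])))
    names(rows) <- c("contour_id", "x_mm", "y_mm", "z_mm")
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  } else {
    doc <- list(units = "mm", vessel = vessel, time = time_label,
                fiducial = if (!is.null(fiducial)) as_point3(fiducial),
                contours = lapply(stack$contours, function(ct)
                  list(index = ct$index,
                       points = unname(apply(ct$points, 1L, as.numeric,
                                             simplify = FALSE)))))
    # digits = I(17): full double precision so point values round-trip
    # bit-identically
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                         null = "null")
  }
  invisible(path)
}

#' Read a contour set
#'
#' Accepts the package's JSON contour-set format or the flat CSV dialect
#' with columns contour_id, x_mm, y_mm, z_mm (or contour_id, x, y, z).
#' Units must be millimetres; the JSON document declares them explicitly.
#'
#' @param path input file.
#' @return a `tc_stack`; metadata (`vessel`, `time`, `fiducial`) attached
#'   as attributes when present.
#' @export
read_contour_set <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path)
    names(df) <- sub("_mm$", "", names(df))
    need <- c("contour_id", "x", "y", "z")
    if (!all(need %in% names(df)))
      stop("CSV contour set needs columns contour_id, x, y, z (mm)")
    ids <- sort(unique(df$contour_id))
    contours <- lapply(seq_along(ids), function(i) {
      p <- as.matrix(df[df$contour_id == ids[i], c("x", "y", "z")])
      if (nrow(p) < 3L)
        stop(sprintf("parse error: contour %s has fewer than 3 points", ids[i]))
      p
    })
    return(contour_stack(contours))
  }
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$units) || !identical(doc$units, "mm"))
    stop("unit error: contour set must declare units \"mm\"")
  if (is.null(doc$contours) || length(doc$contours) < 2L)
    stop("parse error: need at least 2 contours")
  idx <- vapply(doc$contours, function(c) as.integer(c$index), integer(1L))
  if (any(diff(idx) <= 0))
    stop("parse error: contour indices must be strictly increasing")
  contours <- lapply(doc$contours, function(c) {
    p <- do.call(rbind, lapply(c$points, function(q) as.numeric(unlist(q))))
    if (is.null(p) || nrow(p) < 3L)
      stop(sprintf("parse error: contour %s has fewer than 3 points", c$index))
    p
  })
  st <- contour_stack(contours)
  attr(st, "vessel") <- doc$vessel
  attr(st, "time") <- doc$time
  if (!is.null(doc$fiducial)) attr(st, "fiducial") <- as.numeric(unlist(doc$fiducial))
  st
}

num_or_blank <- function(x) ifelse(is.na(x), "", format(x, digits = 12))

#' Write analysis results
#'
#' Emits the full analysis as plain-text artifacts in `outdir`:
#' \itemize{
#'   \item `nodes.csv`: per grid node i, j: sigma (mm), theta (rad),
#'     r (mm), longitudinal and circumferential curvature, Gaussian- and
#'     mean-curvature proxies (masked nodes as empty cells);
#'   \item `contours.csv`: per contour sigma, e, theta_e, D, d;
#'   \item `greenwich.csv`: the Greenwich curve polyline;
#'   \item `surface.vtk`: legacy-ASCII VTK polydata with one scalar array
#'     per curvature field.
#' }
#'
#' @param surface a `tc_surface`.
#' @param long_field,circ_field `tc_field`s on the surface grid.
#' @param profile a `tc_ecc_profile`.
#' @param frame a `tc_greenwich`.
#' @param outdir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_results <- function(surface, long_field, circ_field, profile, frame,
                          outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  prox <- proxy_fields(long_field, circ_field)
  n <- length(surface$sigma)
  nodes <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(i = i, j = seq_along(surface$theta[[i]]),
               sigma_mm = surface$sigma[i], theta_rad = surface$theta[[i]],
               r_mm = surface$radii[[i]],
               kappa_long_per_cm = num_or_blank(long_field$values[[i]]),
               kappa_circ_per_cm = num_or_blank(circ_field$values[[i]]),
               gaussian_proxy_per_cm2 = num_or_blank(prox$gaussian_proxy[[i]]),
               mean_proxy_per_cm = num_or_blank(prox$mean_proxy[[i]]))))
  f1 <- file.path(outdir, "nodes.csv")
  utils::write.csv(nodes, f1, row.names = FALSE, quote = FALSE)
  f2 <- file.path(outdir, "contours.csv")
  ctab <- data.frame(sigma_mm = profile$sigma, e = profile$e,
                     theta_e_rad = num_or_blank(profile$theta_e),
                     D_mm = profile$D_mm, d_mm = profile$d_mm)
  utils::write.csv(ctab, f2, row.names = FALSE, quote = FALSE)
  f3 <- file.path(outdir, "greenwich.csv")
  gw <- data.frame(x_mm = frame$gamma_points[, 1L],
                   y_mm = frame$gamma_points[, 2L],
                   z_mm = frame$gamma_points[, 3L])
  utils::write.csv(gw, f3, row.names = FALSE, quote = FALSE)
  f4 <- file.path(outdir, "surface.vtk")
  write_surface_vtk(surface, list(kappa_long = long_field,
                                  kappa_circ = circ_field), f4)
  invisible(c(f1, f2, f3, f4))
}

#' Legacy-ASCII VTK polydata export of the surface
#'
#' Boundary points become VTK points; consecutive contours with equal point
#' counts are stitched into quads. Each supplied field becomes one scalar
#' point-data array (masked nodes as nan).
#'
#' @param surface a `tc_surface`.
#' @param fields named list of `tc_field`s on the surface grid (may be
#'   empty).
#' @param path output `.vtk` file.
#' @return the path, invisibly.
#' @export
write_surface_vtk <- function(surface, fields, path) {
  m <- vapply(surface$theta, length, integer(1L))
  npts <- sum(m)
  off <- cumsum(c(0L, m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "tubular surface with curvature scalars", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", npts)), con)
  allp <- do.call(rbind, surface$points)
  writeLines(apply(allp, 1L, function(p) paste(sprintf("%.12g", p),
                                               collapse = " ")), con)
  quads <- list()
  for (i in seq_len(length(m) - 1L)) {
    if (m[i] != m[i + 1L]) next
    j <- seq_len(m[i]); jn <- c(j[-1L], 1L)
    quads[[length(quads) + 1L]] <-
      cbind(4L, off[i] + j - 1L, off[i] + jn - 1L,
            off[i + 1L] + jn - 1L, off[i + 1L] + j - 1L)
  }
  if (length(quads)) {
    q <- do.call(rbind, quads)
    writeLines(sprintf("POLYGONS %d %d", nrow(q), length(q)), con)
    writeLines(apply(q, 1L, paste, collapse = " "), con)
  }
  if (length(fields)) {
    writeLines(sprintf("POINT_DATA %d", npts), con)
    for (nm in names(fields)) {
      v <- unlist(fields[[nm]]$values)
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(ifelse(is.na(v), "nan", sprintf("%.9g", v)), con)
    }
  }
  invisible(path)
}
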