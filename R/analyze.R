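#' Run the full coordinate-system analysis on a contour stack
#'
#' Convenience pipeline: fiducial (branch or explicit) -> Greenwich frame
#' -> centerline -> cylindrical surface -> longitudinal and circumferential
#' curvature fields -> eccentricity profile.
#'
#' @param stack mother-vessel `tc_stack`.
#' @param branch optional daughter `tc_stack` for fiducial detection.
#' @param fiducial optional explicit fiducial point (mm).
#' @param method Greenwich propagation method (1, 2, 3).
#' @param window_long longitudinal window (mm, default 30).
#' @param window_circ circumferential window (rad, default pi/4).
#' @param angular_step eccentricity scan step (rad, default pi/720).
#' @param units curvature units, "cm" or "mm".
#' @param tolerance fiducial detection tolerance (mm).
#' @param time_label optional state tag carried on the surface.
#' @return list of class `tc_analysis`: `frame`, `centerline`, `surface`,
#'   `long_field`, `circ_field`, `profile`.
#' @examples
#' ph <- generate_simple()
#' an <- analyze_stack(ph$mother, branch = ph$branch, tolerance = 1)
#' range(unlist(an$circ_field$values), na.rm = TRUE)  # ~1 cm^-1 everywhere
#' @export
analyze_stack <- function(stack, branch = NULL, fiducial = NULL,
                          method = 1L, window_long = 30,
                          window_circ = pi / 4, angular_step = pi / 720,
                          units = c("cm", "mm"), tolerance = NULL,
                          time_label = NULL) {
  units <- match.arg(units)
  frame <- greenwich_frame(stack, fiducial = fiducial, daughter = branch,
                           method = method, tolerance = tolerance)
  cl <- build_centerline(stack, frame$gamma_index)
  surf <- cylindrical_surface(stack, frame, cl, time_label = time_label)
  structure(list(
    frame = frame, centerline = cl, surface = surf,
    long_field = curvature_field(surf, "longitudinal", window_long, units),
    circ_field = curvature_field(surf, "circumferential", window_circ, units),
    profile = eccentricity_profile(stack, frame, angular_step, cl)),
    class = "tc_analysis")
}

#' @export
print.tc_analysis <- function(x, ...) {
  print(x$frame); print(x$surface); print(x$long_field); print(x$circ_field)
  invisible(x)
}
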