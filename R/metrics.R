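#' Nipple landmark of a 2D breast contour
#'
#' The most anterior vertex (maximum x); ties broken toward the lowest y.
#'
#' @param contour vertex matrix (mm).
#' @return length-2 numeric (x, y).
#' @export
nipple_landmark <- function(contour) {
  mx <- max(contour[, 1])
  if (diff(range(contour[, 1])) < 1e-9)
    stop("flat contour: nipple landmark undetectable")
  cand <- which(contour[, 1] > mx - 1e-9)
  cand <- cand[which.min(contour[cand, 2])]
  contour[cand, ]
}

#' Absolute vertical nipple-height difference between two contours
#'
#' @param contour_treated,contour_control closed contours (mm) carrying a
#'   nipple landmark (most anterior point).
#' @return |y_treated - y_control| in mm.
#' @export
nipple_height_difference <- function(contour_treated, contour_control) {
  abs(nipple_landmark(contour_treated)[2] - nipple_landmark(contour_control)[2])
}

#' Breast area inside a disc centred on the nipple
#'
#' Area of the intersection of the breast region (interior of the closed
#' contour) with a disc of fixed radius centred on the nipple landmark,
#' evaluated on a fine grid.
#'
#' @param contour closed breast contour (mm), closed against the chest
#'   wall.
#' @param nipple optional landmark override (x, y).
#' @param radius disc radius (mm).
#' @param grid_n grid points per diameter for the area quadrature.
#' @return area in cm^2.
#' @export
lateral_disc_area <- function(contour, nipple = NULL, radius = 60,
                              grid_n = 400L) {
  stopifnot(radius > 0)
  if (is.null(nipple)) nipple <- nipple_landmark(contour)
  if (!points_in_polygon(nipple[1] - 1e-6, nipple[2], contour))
    stop("nipple landmark falls outside the breast region")
  hh <- 2 * radius / grid_n
  gx <- seq(nipple[1] - radius + hh / 2, nipple[1] + radius - hh / 2, by = hh)
  gy <- seq(nipple[2] - radius + hh / 2, nipple[2] + radius - hh / 2, by = hh)
  px <- rep(gx, times = length(gy))
  py <- rep(gy, each = length(gx))
  in_disc <- (px - nipple[1])^2 + (py - nipple[2])^2 <= radius^2
  inside <- points_in_polygon(px[in_disc], py[in_disc], contour)
  sum(inside) * hh^2 / 100  # mm^2 -> cm^2
}

#' Principal dimensions of the (possibly deformed) cavity
#'
#' Best-fit-ellipse axes of the cavity boundary via the exact area moments
#' of the boundary polygon: for an ellipse the area covariance is
#' diag(a^2/4, b^2/4), so the full axes are 4 sqrt(eigenvalues).
#'
#' @param x a \code{breast_mesh} with a cavity, a \code{healing_state},
#'   or a closed cavity polygon.
#' @param u optional displacement field when \code{x} is a mesh (deformed
#'   cavity).
#' @return named vector (major, minor) in mm; zeros with attribute
#'   \code{closed = TRUE} when the wound is closed.
#' @export
cavity_dimensions <- function(x, u = NULL) {
  poly <- if (inherits(x, "breast_mesh")) cavity_wall_contour(x, u)
          else if (inherits(x, "healing_state")) wound_polygon(x)
          else x
  if (is.null(poly) || nrow(poly) < 3)
    return(structure(c(major = 0, minor = 0), closed = TRUE))
  S <- polygon_covariance(poly)
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  c(major = 4 * sqrt(max(ev[1], 0)), minor = 4 * sqrt(max(ev[2], 0)))
}

#' Segment a cosmesis metric series into three healing phases
#'
#' Exhaustive least-squares segmentation of the series into three
#' linear-trend segments; returns the two change points.
#'
#' @param time time points (weeks), strictly increasing.
#' @param value metric values.
#' @param min_seg minimum points per segment.
#' @return list with \code{breaks} (the two boundary times),
#'   \code{sse}, and \code{degenerate} (TRUE when segmentation does not
#'   improve on a single trend, e.g. monotone or constant series).
#' @export
phase_classifier <- function(time, value, min_seg = 2L) {
  stopifnot(length(time) == length(value), length(time) >= 5,
            all(diff(time) > 0))
  n <- length(time)
  seg_sse <- function(i, j) {
    t <- time[i:j]; v <- value[i:j]
    if (length(t) < 2) return(0)
    r <- stats::lm.fit(cbind(1, t), v)$residuals
    sum(r^2)
  }
  best <- list(sse = Inf, b = c(NA, NA))
  for (b1 in seq(min_seg, n - 2L * min_seg)) {
    for (b2 in seq(b1 + min_seg, n - min_seg)) {
      sse <- seg_sse(1, b1) + seg_sse(b1 + 1L, b2) + seg_sse(b2 + 1L, n)
      if (sse < best$sse) best <- list(sse = sse, b = c(b1, b2))
    }
  }
  sse1 <- seg_sse(1, n)
  degenerate <- !is.finite(best$sse) || sse1 < 1e-12 ||
    best$sse > 0.5 * sse1
  list(breaks = (time[best$b] + time[best$b + 1L]) / 2,
       break_index = best$b, sse = best$sse, degenerate = degenerate)
}

#' Assign healing-phase labels to post-surgery weeks
#'
#' Phase I covers weeks 1-6, phase II weeks 7-20, phase III weeks 21-35;
#' week 0 is the pre-surgery baseline (phase 0).
#'
#' @param weeks numeric vector of weeks after surgery.
#' @return character vector of phase labels.
#' @export
phase_of_week <- function(weeks) {
  ifelse(weeks < 1, "0",
         ifelse(weeks <= 6, "I", ifelse(weeks <= 20, "II", "III")))
}
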