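#' Fuzzy C-means segmentation of a grayscale image
#'
#' Standard fuzzy C-means on pixel intensities: memberships
#' \eqn{u_{ik} = 1 / \sum_j (d_{ik}/d_{ij})^{2/(m-1)}} and centroid updates
#' \eqn{v_k = \sum_i u_{ik}^m x_i / \sum_i u_{ik}^m}, iterated until the
#' largest centroid movement falls below \code{tol}.  Centroids are
#' initialised from seeded jittered percentiles of the data.
#'
#' @param image numeric matrix of intensities.
#' @param n_classes number of classes (default 3: background, fat,
#'   glandular).
#' @param m fuzziness exponent (> 1).
#' @param tol convergence tolerance on centroid movement.
#' @param max_iter iteration cap.
#' @param seed integer seed for the centroid initialisation.
#' @return an \code{fcm_result}: memberships (pixels x classes, rows sum to
#'   1), hard integer \code{labels} matrix (classes ordered by increasing
#'   centroid so 1 = darkest), \code{centroids}, iterations used and the
#'   final centroid change.
#' @export
fuzzy_cmeans <- function(image, n_classes = 3L, m = 2, tol = 1e-5,
                         max_iter = 200L, seed = 1L) {
  stopifnot(length(image) > 0, m > 1, n_classes >= 2)
  x <- as.vector(image)
  if (length(unique(x)) < n_classes)
    stop("fewer distinct intensity values than classes")
  set.seed(as.integer(seed))
  probs <- (seq_len(n_classes) - 0.5) / n_classes
  v <- stats::quantile(x, probs, names = FALSE) +
    stats::rnorm(n_classes, 0, diff(range(x)) * 0.01)
  v <- sort(v)
  expo <- 2 / (m - 1)
  u <- NULL
  it <- 0L; dv <- Inf
  while (it < max_iter) {
    it <- it + 1L
    d2 <- abs(outer(x, v, "-"))          # pixel-to-centroid distance
    d2 <- pmax(d2, 1e-12)
    inv <- d2^(-expo)
    u <- inv / rowSums(inv)
    um <- u^m
    v_new <- colSums(um * x) / colSums(um)
    dv <- max(abs(v_new - v))
    v <- v_new
    if (dv < tol) break
  }
  ord <- order(v)
  v <- v[ord]; u <- u[, ord, drop = FALSE]
  hard <- max.col(u, ties.method = "first")
  structure(list(membership = u,
                 labels = matrix(hard, nrow(image), ncol(image)),
                 centroids = v, iterations = it, final_change = dv),
            class = "fcm_result")
}

## Weighted within-class distance objective of an FCM state; used by the
## monotonicity property test.
fcm_objective <- function(x, u, v, m = 2) {
  d2 <- (outer(as.vector(x), v, "-"))^2
  sum(u^m * d2)
}

#' Tikhonov smoothing of a 1D skin-elevation profile
#'
#' Solves \eqn{\min_u \|u - d\|^2 + \lambda \|D_2 u\|^2} exactly, where
#' \eqn{D_2} is the second-difference operator (curvature penalty with
#' natural boundary conditions).
#'
#' @param profile numeric vector of elevation samples (mm).
#' @param lambda regularisation weight, >= 0.
#' @return smoothed numeric vector of the same length.
#' @export
tikhonov_smooth <- function(profile, lambda) {
  stopifnot(length(profile) >= 3, lambda >= 0, all(is.finite(profile)))
  if (lambda == 0) return(profile)
  n <- length(profile)
  D <- second_difference_matrix(n)
  A <- Matrix::Diagonal(n) + lambda * Matrix::crossprod(D)
  as.vector(Matrix::solve(A, profile))
}

second_difference_matrix <- function(n) {
  i <- rep(seq_len(n - 2L), each = 3L)
  j <- as.vector(vapply(seq_len(n - 2L), function(k) k + 0:2,
                        integer(3)))
  x <- rep(c(1, -2, 1), n - 2L)
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n - 2L, n))
}

#' Extract the tissue/background interface contour from a mask or label map
#'
#' Traces the boundary of the foreground region along pixel edges, so the
#' enclosed polygon area equals the foreground pixel count times the pixel
#' area exactly.  Requires a single connected foreground component.
#'
#' @param x a \code{tissue_label_map} or a logical/0-1 matrix.
#' @param pixel_pitch mm per pixel (ignored when \code{x} is a label map).
#' @param origin physical coordinates of the grid corner (mm).
#' @return closed simple polyline (matrix of x, y in mm), counter-clockwise.
#' @export
extract_contour <- function(x, pixel_pitch = 1, origin = c(0, 0)) {
  if (inherits(x, "tissue_label_map")) {
    mask <- tissue_mask(x)
    pixel_pitch <- x$pixel_pitch
    origin <- x$origin
  } else {
    mask <- x > 0
  }
  if (!any(mask)) stop("no foreground component")
  if (n_components4(mask) != 1L)
    stop("foreground must be a single connected component")
  loops <- trace_mask_loops(mask, pixel_pitch, origin)
  areas <- vapply(loops, polygon_area, numeric(1))
  outer_loop <- loops[[which.max(abs(areas))]]
  if (polygon_area(outer_loop) < 0) outer_loop <- outer_loop[rev(seq_len(nrow(outer_loop))), ]
  simplify_collinear(outer_loop)
}

## Count 4-connected components of a binary mask (label propagation).
n_components4 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  repeat {
    nr <- nrow(lab); nc <- ncol(lab)
    nb <- pmax(
      rbind(lab[1, , drop = FALSE] * 0L, lab[-nr, , drop = FALSE]),
      rbind(lab[-1, , drop = FALSE], lab[nr, , drop = FALSE] * 0L),
      cbind(lab[, 1, drop = FALSE] * 0L, lab[, -nc, drop = FALSE]),
      cbind(lab[, -1, drop = FALSE], lab[, nc, drop = FALSE] * 0L))
    new_lab <- pmax(lab, nb * (lab > 0L))
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  length(unique(lab[lab > 0L]))
}

#' Skin elevation profile of a label map
#'
#' For each image column, the highest foreground extent (mm); the 1D signal
#' the Tikhonov smoother operates on.
#'
#' @param map a \code{tissue_label_map}.
#' @return numeric vector, one sample per column containing tissue;
#'   \code{NA} for empty columns.
#' @export
skin_profile <- function(map) {
  mask <- tissue_mask(map)
  apply(mask, 2, function(col) {
    w <- which(col)
    if (length(w) == 0) NA_real_ else max(w) * map$pixel_pitch
  })
}
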