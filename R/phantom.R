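#' Specification of a synthetic 2D breast phantom
#'
#' The phantom emulates a single sagittal cross-section of a breast: a
#' perturbed half-ellipse of soft tissue attached to a vertical chest wall,
#' a thin skin layer, scattered glandular tissue inside a dominant fat
#' compartment, and an ellipsoidal tumour bed above the nipple.
#'
#' @param chest_wall_length vertical extent of the chest wall (mm).
#' @param breast_protrusion maximal anterior protrusion of the breast (mm).
#' @param glandular_fraction fraction of the interior (fat + glandular)
#'   occupied by glandular tissue, in (0, 1).
#' @param skin_thickness skin layer thickness (mm).
#' @param tumor_center centre of the tumour bed (x, y) in mm.
#' @param tumor_axes full major/minor axes of the tumour bed (mm).
#' @param tumor_orientation orientation of the tumour major axis (radians
#'   from the x axis).
#' @param nipple_position nipple landmark (x, y) in mm.
#' @param pixel_pitch raster resolution (mm per pixel).
#' @param rng_seed integer seed controlling the random glandular texture
#'   and outline perturbation.
#' @return an object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(chest_wall_length = 120,
                         breast_protrusion = 70,
                         glandular_fraction = 0.25,
                         skin_thickness = 1,
                         tumor_center = c(23, 70),
                         tumor_axes = c(12, 9),
                         tumor_orientation = pi / 2,
                         nipple_position = c(breast_protrusion,
                                             chest_wall_length / 2),
                         pixel_pitch = 0.7031,
                         rng_seed = 20120507L) {
  stopifnot(chest_wall_length > 0, breast_protrusion > 0,
            glandular_fraction >= 0, glandular_fraction < 1,
            skin_thickness > 0, pixel_pitch > 0,
            length(tumor_center) == 2, length(tumor_axes) == 2,
            all(tumor_axes > 0))
  structure(list(chest_wall_length = chest_wall_length,
                 breast_protrusion = breast_protrusion,
                 glandular_fraction = glandular_fraction,
                 skin_thickness = skin_thickness,
                 tumor_center = tumor_center,
                 tumor_axes = tumor_axes,
                 tumor_orientation = tumor_orientation,
                 nipple_position = nipple_position,
                 pixel_pitch = pixel_pitch,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

## Tissue label codes used throughout the package.
TISSUE_LEVELS <- c(background = 0L, fat = 1L, glandular = 2L,
                   skin = 3L, chest = 4L)

## Radius profile of the breast outline as a function of the polar angle
## around the mid chest wall; half-ellipse plus a smooth seeded perturbation
## and a gentle nipple bump.
phantom_outline_radius <- function(theta, spec) {
  a <- spec$breast_protrusion
  b <- spec$chest_wall_length / 2
  r0 <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  set.seed(derive_seed(spec$rng_seed, 1L))
  amp <- stats::rnorm(3, 0, 0.015)
  phs <- stats::runif(3, 0, 2 * pi)
  pert <- amp[1] * sin(2 * theta + phs[1]) + amp[2] * sin(3 * theta + phs[2]) +
    amp[3] * sin(4 * theta + phs[3])
  nip_th <- atan2(spec$nipple_position[2] - b, spec$nipple_position[1])
  bump <- 0.04 * exp(-((theta - nip_th) / 0.18)^2)
  r0 * (1 + pert + bump)
}

#' Generate a synthetic tissue label map
#'
#' Rasterises the phantom outline, labels the chest-wall band, grows a thin
#' skin layer along the breast/background interface and distributes
#' glandular tissue as smoothed random blobs biased toward the retro-areolar
#' region, thresholded so that the requested glandular fraction of the
#' interior is met.
#'
#' @param spec a [phantom_spec()].
#' @return a \code{tissue_label_map}: list with \code{labels} (integer
#'   matrix, row 1 at y = 0), \code{pixel_pitch}, \code{origin} and the
#'   originating spec.  Label codes: 0 background, 1 fat, 2 glandular,
#'   3 skin, 4 chest.
#' @export
generate_phantom <- function(spec) {
  p <- spec$pixel_pitch
  chest_depth <- 3  # mm of chest-wall band kept in the domain
  nx <- ceiling((spec$breast_protrusion * 1.12 + chest_depth) / p)
  ny <- ceiling(spec$chest_wall_length / p)
  ## pixel centres
  xs <- (seq_len(nx) - 0.5) * p
  ys <- (seq_len(ny) - 0.5) * p
  X <- matrix(xs, ny, nx, byrow = TRUE)
  Y <- matrix(ys, ny, nx)
  b <- spec$chest_wall_length / 2
  theta <- atan2(Y - b, X)
  r <- sqrt(X^2 + (Y - b)^2)
  rmax <- matrix(phantom_outline_radius(as.vector(theta), spec), ny, nx)
  tissue <- r <= rmax & X >= 0
  labels <- matrix(TISSUE_LEVELS[["background"]], ny, nx)
  labels[tissue] <- TISSUE_LEVELS[["fat"]]
  chest <- tissue & X <= chest_depth
  labels[chest] <- TISSUE_LEVELS[["chest"]]

  ## tumour-bed validity: effective ellipse must stay inside the tissue,
  ## at least skin_thickness + 1 mm clear of the outline
  tb <- tumor_boundary_points(spec)
  tb_th <- atan2(tb[, 2] - b, tb[, 1])
  tb_r <- sqrt(tb[, 1]^2 + (tb[, 2] - b)^2)
  lim <- phantom_outline_radius(tb_th, spec) - (spec$skin_thickness + 1)
  if (any(tb_r > lim) || any(tb[, 1] < chest_depth))
    stop("tumor ellipse is not strictly inside the breast interior")

  ## skin: tissue pixels within skin_thickness of background
  k <- max(1L, as.integer(round(spec$skin_thickness / p)))
  bg <- !tissue
  near_bg <- bg
  for (i in seq_len(k)) near_bg <- dilate4(near_bg)
  skin <- tissue & near_bg & !chest
  labels[skin] <- TISSUE_LEVELS[["skin"]]

  ## glandular texture: smoothed seeded noise biased toward the nipple line
  interior <- tissue & !skin & !chest
  set.seed(derive_seed(spec$rng_seed, 2L))
  noise <- matrix(stats::rnorm(ny * nx), ny, nx)
  sm <- smooth_field(noise, passes = as.integer(round(4 / p)))
  nip <- spec$nipple_position
  d2 <- ((X - 0.55 * nip[1])^2 + (Y - nip[2])^2) / (0.45 * b)^2
  field <- sm / stats::sd(sm) - 0.6 * d2
  vals <- field[interior]
  thr <- stats::quantile(vals, 1 - spec$glandular_fraction, names = FALSE)
  gl <- interior & field > thr
  labels[gl] <- TISSUE_LEVELS[["glandular"]]

  structure(list(labels = labels, pixel_pitch = p, origin = c(0, 0),
                 spec = spec),
            class = "tissue_label_map")
}

## Points on the effective tumour-bed ellipse boundary (full axes in mm).
tumor_boundary_points <- function(spec, margin = 0, n = 72L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-1L]
  a <- spec$tumor_axes[1] / 2 + margin
  bb <- spec$tumor_axes[2] / 2 + margin
  co <- cos(spec$tumor_orientation); si <- sin(spec$tumor_orientation)
  ex <- a * cos(th); ey <- bb * sin(th)
  cbind(spec$tumor_center[1] + co * ex - si * ey,
        spec$tumor_center[2] + si * ex + co * ey)
}

## 4-neighbour binary dilation.
dilate4 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  out[-1, ] <- out[-1, ] | m[-nr, ]
  out[-nr, ] <- out[-nr, ] | m[-1, ]
  out[, -1] <- out[, -1] | m[, -nc]
  out[, -nc] <- out[, -nc] | m[, -1]
  out
}

## Cheap separable box smoothing, repeated.
smooth_field <- function(m, passes = 4L) {
  for (i in seq_len(max(1L, passes))) {
    nr <- nrow(m); nc <- ncol(m)
    m <- (m +
            rbind(m[1, , drop = FALSE], m[-nr, , drop = FALSE]) +
            rbind(m[-1, , drop = FALSE], m[nr, , drop = FALSE]) +
            cbind(m[, 1, drop = FALSE], m[, -nc, drop = FALSE]) +
            cbind(m[, -1, drop = FALSE], m[, nc, drop = FALSE])) / 5
  }
  m
}

#' Tissue mask helpers
#' @param map a \code{tissue_label_map}.
#' @return logical matrix marking non-background pixels.
#' @export
tissue_mask <- function(map) map$labels != TISSUE_LEVELS[["background"]]

#' Generate an MRI-like grayscale image from a label map
#'
#' Each pixel takes its class mean intensity plus Gaussian noise, clipped
#' to the 8-bit range.
#'
#' @param map a \code{tissue_label_map}.
#' @param class_means named intensities for classes background, fat,
#'   glandular, skin, chest.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param seed integer seed.
#' @return numeric matrix (same shape as the label grid) in [0, 255].
#' @export
generate_mri_image <- function(map,
                               class_means = c(background = 20, fat = 200,
                                               glandular = 120, skin = 170,
                                               chest = 90),
                               noise_sd = 0, seed = 1L) {
  stopifnot(inherits(map, "tissue_label_map"), noise_sd >= 0)
  if (anyDuplicated(class_means[c("background", "fat", "glandular")]))
    stop("class means must be distinct")
  lab <- map$labels
  img <- matrix(class_means[match(lab, TISSUE_LEVELS)], nrow(lab), ncol(lab))
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                        nrow(img), ncol(img))
  }
  pmin(pmax(img, 0), 255)
}

#' Generate a noisy synthetic contour observation for one healing phase
#'
#' Runs the forward model at known true parameters, converts the predicted
#' skin contour to "photograph units" by dividing by the applied aspect
#' ratio (about the contour centroid), and perturbs vertices along their
#' local outward normals with Gaussian noise.  Used to plant ground truth
#' for calibration experiments.
#'
#' @param study a study context from [study_setup()].
#' @param phase one of \code{"0"}, \code{"I"}, \code{"II"}, \code{"III"}.
#' @param true_params named numeric vector of the phase's unknown
#'   parameters (see [simulate_phase()]).
#' @param noise_sd contour noise standard deviation (mm).
#' @param aspect_ratio applied aspect ratio (mm per photo unit); the
#'   calibration nuisance \code{s} recovers it.
#' @param seed integer seed for the noise (and the healing CA of phase II).
#' @return a \code{synthetic_observation}: list with the observed contour,
#'   phase id, true parameters, noise level and applied aspect ratio.
#' @export
generate_observation <- function(study, phase, true_params, noise_sd = 0,
                                 aspect_ratio = 1, seed = 1L) {
  stopifnot(noise_sd >= 0, aspect_ratio > 0)
  clean <- simulate_phase(study, phase, true_params, seed = seed)
  ctr <- polygon_centroid(clean)
  obs <- sweep(sweep(clean, 2, ctr), 2, c(1, 1) / aspect_ratio, `*`)
  obs <- sweep(obs, 2, ctr, `+`)
  if (noise_sd > 0) {
    set.seed(derive_seed(as.integer(seed), 91L))
    nrm <- polyline_normals(obs)
    obs <- obs + nrm * stats::rnorm(nrow(obs), 0, noise_sd / aspect_ratio)
  }
  structure(list(contour = obs, phase = phase, true_params = true_params,
                 noise_sd = noise_sd, aspect_ratio = aspect_ratio,
                 seed = as.integer(seed)),
            class = "synthetic_observation")
}

## Unit outward normals at vertices of a closed polyline (CCW assumed).
polyline_normals <- function(poly) {
  n <- nrow(poly)
  nxt <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  prv <- rbind(poly[n, , drop = FALSE], poly[-n, , drop = FALSE])
  t <- nxt - prv
  len <- sqrt(rowSums(t^2)); len[len == 0] <- 1
  cbind(t[, 2], -t[, 1]) / len
}
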