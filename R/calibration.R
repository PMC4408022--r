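#' Rasterise a contour onto a square region of interest
#'
#' Marks every grid cell crossed by the polyline, on a grid at the MRI
#' resolution.  Cells are addressed from the ROI origin.
#'
#' @param contour closed polyline (mm).
#' @param roi list with \code{origin} (x, y) and \code{size} (mm).
#' @param resolution grid cell size (mm), default the MRI pixel pitch.
#' @return a \code{raster_contour}: logical matrix plus ROI metadata.
#' @export
rasterize_contour <- function(contour, roi, resolution = 0.7031) {
  if (is.null(contour) || nrow(contour) < 2) stop("empty contour")
  n <- ceiling(roi$size / resolution)
  ## densely sample each segment so no crossed cell is skipped
  closed <- rbind(contour, contour[1, , drop = FALSE])
  seglen <- sqrt(rowSums(diff(closed)^2))
  pts <- vector("list", nrow(contour))
  for (k in seq_len(nrow(contour))) {
    m <- max(2L, ceiling(seglen[k] / (resolution / 4)))
    t <- seq(0, 1, length.out = m)
    pts[[k]] <- cbind(closed[k, 1] + t * (closed[k + 1, 1] - closed[k, 1]),
                      closed[k, 2] + t * (closed[k + 1, 2] - closed[k, 2]))
  }
  pts <- do.call(rbind, pts)
  ci <- floor((pts[, 1] - roi$origin[1]) / resolution) + 1L
  ri <- floor((pts[, 2] - roi$origin[2]) / resolution) + 1L
  if (any(ci < 1 | ci > n | ri < 1 | ri > n))
    stop("contour extends outside the ROI")
  G <- matrix(FALSE, n, n)
  G[unique(cbind(ri, ci))] <- TRUE
  structure(list(grid = G, roi = roi, resolution = resolution),
            class = "raster_contour")
}

## Default square ROI jointly covering both contours, anchored at the
## shared bounding-box centre so the objective is invariant to common
## rigid translations.
default_roi <- function(model, gt, resolution, s_range = c(0.5, 2)) {
  ctr_gt <- polygon_centroid(gt)
  ext <- function(poly) max(abs(sweep(poly, 2, ctr_gt)))
  reach <- max(ext(model), ext(gt) * max(s_range, 1)) + 15
  size <- 2 * reach
  list(origin = c(ctr_gt[1] - reach, ctr_gt[2] - reach), size = size)
}

#' Contour-mismatch objective
#'
#' Rasterises the model contour and the ground-truth contour scaled by the
#' aspect-ratio nuisance \code{s} (about the ground-truth centroid) on a
#' common ROI and counts mismatched cells (symmetric difference of the two
#' indicator grids).  Zero iff the rasters coincide.
#'
#' @param model_contour predicted contour (mm).
#' @param gt_contour observed contour.
#' @param s aspect-ratio scale applied to the observed contour.
#' @param roi optional ROI (defaults to a joint bounding box).
#' @param resolution raster cell size (mm).
#' @return non-negative mismatch count.
#' @export
objective_f <- function(model_contour, gt_contour, s = 1, roi = NULL,
                        resolution = 0.7031) {
  if (is.null(roi)) roi <- default_roi(model_contour, gt_contour, resolution)
  rm_ <- rasterize_contour(model_contour, roi, resolution)
  rg <- rasterize_contour(scale_contour(gt_contour, s), roi, resolution)
  sum(xor(rm_$grid, rg$grid))
}

## Scale a contour about its own centroid.
scale_contour <- function(poly, s) {
  ctr <- polygon_centroid(poly)
  sweep(sweep(poly, 2, ctr), 2, c(s, s), `*`) + rep(ctr, each = nrow(poly))
}

## Mismatch of a model raster against cached scaled-gt rasters; returns
## min over the s grid (with the minimising s).
objective_over_s <- function(model_raster, gt_rasters, s_grid) {
  f <- vapply(gt_rasters, function(g) sum(xor(model_raster$grid, g$grid)),
              numeric(1))
  k <- which.min(f)
  c(f = f[k], s = s_grid[k])
}

#' Set up the synthetic calibration study
#'
#' Builds the phantom, the baseline mesh, and the post-lumpectomy mesh
#' with the cavity placed at the tumour bed, and records the fixed model
#' parameters shared by all phases.
#'
#' @param spec a [phantom_spec()].
#' @param target_size mesh element size (mm).
#' @param base_E baseline Young moduli (kPa) named fat, glandular, skin
#'   (the planted phase-0 truth for synthetic studies).
#' @param E_inflamed inflammation modulus (kPa).
#' @param inflamed_width inflamed ring width (mm).
#' @param healing a [healing_params()] carrying the fixed biology values.
#' @param weeks_phase2 healing duration of the proliferative phase (weeks).
#' @return a \code{bct_study} context consumed by [simulate_phase()] and
#'   [fit_phase()].
#' @export
study_setup <- function(spec = phantom_spec(), target_size = 2,
                        base_E = c(fat = 3.7, glandular = 9.5, skin = 25),
                        E_inflamed = 80, inflamed_width = 5,
                        healing = healing_params(), weeks_phase2 = 19) {
  map <- generate_phantom(spec)
  mesh0 <- build_mesh(map, target_size)
  cav <- cavity_spec(center = spec$tumor_center, bed_axes = spec$tumor_axes,
                     margin = 5, orientation = spec$tumor_orientation)
  mesh_cav <- apply_virtual_lumpectomy(mesh0, cav)
  env <- new.env(parent = emptyenv())   # caches (fe setups, trajectories)
  structure(list(spec = spec, map = map, mesh0 = mesh0, mesh_cav = mesh_cav,
                 cavity = cav, base_E = base_E, E_inflamed = E_inflamed,
                 inflamed_width = inflamed_width, healing = healing,
                 weeks_phase2 = weeks_phase2, cache = env),
            class = "bct_study")
}

study_materials <- function(study, E = study$base_E, E_scar = 24) {
  material_params(E_fat = E[["fat"]], E_glandular = E[["glandular"]],
                  E_skin = E[["skin"]], E_scar = E_scar,
                  E_inflamed = study$E_inflamed)
}

cached_setup <- function(study, key, mesh) {
  if (is.null(study$cache[[key]])) study$cache[[key]] <- fe_setup(mesh)
  study$cache[[key]]
}

## Phase II wound trajectory depends only on (alpha0, seed) when
## alpha1 = 0; cache it across the (lambda2, alpha0) grid.
phase2_mesh <- function(study, alpha0, seed) {
  key <- paste0("ph2_", format(alpha0, digits = 12), "_", seed)
  if (is.null(study$cache[[key]])) {
    hp <- study$healing
    hp$alpha0 <- alpha0
    traj <- coupling_loop(study$mesh_cav, study_materials(study), hp,
                          weeks = study$weeks_phase2, seed = seed)
    study$cache[[key]] <- traj
  }
  study$cache[[key]]
}

#' Forward model of one healing phase
#'
#' Returns the outer breast contour of the loaded (seated) equilibrium for
#' the phase's configuration:
#' \describe{
#'   \item{Phase 0}{pre-surgery baseline: \code{alpha = c(E_fat,
#'     E_glandular, E_skin)} (kPa), no cavity.}
#'   \item{Phase I}{inflammation: \code{alpha = c(lambda1, P)}; fat and
#'     glandular moduli scaled by lambda1, skin unchanged, an inflamed
#'     ring of fixed width at the inflammation modulus around the cavity,
#'     and seroma pressure P (Pa) on the cavity wall.}
#'   \item{Phase II}{proliferation: \code{alpha = c(lambda2, alpha0)};
#'     baseline moduli, zero pressure, coupled healing for the configured
#'     number of weeks, lambda2 scaling fat/glandular/scar afterwards.}
#'   \item{Phase III}{radiotherapy: \code{alpha = c(lambda3, E_scar)};
#'     wound closed, former cavity filled with scar at E_scar, fat and
#'     glandular scaled by lambda3.}
#' }
#'
#' @param study a [study_setup()] context.
#' @param phase \code{"0"}, \code{"I"}, \code{"II"} or \code{"III"}.
#' @param alpha named or positional numeric parameter vector (see above).
#' @param seed seed for the phase-II healing CA.
#' @param warm optional warm-start displacement.
#' @return predicted contour (matrix, mm); the solved
#'   \code{mechanical_state} is attached as attribute \code{"state"}.
#' @export
simulate_phase <- function(study, phase = c("0", "I", "II", "III"), alpha,
                           seed = 1L, warm = NULL) {
  phase <- match.arg(as.character(phase), c("0", "I", "II", "III"))
  alpha <- unname(alpha)
  seated <- load_case("seated")
  if (phase == "0") {
    stopifnot(length(alpha) == 3)
    mats <- study_materials(study, E = c(fat = alpha[1], glandular = alpha[2],
                                         skin = alpha[3]))
    st <- solve_equilibrium(study$mesh0, mats, seated, u0 = warm,
                            setup = cached_setup(study, "mesh0", study$mesh0))
    ctr <- mesh_skin_contour(study$mesh0, st$u)
  } else if (phase == "I") {
    stopifnot(length(alpha) == 2)
    lambda1 <- alpha[1]; P <- alpha[2]
    mats <- study_materials(study)
    mats <- scale_materials(mats, lambda1, which = c("fat", "glandular"))
    mesh <- mark_inflamed_ring(study$mesh_cav, study$inflamed_width)
    st <- solve_equilibrium(mesh, mats, load_case("seated", pressure = P),
                            u0 = warm,
                            setup = cached_setup(study, "mesh_cav", mesh))
    ctr <- mesh_skin_contour(mesh, st$u)
  } else if (phase == "II") {
    stopifnot(length(alpha) == 2)
    lambda2 <- alpha[1]; alpha0 <- alpha[2]
    traj <- phase2_mesh(study, alpha0, seed)
    mesh <- traj$mesh
    mats <- scale_materials(study_materials(study), lambda2,
                            which = c("fat", "glandular", "scar"))
    key <- paste0("ph2mesh_", format(alpha0, digits = 12), "_", seed)
    st <- solve_equilibrium(mesh, mats, seated, u0 = warm,
                            setup = cached_setup(study, key, mesh))
    ctr <- mesh_skin_contour(mesh, st$u)
  } else {
    stopifnot(length(alpha) == 2)
    lambda3 <- alpha[1]; E_scar <- alpha[2]
    key <- "ph3mesh"
    if (is.null(study$cache[[key]]))
      study$cache[[key]] <- remesh_from_wound(study$mesh_cav, NULL)
    mesh <- study$cache[[key]]
    mats <- study_materials(study, E_scar = E_scar)
    mats <- scale_materials(mats, lambda3, which = c("fat", "glandular"))
    st <- solve_equilibrium(mesh, mats, seated, u0 = warm,
                            setup = cached_setup(study, "ph3mesh_fe", mesh))
    ctr <- mesh_skin_contour(mesh, st$u)
  }
  attr(ctr, "state") <- st
  ctr
}

#' Grid-search calibration of one phase against an observed contour
#'
#' Evaluates the contour objective exhaustively on a parameter grid,
#' minimising the aspect-ratio nuisance \code{s} over a fixed scale grid
#' per point, and returns the full objective surface with its argmin.
#'
#' @param study a [study_setup()] context.
#' @param phase phase id.
#' @param observation a \code{synthetic_observation} or a bare contour
#'   matrix.
#' @param grid named list of parameter-axis vectors (in phase order).
#' @param s_grid aspect-ratio search grid.
#' @param resolution raster resolution (mm).
#' @param seed healing seed used by the phase-II forward model (must match
#'   the observation's).
#' @return a \code{phase_fit}: \code{surface} (array of f values),
#'   \code{axes}, \code{argmin} (named parameters), \code{s_hat},
#'   \code{f_min}, and the per-point minimising s.
#' @export
fit_phase <- function(study, phase, observation, grid, s_grid = NULL,
                      resolution = 0.7031, seed = NULL) {
  gt <- if (inherits(observation, "synthetic_observation"))
    observation$contour else observation
  if (is.null(seed))
    seed <- if (inherits(observation, "synthetic_observation"))
      observation$seed else 1L
  if (is.null(s_grid))
    s_grid <- sort(unique(c(1, seq(0.5, 2, by = 0.025))))
  axes <- grid
  dims <- vapply(axes, length, integer(1))
  pts <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  ## snake order over the grid so consecutive forward solves are close
  ord <- snake_order(dims)
  roi <- NULL
  fvals <- numeric(nrow(pts)); svals <- numeric(nrow(pts))
  warm <- NULL
  done <- 0L
  for (k in ord) {
    done <- done + 1L
    if (done %% 25L == 0L) gc(FALSE)  # release factorisation arrears
    ctr <- simulate_phase(study, phase, pts[k, ], seed = seed, warm = warm)
    warm <- attr(ctr, "state")$u
    if (is.null(roi)) {
      roi <- default_roi(ctr, gt, resolution,
                         s_range = range(s_grid))
      gt_rasters <- lapply(s_grid, function(s)
        rasterize_contour(scale_contour(gt, s), roi, resolution))
    }
    mr <- rasterize_contour(ctr, roi, resolution)
    fs <- objective_over_s(mr, gt_rasters, s_grid)
    fvals[k] <- fs["f"]; svals[k] <- fs["s"]
  }
  surface <- array(fvals, dim = dims, dimnames = lapply(axes, format))
  k_min <- which.min(fvals)
  argmin <- pts[k_min, ]
  names(argmin) <- names(axes)
  structure(list(surface = surface, axes = axes, argmin = argmin,
                 s_hat = svals[k_min], f_min = fvals[k_min],
                 s_per_point = array(svals, dim = dims),
                 phase = phase, seed = seed),
            class = "phase_fit")
}

## Visit grid points in an order where consecutive points differ by one
## step along the first axis (boustrophedon over the flattened grid).
snake_order <- function(dims) {
  n1 <- dims[1]
  rest <- prod(dims) / n1
  idx <- integer(0)
  for (b in seq_len(rest)) {
    blk <- ((b - 1) * n1 + 1):(b * n1)
    if (b %% 2 == 0) blk <- rev(blk)
    idx <- c(idx, blk)
  }
  idx
}

#' Range of the objective surface along each parameter axis
#'
#' For sensitivity reading: the mean over the other axes of the per-slice
#' range along the named axis.
#'
#' @param fit a \code{phase_fit}.
#' @return named numeric vector of ranges, one per axis.
#' @export
surface_axis_ranges <- function(fit) {
  s <- fit$surface
  nd <- length(dim(s))
  out <- numeric(nd)
  for (d in seq_len(nd)) {
    rng <- apply(s, setdiff(seq_len(nd), d), function(v) diff(range(v)))
    out[d] <- mean(rng)
  }
  stats::setNames(out, names(fit$axes))
}

#' Default planted truths and search grids for the synthetic study
#'
#' The truths are the package's reference patient scenario (baseline
#' moduli 3.7 / 9.5 / 25 kPa;
#' inflammation lambda1 = 2.0 with 120 Pa seroma pressure; proliferation
#' lambda2 = 1.2 with alpha0 = 0.17; radiotherapy lambda3 = 1.7 with a
#' 24 kPa scar).  The grids span the physiological search ranges and are
#' spaced so every truth lies on a grid point, which makes exact recovery
#' a well-posed check.
#'
#' @return list with elements \code{truths} and \code{grids}, each a named
#'   list over phases \code{"0"}, \code{"I"}, \code{"II"}, \code{"III"}.
#' @export
default_study_design <- function() {
  truths <- list("0" = c(E_fat = 3.7, E_glandular = 9.5, E_skin = 25),
                 "I" = c(lambda1 = 2.0, P = 120),
                 "II" = c(lambda2 = 1.2, alpha0 = 0.17),
                 "III" = c(lambda3 = 1.7, E_scar = 24))
  grids <- list("0" = list(E_fat = seq(2, 13.9, by = 1.7),
                           E_glandular = seq(5, 14, by = 1.5),
                           E_skin = seq(5, 30, by = 2.5)),
                "I" = list(lambda1 = seq(1, 3, by = 0.2),
                           P = seq(0, 480, by = 40)),
                "II" = list(lambda2 = seq(1, 3, by = 0.2),
                            alpha0 = seq(0, 0.595, by = 0.085)),
                "III" = list(lambda3 = seq(1, 3, by = 0.1),
                             E_scar = seq(10, 80, by = 7)))
  list(truths = truths, grids = grids)
}

#' Run the four-phase synthetic calibration study end to end
#'
#' Generates noiseless observations at planted true parameters, fits each
#' phase by grid search (threading the fitted phase-0 moduli forward),
#' and reports per-phase fits and cosmesis metrics.
#'
#' @param study a [study_setup()] context.
#' @param truths named list of true parameter vectors for phases
#'   \code{"0"}, \code{"I"}, \code{"II"}, \code{"III"}.
#' @param grids named list of grid axis lists per phase.
#' @param noise_sd contour observation noise (mm).
#' @param aspect_ratio applied observation aspect ratio.
#' @param seed master seed.
#' @return a \code{bct_report} with per-phase fits, observations, metrics
#'   and the configuration.
#' @export
run_full_study <- function(study, truths = default_study_design()$truths,
                           grids = default_study_design()$grids,
                           noise_sd = 0,
                           aspect_ratio = 1, seed = 1L) {
  phases <- c("0", "I", "II", "III")
  if (!identical(names(truths), phases) || !identical(names(grids), phases))
    stop("truths and grids must be named lists for phases 0, I, II, III ",
         "in order")
  fits <- list(); obs <- list()
  for (ph in phases) {
    o <- generate_observation(study, ph, truths[[ph]], noise_sd = noise_sd,
                              aspect_ratio = aspect_ratio,
                              seed = derive_seed(seed, match(ph, phases)))
    fit <- fit_phase(study, ph, o, grids[[ph]])
    if (ph == "0") {
      ## thread fitted moduli into the later phases
      study$base_E <- c(fat = unname(fit$argmin[1]),
                        glandular = unname(fit$argmin[2]),
                        skin = unname(fit$argmin[3]))
    }
    obs[[ph]] <- o; fits[[ph]] <- fit
  }
  ## cosmesis metrics from the fitted forward contours
  ctr0 <- simulate_phase(study, "0", fits[["0"]]$argmin)
  ctr1 <- simulate_phase(study, "I", fits[["I"]]$argmin)
  metrics <- list(
    nipple_elevation_phase1 = nipple_height_difference(ctr1, ctr0),
    lateral_area_gain_phase1 =
      lateral_disc_area(ctr1, radius = 60) - lateral_disc_area(ctr0, radius = 60))
  structure(list(fits = fits, observations = obs, metrics = metrics,
                 truths = truths, grids = grids, seed = seed,
                 noise_sd = noise_sd),
            class = "bct_report")
}

#' Serialise a study report to JSON
#' @param report a \code{bct_report}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- list(seed = report$seed, noise_sd = report$noise_sd,
              phases = lapply(report$fits, function(f)
                list(argmin = as.list(f$argmin), s_hat = f$s_hat,
                     f_min = f$f_min,
                     axis_ranges = as.list(surface_axis_ranges(f)))),
              metrics = report$metrics)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
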