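#' Parameters of the mechano-biological healing model
#'
#' @param D growth-factor diffusion coefficient (cm^2/day).
#' @param Lambda growth-factor decay rate (1/day).
#' @param alpha0 baseline division probability coefficient, in [0, 0.6].
#' @param alpha1 mechano-sensitivity coefficient (dimensionless).
#' @param active_width active-layer width (mm): the band of occupied sites
#'   adjacent to the wound edge that produces growth factor.
#' @param c_threshold cut-off concentration for the division gate F;
#'   \code{NULL} defaults to 10\% of the steady active-layer level.
#' @param ca_step CA clock (days per division sweep); the default of one
#'   sweep per week matches the cell-cycle timescale and the weekly
#'   mechanics coupling.
#' @param coupling_interval days between mechanics/healing alternations.
#' @return a \code{healing_params}.
#' @export
healing_params <- function(D = 0.05, Lambda = 0, alpha0 = 0.17, alpha1 = 0,
                           active_width = 2.5, c_threshold = NULL,
                           ca_step = 7, coupling_interval = 7) {
  stopifnot(D > 0, Lambda >= 0, alpha0 >= 0, alpha1 >= 0, active_width > 0,
            ca_step > 0, coupling_interval > 0)
  structure(list(D = D, Lambda = Lambda, alpha0 = alpha0, alpha1 = alpha1,
                 active_width = active_width, c_threshold = c_threshold,
                 ca_step = ca_step, coupling_interval = coupling_interval),
            class = "healing_params")
}

## Build a hexagonal lattice patch covering a rectangle [x0,x1] x [y0,y1].
## Axial coordinates (q, r); site centres x = h (q + r/2), y = h sqrt(3)/2 r.
## Returns centres, a neighbour index matrix (n x 6, NA where absent) and
## the axial coordinates.
hex_patch <- function(xlim, ylim, h) {
  rmin <- floor(ylim[1] / (h * sqrt(3) / 2)) - 1L
  rmax <- ceiling(ylim[2] / (h * sqrt(3) / 2)) + 1L
  rows <- rmin:rmax
  qr <- do.call(rbind, lapply(rows, function(r) {
    qmin <- floor(xlim[1] / h - r / 2) - 1L
    qmax <- ceiling(xlim[2] / h - r / 2) + 1L
    cbind(q = qmin:qmax, r = r)
  }))
  x <- h * (qr[, 1] + qr[, 2] / 2)
  y <- h * sqrt(3) / 2 * qr[, 2]
  keep <- x >= xlim[1] - h & x <= xlim[2] + h &
    y >= ylim[1] - h & y <= ylim[2] + h
  qr <- qr[keep, , drop = FALSE]
  x <- x[keep]; y <- y[keep]
  key <- paste(qr[, 1], qr[, 2])
  idx <- seq_along(key)
  lookup <- stats::setNames(idx, key)
  dq <- c(1, -1, 0, 0, 1, -1)
  dr <- c(0, 0, 1, -1, -1, 1)
  nbr <- matrix(NA_integer_, nrow(qr), 6)
  for (d in 1:6) {
    nk <- paste(qr[, 1] + dq[d], qr[, 2] + dr[d])
    nbr[, d] <- lookup[nk]
  }
  list(centers = cbind(x = x, y = y), nbr = nbr, axial = qr, h = h,
       site_area = sqrt(3) / 2 * h^2, lap_weight = 2 / (3 * h^2))
}

#' One-dimensional chain lattice
#'
#' A degenerate lattice (sites on a line, two neighbours each) used to
#' verify the growth-factor solver against closed-form one-dimensional
#' solutions; the Laplacian weight is the standard 1/h^2 three-point
#' stencil.
#'
#' @param length chain extent (mm).
#' @param h site spacing (mm).
#' @return a lattice list as produced by the hexagonal patch builder.
#' @export
chain_lattice <- function(length, h) {
  x <- seq(0, length, by = h)
  n <- base::length(x)
  nbr <- cbind(c(NA, seq_len(n - 1L)), c(seq_len(n - 1L) + 1L, NA),
               NA, NA, NA, NA)
  list(centers = cbind(x = x, y = rep(0, n)), nbr = nbr,
       axial = cbind(q = seq_len(n), r = 0L), h = h, site_area = h,
       lap_weight = 1 / h^2)
}

#' Initialise the healing state on the unloaded cavity region
#'
#' Lays a hexagonal lattice over the cavity neighbourhood of the mesh:
#' sites inside the cavity are empty (wound), sites in tissue are occupied,
#' the patch rim carries the far-field Dirichlet condition for the growth
#' factor, and the active layer is the band of occupied sites within the
#' configured width of the wound edge.
#'
#' @param mesh a \code{breast_mesh} (the unloaded geometry) with a cavity;
#'   alternatively \code{NULL} when \code{wound_polygon} is given.
#' @param spacing lattice spacing (mm).
#' @param params a [healing_params()].
#' @param wound_polygon optional explicit wound polygon (mm) overriding the
#'   mesh cavity.
#' @param pad physical padding of the patch beyond the wound (mm);
#'   defaults to 4 diffusion-ish widths of the active layer.
#' @return a \code{healing_state}: lattice, occupancy, growth-factor field
#'   \code{c}, active-layer mask, elapsed time.
#' @export
init_healing <- function(mesh, spacing, params, wound_polygon = NULL,
                         pad = NULL) {
  wound <- if (!is.null(wound_polygon)) wound_polygon
           else cavity_wall_contour(mesh)
  if (is.null(pad)) pad <- max(4 * params$active_width, 10)
  state <- new_healing_state(wound, spacing, params, pad, mesh = mesh)
  state
}

new_healing_state <- function(wound, spacing, params, pad, mesh = NULL) {
  if (is.null(wound) || nrow(wound) < 3) {
    ## closed wound: degenerate state
    lat <- hex_patch(c(0, 4 * spacing), c(0, 4 * spacing), spacing)
    occ <- rep(TRUE, nrow(lat$centers))
    st <- structure(list(lattice = lat, occupied = occ,
                         c = rep(0, length(occ)),
                         active = rep(FALSE, length(occ)),
                         dirichlet = rep(FALSE, length(occ)),
                         params = params, time = 0, mesh = mesh,
                         Ehat = rep(0, length(occ))),
                    class = "healing_state")
    return(st)
  }
  rx <- range(wound[, 1]); ry <- range(wound[, 2])
  minor <- min(diff(rx), diff(ry))
  if (spacing > minor / 4)
    stop("lattice spacing too coarse for this cavity (need <= minor radius / 4)")
  lat <- hex_patch(rx + c(-pad, pad), ry + c(-pad, pad), spacing)
  inside <- points_in_polygon(lat$centers[, 1], lat$centers[, 2], wound)
  occ <- !inside
  ## restrict to tissue when a mesh is available: sites outside the meshed
  ## region are dropped from the patch
  if (!is.null(mesh)) {
    stat <- site_cell_status(mesh, lat$centers)
    keep <- inside | (stat > 0L)
    lat_keep <- which(keep)
    remap <- rep(NA_integer_, nrow(lat$centers))
    remap[lat_keep] <- seq_along(lat_keep)
    lat$centers <- lat$centers[lat_keep, , drop = FALSE]
    lat$nbr <- matrix(remap[lat$nbr[lat_keep, ]], length(lat_keep), 6)
    lat$axial <- lat$axial[lat_keep, , drop = FALSE]
    occ <- occ[lat_keep]
  }
  dirichlet <- rowSums(!is.na(lat$nbr)) < 6 & occ  # patch rim (far field)
  st <- structure(list(lattice = lat, occupied = occ,
                       c = rep(0, nrow(lat$centers)),
                       active = rep(FALSE, nrow(lat$centers)),
                       dirichlet = dirichlet,
                       params = params, time = 0, mesh = mesh,
                       Ehat = rep(0, nrow(lat$centers))),
                  class = "healing_state")
  st$active <- active_layer(st)
  st
}

## Cell status of the mesh cell containing each point (0 when outside).
site_cell_status <- function(mesh, pts) {
  ci <- floor((pts[, 1] - mesh$origin[1]) / mesh$h) + 1L
  ri <- floor((pts[, 2] - mesh$origin[2]) / mesh$h) + 1L
  ok <- ci >= 1L & ci <= ncol(mesh$status) & ri >= 1L & ri <= nrow(mesh$status)
  out <- rep(0L, nrow(pts))
  out[ok] <- mesh$status[cbind(ri[ok], ci[ok])]
  out
}

#' Wound-edge sites: empty sites adjacent to at least one occupied site
#' @param state a \code{healing_state}.
#' @return logical mask over lattice sites.
#' @export
wound_edge <- function(state) {
  occ <- state$occupied
  nbr_occ <- matrix(occ[state$lattice$nbr], nrow(state$lattice$nbr), 6)
  nbr_occ[is.na(nbr_occ)] <- FALSE
  !occ & rowSums(nbr_occ) > 0
}

## Active layer: occupied sites within the configured width (in lattice
## rings) of the wound edge.
active_layer <- function(state) {
  rings <- max(1L, round(state$params$active_width / state$lattice$h))
  occ <- state$occupied
  if (!any(!occ)) return(rep(FALSE, length(occ)))
  frontier <- !occ
  reached <- frontier
  for (k in seq_len(rings)) {
    nb <- state$lattice$nbr[which(frontier), , drop = FALSE]
    nb <- nb[!is.na(nb)]
    newly <- rep(FALSE, length(occ))
    newly[nb] <- TRUE
    newly <- newly & !reached
    reached <- reached | newly
    frontier <- newly
  }
  reached & occ
}

#' Integrate the growth-factor reaction-diffusion equation on the lattice
#'
#' Implicit-Euler integration of dc/dt = D Lap c - Lambda c + chi_active
#' on the occupied sites; no-flux at the wound wall (missing neighbours),
#' homogeneous Dirichlet on the far-field patch rim.  The hexagonal
#' 7-point Laplacian is (2 / (3 h^2)) * sum(c_j - c_i).
#'
#' @param state a \code{healing_state}.
#' @param duration days to integrate.
#' @param dt time step (days).
#' @param chi source value in the active layer (concentration/day).
#' @param steady if \code{TRUE}, iterate (with growing steps) until the
#'   per-day change is below \code{1e-6} instead of a fixed duration.
#' @return the state with an updated \code{c} field.
#' @export
solve_growth_factor <- function(state, duration = NULL, dt = 1, chi = 1,
                                steady = is.null(duration)) {
  p <- state$params
  h_mm <- state$lattice$h
  D <- p$D * 100 / 1  # cm^2/day -> mm^2/day
  occ_idx <- which(state$occupied)
  n <- length(occ_idx)
  if (n == 0) return(state)
  remap <- rep(NA_integer_, length(state$occupied))
  remap[occ_idx] <- seq_len(n)
  nbr <- matrix(remap[state$lattice$nbr[occ_idx, ]], n, 6)
  ii <- rep(seq_len(n), 6)
  jj <- as.vector(nbr)
  ok <- !is.na(jj)
  w <- state$lattice$lap_weight
  if (is.null(w)) w <- 2 / (3 * h_mm^2)
  L <- Matrix::sparseMatrix(i = ii[ok], j = jj[ok], x = w,
                            dims = c(n, n))
  deg <- Matrix::rowSums(L)
  L <- L - Matrix::Diagonal(n, deg)        # no-flux: missing links omitted
  chi_vec <- as.numeric(state$active[occ_idx]) * chi
  diri <- state$dirichlet[occ_idx]
  cvec <- state$c[occ_idx]
  step_once <- function(cvec, dt) {
    A <- Matrix::Diagonal(n, 1 / dt + p$Lambda) - D * L
    b <- cvec / dt + chi_vec
    if (any(diri)) {
      A[diri, ] <- 0
      A[cbind(which(diri), which(diri))] <- 1
      b[diri] <- 0
    }
    as.vector(Matrix::solve(A, b))
  }
  if (steady) {
    step <- dt
    for (it in 1:200) {
      cnew <- step_once(cvec, step)
      rate <- max(abs(cnew - cvec)) / step
      cvec <- cnew
      if (rate < 1e-6) break
      step <- min(step * 2, 1e6)
    }
  } else {
    nstep <- ceiling(duration / dt - 1e-9)
    dt_eff <- duration / nstep
    for (k in seq_len(nstep)) cvec <- step_once(cvec, dt_eff)
  }
  cvec <- pmax(cvec, 0)
  state$c[occ_idx] <- cvec
  state
}

#' Division probability per site
#'
#' \eqn{p = F(c) (\alpha_0 + \alpha_1 \hat{E})}, clamped to [0, 1];
#' the gate F is a hard threshold at the cut-off concentration.
#'
#' @param c growth-factor concentration per site.
#' @param Ehat normalised stress per site, in [0, 1].
#' @param params a [healing_params()].
#' @return probability vector.
#' @export
division_probability <- function(c, Ehat, params) {
  stopifnot(all(c >= -1e-12), all(Ehat >= -1e-12 & Ehat <= 1 + 1e-12))
  thr <- params$c_threshold
  if (is.null(thr)) {
    ref <- if (params$Lambda > 0) 1 / params$Lambda else max(c, 1)
    thr <- 0.1 * ref
  }
  Fgate <- as.numeric(c >= thr)
  pmin(pmax(Fgate * (params$alpha0 + params$alpha1 * Ehat), 0), 1)
}

#' One cellular-automaton division step
#'
#' Each empty wound-edge site is filled when at least one adjacent
#' occupied active-layer site succeeds in an independent division attempt
#' with its probability p, so the fill probability of an edge site is
#' 1 - prod(1 - p_neighbour).  Wound area never increases.
#'
#' @param state a \code{healing_state}.
#' @param p division probability per site (vector over all sites).
#' @param seed optional integer seed for reproducibility.
#' @return the updated state (time advanced by one CA step).
#' @export
step_ca <- function(state, p, seed = NULL) {
  stopifnot(all(p >= 0 & p <= 1))
  if (!is.null(seed)) set.seed(as.integer(seed))
  edge <- which(wound_edge(state))
  if (length(edge) > 0) {
    nbr <- state$lattice$nbr[edge, , drop = FALSE]
    pn <- matrix(0, nrow(nbr), 6)
    valid <- !is.na(nbr)
    src <- nbr[valid]
    contributes <- state$occupied[src] & state$active[src]
    pv <- ifelse(contributes, p[src], 0)
    pn[valid] <- pv
    p_fill <- 1 - apply(1 - pn, 1, prod)
    fill <- stats::runif(length(edge)) < p_fill
    state$occupied[edge[fill]] <- TRUE
  }
  state$time <- state$time + state$params$ca_step
  state$active <- active_layer(state)
  state
}

#' Expected one-step wound-area decrease (edge-fill expectation)
#'
#' Analytic expectation of the area filled by one CA step, used as the
#' Monte-Carlo oracle: sum over wound-edge sites of their fill
#' probability times the site area.
#'
#' @param state a \code{healing_state}.
#' @param p per-site division probabilities.
#' @return expected area decrease (mm^2).
#' @export
expected_fill_area <- function(state, p) {
  edge <- which(wound_edge(state))
  if (length(edge) == 0) return(0)
  nbr <- state$lattice$nbr[edge, , drop = FALSE]
  pn <- matrix(0, nrow(nbr), 6)
  valid <- !is.na(nbr)
  src <- nbr[valid]
  contributes <- state$occupied[src] & state$active[src]
  pn[valid] <- ifelse(contributes, p[src], 0)
  p_fill <- 1 - apply(1 - pn, 1, prod)
  sum(p_fill) * state$lattice$site_area
}

#' Wound area of a healing state
#' @param state a \code{healing_state}.
#' @return area (mm^2): empty-site count times the hexagonal site area.
#' @export
wound_area <- function(state) {
  sum(!state$occupied) * state$lattice$site_area
}

#' Extract the wound boundary polygon from the lattice occupancy
#'
#' Rasterises the empty sites at half the lattice spacing and traces the
#' region boundary; returns \code{NULL} for a closed wound.
#'
#' @param state a \code{healing_state}.
#' @return closed polyline (mm) or \code{NULL}.
#' @export
wound_polygon <- function(state) {
  empty <- which(!state$occupied)
  if (length(empty) == 0) return(NULL)
  pts <- state$lattice$centers[empty, , drop = FALSE]
  h <- state$lattice$h
  pitch <- h / 2
  x0 <- min(pts[, 1]) - h; y0 <- min(pts[, 2]) - h
  nx <- ceiling((max(pts[, 1]) + h - x0) / pitch)
  ny <- ceiling((max(pts[, 2]) + h - y0) / pitch)
  gx <- x0 + (seq_len(nx) - 0.5) * pitch
  gy <- y0 + (seq_len(ny) - 0.5) * pitch
  G <- matrix(FALSE, ny, nx)
  ## mark raster cells within one site radius of an empty site
  rad <- h / sqrt(3)  # hexagon circumradius for area-consistent footprint
  for (k in seq_len(nrow(pts))) {
    cset <- which(abs(gx - pts[k, 1]) <= rad)
    rset <- which(abs(gy - pts[k, 2]) <= rad)
    if (length(cset) && length(rset)) {
      sub <- outer((gy[rset] - pts[k, 2])^2, (gx[cset] - pts[k, 1])^2, "+")
      G[rset, cset] <- G[rset, cset] | (sub <= rad^2)
    }
  }
  loops <- trace_mask_loops(G, pitch, c(x0, y0))
  areas <- vapply(loops, polygon_area, numeric(1))
  poly <- loops[[which.max(abs(areas))]]
  if (polygon_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
  simplify_collinear(poly)
}

#' Level-set style front-propagation reference for wound closure
#'
#' Moves every polygon vertex inward along its normal at the given speed;
#' an independent cross-check for the CA, not part of the model.
#'
#' @param polygon closed wound polygon (mm), counter-clockwise.
#' @param speed inward normal speed (mm/day).
#' @param duration days to propagate.
#' @param dt time step (days).
#' @return final polygon (possibly \code{NULL} when collapsed), plus an
#'   attribute \code{trajectory}: data.frame(time, area).
#' @export
level_set_reference <- function(polygon, speed, duration, dt = 0.25) {
  poly <- polygon
  times <- seq(0, duration, by = dt)
  areas <- numeric(length(times))
  areas[1] <- abs(polygon_area(poly))
  for (k in seq_along(times)[-1]) {
    if (is.null(poly)) { areas[k] <- 0; next }
    nrm <- polyline_normals(poly)
    poly <- poly - nrm * speed * dt
    a <- polygon_area(poly)
    if (!is.finite(a) || a <= 0 || sqrt(a / pi) < speed * dt) {
      poly <- NULL
      areas[k] <- 0
    } else {
      areas[k] <- a
    }
  }
  structure(list(polygon = poly,
                 trajectory = data.frame(time = times, area = areas)))
}

#' Alternate mechanics and healing over a treatment period
#'
#' The weekly coupling loop: solve the loaded mechanics, normalise the
#' stress field, map it onto the unloaded lattice, integrate the growth
#' factor to steady state, run daily CA steps for the coupling interval,
#' then extract the wound boundary and remesh.  When \code{alpha1 = 0}
#' the division probability does not depend on the stress field and the
#' per-interval mechanics solve is skipped (the loaded state is recomputed
#' for the final mesh).
#'
#' @param mesh unloaded \code{breast_mesh} with a cavity.
#' @param materials a [material_params()].
#' @param params a [healing_params()].
#' @param weeks number of weeks to simulate.
#' @param seed master seed; per-interval streams are derived from it.
#' @param spacing lattice spacing (mm); default cavity minor radius / 6.
#' @param load load case applied during healing (default seated gravity).
#' @return a \code{healing_trajectory}: per-interval records of week,
#'   wound area, wound polygon, mesh; plus the final mesh and state.
#' @export
coupling_loop <- function(mesh, materials, params, weeks, seed = 1L,
                          spacing = NULL, load = load_case("seated")) {
  stopifnot(inherits(mesh, "breast_mesh"))
  wound0 <- cavity_wall_contour(mesh)
  if (is.null(wound0)) stop("coupling loop needs an open cavity")
  if (is.null(spacing)) spacing <- 0.7031  # MRI pixel pitch
  state <- init_healing(mesh, spacing, params)
  records <- list()
  cur_mesh <- mesh
  n_int <- ceiling(weeks * 7 / params$coupling_interval)
  for (it in seq_len(n_int)) {
    if (params$alpha1 > 0 && any(!state$occupied)) {
      st <- solve_equilibrium(cur_mesh, materials, load)
      Ehat_el <- normalized_stress(st)
      state$Ehat <- map_stress_to_lattice(cur_mesh, Ehat_el, state)
    }
    if (any(!state$occupied)) {
      state <- solve_growth_factor(state, steady = TRUE)
      ndays <- round(params$coupling_interval / params$ca_step)
      for (d in seq_len(ndays)) {
        p <- division_probability(state$c, state$Ehat, params)
        state <- step_ca(state, p,
                         seed = derive_seed(seed, it * 101L + d))
      }
      poly <- wound_polygon(state)
      if (any(cur_mesh$status == -2L))
        cur_mesh <- remesh_from_wound(cur_mesh, poly)
    }
    records[[it]] <- list(week = it * params$coupling_interval / 7,
                          wound_area = wound_area(state),
                          wound_polygon = wound_polygon(state),
                          mesh = cur_mesh)
  }
  structure(list(records = records, mesh = cur_mesh, state = state,
                 params = params, seed = seed),
            class = "healing_trajectory")
}

## Nearest-element stress lookup for lattice sites (reference coords).
map_stress_to_lattice <- function(mesh, Ehat_el, state) {
  ctr <- (mesh$nodes[mesh$tri[, 1], ] + mesh$nodes[mesh$tri[, 2], ] +
            mesh$nodes[mesh$tri[, 3], ]) / 3
  pts <- state$lattice$centers
  out <- numeric(nrow(pts))
  ## chunked nearest-centroid search
  for (start in seq(1, nrow(pts), by = 512)) {
    idx <- start:min(start + 511, nrow(pts))
    d2 <- outer(pts[idx, 1], ctr[, 1], "-")^2 +
      outer(pts[idx, 2], ctr[, 2], "-")^2
    out[idx] <- Ehat_el[max.col(-d2)]
  }
  out
}
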