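#' Derive Neo-Hookean moduli from Young modulus and Poisson ratio
#'
#' @param E Young modulus (kPa), > 0.
#' @param nu Poisson ratio, in (0, 0.5).
#' @return named vector with shear modulus \code{mu} = E / (2(1+nu)) and
#'   bulk modulus \code{K} = E / (3(1-2nu)), both kPa.
#' @export
derive_moduli <- function(E, nu) {
  stopifnot(all(E > 0))
  if (any(nu >= 0.5) || any(nu <= 0))
    stop("Poisson ratio must lie strictly between 0 and 0.5")
  c(mu = E / (2 * (1 + nu)), K = E / (3 * (1 - 2 * nu)))
}

#' Neo-Hookean strain energy density
#'
#' \eqn{W = \mu/2\,(J^{-2/3} I_1 - 3) + K/2\,(J-1)^2}.
#'
#' @param I1 first invariant of the left Cauchy-Green tensor.
#' @param J determinant of the deformation gradient, > 0.
#' @param mu shear modulus (kPa).
#' @param K bulk modulus (kPa).
#' @return energy density (kPa).
#' @export
strain_energy <- function(I1, J, mu, K) {
  if (any(J <= 0)) stop("J must be positive")
  mu / 2 * (J^(-2 / 3) * I1 - 3) + K / 2 * (J - 1)^2
}

#' Material parameter table for the breast tissues
#'
#' Young moduli are per tissue; Poisson ratio and densities default to the
#' quasi-incompressible soft-tissue values (nu = 0.49; fat 0.9 kg/L, other
#' tissues 1 kg/L).
#'
#' @param E_fat,E_glandular,E_skin,E_scar,E_inflamed Young moduli (kPa).
#' @param nu common Poisson ratio.
#' @param rho named densities (kg/L) per material.
#' @return a \code{material_params} list with per-material E, nu, rho and
#'   derived mu, K.
#' @export
material_params <- function(E_fat = 3.7, E_glandular = 9.5, E_skin = 25,
                            E_scar = 24, E_inflamed = 80, nu = 0.49,
                            rho = c(fat = 0.9, glandular = 1, skin = 1,
                                    scar = 1, inflamed = 1)) {
  E <- c(fat = E_fat, glandular = E_glandular, skin = E_skin,
         scar = E_scar, inflamed = E_inflamed)
  m <- derive_moduli(E, nu)
  structure(list(E = E, nu = nu, rho = rho,
                 mu = stats::setNames(m[seq_along(E)], names(E)),
                 K = stats::setNames(m[length(E) + seq_along(E)], names(E))),
            class = "material_params")
}

#' Scale selected tissue moduli by a common factor
#' @param materials a \code{material_params}.
#' @param lambda multiplicative stiffness factor.
#' @param which material names to scale (default fat and glandular, the
#'   convention used by the phase models; skin keeps its baseline value).
#' @return updated \code{material_params}.
#' @export
scale_materials <- function(materials, lambda,
                            which = c("fat", "glandular", "scar")) {
  E <- materials$E
  E[which] <- E[which] * lambda
  material_params(E_fat = E[["fat"]], E_glandular = E[["glandular"]],
                  E_skin = E[["skin"]], E_scar = E[["scar"]],
                  E_inflamed = E[["inflamed"]], nu = materials$nu,
                  rho = materials$rho)
}

#' Load case: gravity posture and cavity pressure
#'
#' @param posture \code{"seated"} (gravity -y), \code{"prone"} (gravity
#'   +x, anterior), or \code{"none"}.
#' @param gravity gravitational acceleration magnitude (m/s^2).
#' @param pressure seroma pressure on the cavity wall (Pa), >= 0.
#' @return a \code{load_case}.
#' @export
load_case <- function(posture = c("seated", "prone", "none"),
                      gravity = 9.81, pressure = 0) {
  posture <- match.arg(posture)
  stopifnot(pressure >= 0, gravity >= 0)
  g <- switch(posture, seated = c(0, -gravity), prone = c(gravity, 0),
              none = c(0, 0))
  structure(list(posture = posture, g = g, pressure = pressure),
            class = "load_case")
}

## Map element material codes to per-element mu, K (kPa) and body force
## (mN/mm^3): rho [kg/L] * g [m/s^2] * 1e-3.
element_properties <- function(mesh, materials, load, g_scale = 1) {
  nm <- names(MATERIAL_LEVELS)[match(mesh$material, MATERIAL_LEVELS)]
  mu <- materials$mu[nm]
  K <- materials$K[nm]
  rho <- materials$rho[nm]
  bf <- cbind(rho * load$g[1], rho * load$g[2]) * 1e-3 * g_scale
  list(mu = unname(mu), K = unname(K), bodyf = unname(bf))
}

## Assembly pattern over free dofs, cached per mesh geometry.  Returns an
## environment with the slot maps, the free-dof index and a symbolic
## Cholesky factor reused across Newton iterations and grid points.
fe_setup <- function(mesh) {
  nnodes <- nrow(mesh$nodes)
  ndof <- 2L * nnodes
  ## clamped: nodes on chest_wall edges
  cw <- mesh$belem[mesh$belem[, "marker"] == EDGE_MARKERS[["chest_wall"]], ,
                   drop = FALSE]
  clamped_nodes <- unique(as.vector(cw[, c("n1", "n2", "mid")]))
  clamped <- rep(FALSE, ndof)
  clamped[2 * clamped_nodes - 1L] <- TRUE
  clamped[2 * clamped_nodes] <- TRUE
  free <- which(!clamped)
  red <- integer(ndof); red[free] <- seq_along(free)  # 1-based reduced ids

  el_dofs <- function(tr) {
    d <- matrix(0L, nrow(tr), 2L * ncol(tr))
    for (a in seq_len(ncol(tr))) {
      d[, 2 * a - 1L] <- 2L * tr[, a] - 1L
      d[, 2 * a] <- 2L * tr[, a]
    }
    d
  }
  dofs <- el_dofs(mesh$tri)                  # nel x 12
  nel <- nrow(dofs)
  ii <- dofs[, rep(seq_len(12), each = 12)]  # row index per slot
  jj <- dofs[, rep(seq_len(12), times = 12)]
  ri <- red[ii]; rj <- red[jj]
  keep <- ri > 0L & rj > 0L

  pe <- mesh$belem[mesh$belem[, "marker"] == EDGE_MARKERS[["cavity_wall"]], ,
                   drop = FALSE]
  if (nrow(pe) > 0) {
    pedof <- el_dofs(pe[, c("n1", "mid", "n2"), drop = FALSE])  # npe x 6
    pii <- pedof[, rep(seq_len(6), each = 6)]
    pjj <- pedof[, rep(seq_len(6), times = 6)]
    pri <- red[pii]; prj <- red[pjj]
    pkeep <- pri > 0L & prj > 0L
  } else {
    pri <- prj <- integer(0); pkeep <- logical(0)
  }

  nfree <- length(free)
  allkey_i <- c(ri[keep], pri[pkeep])
  allkey_j <- c(rj[keep], prj[pkeep])
  pat <- Matrix::sparseMatrix(i = allkey_i, j = allkey_j,
                              x = 1, dims = c(nfree, nfree))
  pat <- methods::as(pat, "CsparseMatrix")
  ## CSC slot of each (i, j): match on composite keys
  csc_keys <- rep.int(seq_len(nfree), diff(pat@p)) * (nfree + 1) +
    (pat@i + 1)
  ## csc column index expanded; key = col * (nfree+1) + row
  slot_of <- function(i, j) {
    key <- j * (nfree + 1) + i
    match(key, csc_keys) - 1L            # 0-based for C++
  }
  slot_el <- rep(-1L, length(ri))
  slot_el[keep] <- slot_of(ri[keep], rj[keep])
  slot_el <- matrix(slot_el, nrow = nel)           # nel x 144
  slot_el <- as.integer(t(slot_el))                # element-major for C++
  if (nrow(pe) > 0) {
    slot_pe <- rep(-1L, length(pri))
    slot_pe[pkeep] <- slot_of(pri[pkeep], prj[pkeep])
    slot_pe <- as.integer(t(matrix(slot_pe, nrow = nrow(pe))))
    pedges <- pe[, c("n1", "mid", "n2"), drop = FALSE]
  } else {
    slot_pe <- integer(0)
    pedges <- matrix(0L, 0, 3)
  }

  env <- new.env(parent = emptyenv())
  env$free <- free
  env$nfree <- nfree
  env$pattern <- pat
  env$nnz <- length(pat@x)
  env$slot_el <- slot_el
  env$slot_pe <- slot_pe
  env$pedges <- pedges
  env$chol <- NULL
  env
}

## One tangent/residual assembly; returns list(res_free, Kmat or NULL).
fe_assemble <- function(mesh, setup, props, pmag_kpa, u, want_tangent) {
  out <- nh_assemble(mesh$nodes, mesh$tri, u, props$mu, props$K,
                     props$bodyf, setup$pedges, pmag_kpa,
                     setup$slot_el, setup$slot_pe, setup$nnz, want_tangent)
  if (!out$ok) return(NULL)
  Kmat <- NULL
  if (want_tangent) {
    Kmat <- setup$pattern
    Kmat@x <- as.vector(out$xvals)
  }
  list(res = as.vector(out$res)[setup$free], Kmat = Kmat,
       energy = out$energy)
}

## Solve K du = -r with a cached CHOLMOD factorisation.  An indefinite
## tangent (factorisation failure) is reported as NULL: the Newton driver
## treats it as divergence and cuts the load step, rather than grinding
## on with modified directions.
fe_linear_solve <- function(setup, Kmat, r) {
  sym <- Matrix::forceSymmetric(Kmat, uplo = "L")
  f <- tryCatch({
    if (is.null(setup$chol)) {
      setup$chol <- Matrix::Cholesky(sym, LDL = FALSE, perm = TRUE)
    } else {
      setup$chol <- Matrix::update(setup$chol, sym)
    }
    setup$chol
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(f)) return(NULL)
  as.vector(Matrix::solve(f, -r))
}

#' Solve the quasi-static equilibrium of the breast under a load case
#'
#' Total-Lagrangian plane-strain Neo-Hookean finite elements on quadratic
#' triangles; gravity enters as a body force per reference density and the
#' seroma pressure as a follower traction on the cavity wall.  Newton
#' iteration with backtracking line search and adaptive load stepping;
#' chest-wall nodes are clamped.
#'
#' @param mesh a \code{breast_mesh}.
#' @param materials a [material_params()].
#' @param load a [load_case()].
#' @param tol relative residual tolerance.
#' @param max_newton Newton iteration cap per load step.
#' @param u0 optional initial displacement guess (warm start).
#' @param setup optional cached [fe_setup()] environment for this mesh.
#' @return a \code{mechanical_state}: displacements \code{u} (2 per node,
#'   mm), deformed coordinates, per-element \code{J}, \code{I1}, strain
#'   energy density \code{W} (kPa), convergence diagnostics, and the
#'   applied load.
#' @export
solve_equilibrium <- function(mesh, materials, load, tol = 1e-8,
                              max_newton = 30L, u0 = NULL, setup = NULL) {
  if (is.null(setup)) setup <- fe_setup(mesh)
  ndof <- 2L * nrow(mesh$nodes)
  if (!is.null(u0) && length(u0) != ndof) u0 <- NULL  # mesh changed
  u <- if (is.null(u0)) numeric(ndof) else u0
  u[-setup$free] <- 0
  pmag_full <- load$pressure * 1e-3  # Pa -> kPa

  ref_props <- element_properties(mesh, materials, load)
  fext_norm <- {
    pr <- element_properties(mesh, materials, load)
    z <- nh_assemble(mesh$nodes, mesh$tri, numeric(ndof),
                     pr$mu * 0 + 1e-12, pr$K * 0 + 1e-12, pr$bodyf,
                     setup$pedges, pmag_full, setup$slot_el, setup$slot_pe,
                     setup$nnz, FALSE)
    max(sqrt(sum(as.vector(z$res)[setup$free]^2)), 1e-10)
  }

  ## Full Newton steps (the residual may spike once before quadratic
  ## convergence sets in); backtrack only when a step inverts elements,
  ## and leave global robustness to the load stepping.
  newton_at <- function(u, s) {
    props <- element_properties(mesh, materials, load, g_scale = s)
    pm <- pmag_full * s
    target <- tol * max(fext_norm * s, 1e-10)
    u_prev <- u; du <- NULL; alpha <- 1
    for (it in seq_len(max_newton)) {
      asm <- fe_assemble(mesh, setup, props, pm, u, TRUE)
      if (is.null(asm)) {
        ## invalid state (J <= 0): backtrack along the last step
        if (is.null(du)) return(NULL)
        alpha <- alpha / 2
        if (alpha < 1e-3) return(NULL)
        u <- u_prev
        u[setup$free] <- u_prev[setup$free] + alpha * du
        next
      }
      rn <- sqrt(sum(asm$res^2))
      if (rn < target) return(list(u = u, iters = it - 1L, resid = rn))
      if (!is.finite(rn) || rn > 1e8 * max(target, 1)) return(NULL)
      du <- fe_linear_solve(setup, asm$Kmat, asm$res)
      if (is.null(du)) return(NULL)
      alpha <- 1
      u_prev <- u
      u[setup$free] <- u[setup$free] + du
    }
    NULL
  }

  ## with a warm start, try the full load directly; otherwise (or when
  ## the warm attempt diverges) ramp the load from zero, halving the
  ## increment on failure
  total_iters <- 0L; resid <- NA_real_
  sol <- if (!is.null(u0)) newton_at(u, 1) else NULL
  if (!is.null(sol)) {
    u <- sol$u; total_iters <- sol$iters; resid <- sol$resid
  } else {
    u <- numeric(ndof)
    s_done <- 0; s_step <- 0.25; nsplits <- 0L
    while (s_done < 1 - 1e-12) {
      s_try <- min(1, s_done + s_step)
      sol <- newton_at(u, s_try)
      if (is.null(sol)) {
        s_step <- s_step / 2
        nsplits <- nsplits + 1L
        if (nsplits > 12L)
          stop("Newton solver failed to converge; last residual ",
               format(resid))
        next
      }
      u <- sol$u
      total_iters <- total_iters + sol$iters
      resid <- sol$resid
      s_done <- s_try
      s_step <- min(s_step * 2, 1)
    }
  }

  fields <- nh_fields(mesh$nodes, mesh$tri, u, ref_props$mu, ref_props$K)
  structure(list(u = u,
                 deformed = mesh$nodes + matrix(u, ncol = 2, byrow = TRUE),
                 W = fields[, 1], J = fields[, 2], I1 = fields[, 3],
                 area_ref = fields[, 4],
                 resid = resid, newton_iters = total_iters,
                 load = load, mesh = mesh),
            class = "mechanical_state")
}

#' Normalised per-element stress field
#'
#' Strain-energy density per element divided by its maximum, the scalar
#' that modulates the mechano-sensitive term of the division probability.
#'
#' @param state a \code{mechanical_state}.
#' @return numeric vector in [0, 1] (all zero for an unloaded state).
#' @export
normalized_stress <- function(state) {
  stopifnot(inherits(state, "mechanical_state"))
  mx <- max(state$W)
  if (mx <= 0) return(rep(0, length(state$W)))
  state$W / mx
}

#' Estimate the unloaded (stress-free) configuration
#'
#' Fixed-point inverse iteration: starting from the observed geometry, the
#' reference coordinates are corrected by the forward-model mismatch
#' until loading the estimate reproduces the observation.
#'
#' @param mesh_observed mesh of the observed (loaded) geometry.
#' @param materials a [material_params()].
#' @param observed_load the load under which the geometry was observed.
#' @param tol maximum nodal error (mm) on the reproduced geometry.
#' @param max_cycles fixed-point iteration cap.
#' @param relax relaxation factor on the correction.
#' @return list with the unloaded \code{mesh}, the displacement of its
#'   final forward solve, cycles used and the final max nodal error.
#' @export
estimate_unloaded <- function(mesh_observed, materials, observed_load,
                              tol = 0.05, max_cycles = 30L, relax = 1) {
  x_obs <- mesh_observed$nodes
  mesh <- mesh_observed
  setup <- fe_setup(mesh)
  u_warm <- NULL
  err <- Inf
  for (cy in seq_len(max_cycles)) {
    st <- solve_equilibrium(mesh, materials, observed_load, u0 = u_warm,
                            setup = setup)
    mism <- st$deformed - x_obs
    err <- max(sqrt(rowSums(mism^2)))
    if (err < tol)
      return(list(mesh = mesh, state = st, cycles = cy, error = err))
    mesh$nodes <- mesh$nodes - relax * mism
    u_warm <- st$u
  }
  stop("unloaded-state iteration did not contract below ", tol,
       " mm in ", max_cycles, " cycles (last error ", format(err), ")")
}
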