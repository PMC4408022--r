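## Shared fixtures, all built in code.

## A rectangular all-fat label map, optionally with a chest band on the
## left so meshes built from it have clamped boundary.
block_map <- function(nx = 20, ny = 20, pitch = 1, chest_cols = 0L,
                      label = 1L) {
  labs <- matrix(label, ny, nx)
  if (chest_cols > 0L) labs[, seq_len(chest_cols)] <- 4L
  structure(list(labels = labs, pixel_pitch = pitch, origin = c(0, 0),
                 spec = NULL), class = "tissue_label_map")
}

## Cantilever: fat block of len x thick mm clamped at the left (2 mm
## chest band), meshed at element size `target`.
cantilever_mesh <- function(len = 20, thick = 6, pitch = 1, target = pitch) {
  nx <- round((len + 2) / pitch); ny <- round(thick / pitch)
  build_mesh(block_map(nx, ny, pitch, chest_cols = as.integer(round(2 / pitch))),
             target)
}

## Memoised default phantom study (shared by the slower tests).
the <- new.env(parent = emptyenv())
default_study <- function() {
  if (is.null(the$study)) the$study <- study_setup(target_size = 3)
  the$study
}
default_map <- function() default_study()$map

## Hexagonal healing state over an explicit circular wound, without a
## mesh (far-field rim is the Dirichlet boundary).
circle_state <- function(radius = 6, spacing = 0.5, pad = 6,
                         params = healing_params()) {
  th <- seq(0, 2 * pi, length.out = 181)[-1]
  poly <- cbind(radius * cos(th), radius * sin(th))
  bctshape:::new_healing_state(poly, spacing, params, pad)
}

## Hexagonal void of k rings of empty sites (graph distances 0..k-1 from
## the centre site), so closure at p = 1 takes exactly one step per ring.
ring_void_state <- function(k = 3, spacing = 1, params = healing_params()) {
  st <- circle_state(radius = (k + 1) * spacing, spacing = spacing,
                     pad = 4 * spacing, params = params)
  nbr <- st$lattice$nbr
  ctr <- which.min(rowSums(st$lattice$centers^2))
  dist <- rep(NA_integer_, nrow(nbr)); dist[ctr] <- 0L
  frontier <- ctr
  for (d in seq_len(k - 1L)) {
    nxt <- unique(stats::na.omit(as.vector(nbr[frontier, , drop = FALSE])))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  st$occupied <- is.na(dist)
  st$c <- rep(0, length(st$occupied))
  st$active <- bctshape:::active_layer(st)
  st
}

## Linear plane-strain elasticity on the same P2 mesh: an independent
## small-strain oracle assembled directly in R from the B-matrix form.
linear_elastic_solve <- function(mesh, materials, load) {
  nm <- names(bctshape:::MATERIAL_LEVELS)[match(mesh$material,
                                                bctshape:::MATERIAL_LEVELS)]
  E <- materials$E[nm]; nu <- materials$nu
  rho <- materials$rho[nm]
  nn <- nrow(mesh$nodes)
  qp <- rbind(c(1/6, 1/6), c(2/3, 1/6), c(1/6, 2/3)); qw <- 1/6
  dshape <- function(xi, eta) {
    l1 <- 1 - xi - eta
    rbind(c(-(4*l1-1), -(4*l1-1)), c(4*xi-1, 0), c(0, 4*eta-1),
          c(4*(l1-xi), -4*xi), c(4*eta, 4*xi), c(-4*eta, 4*(l1-eta)))
  }
  ii <- jj <- xx <- list(); fvec <- numeric(2 * nn)
  shape <- function(xi, eta) {
    l1 <- 1 - xi - eta
    c(l1*(2*l1-1), xi*(2*xi-1), eta*(2*eta-1), 4*l1*xi, 4*xi*eta, 4*eta*l1)
  }
  for (e in seq_len(nrow(mesh$tri))) {
    idx <- mesh$tri[e, ]
    X <- mesh$nodes[idx, ]
    lam <- E[e] * nu / ((1 + nu) * (1 - 2 * nu))
    muE <- E[e] / (2 * (1 + nu))
    D <- matrix(c(lam + 2*muE, lam, 0, lam, lam + 2*muE, 0, 0, 0, muE), 3, 3)
    dofs <- as.vector(rbind(2 * idx - 1, 2 * idx))
    Ke <- matrix(0, 12, 12); fe <- numeric(12)
    for (q in 1:3) {
      dN <- dshape(qp[q, 1], qp[q, 2])
      Jm <- t(X) %*% dN
      detJ <- det(Jm)
      dNX <- dN %*% solve(Jm)
      B <- matrix(0, 3, 12)
      B[1, seq(1, 12, 2)] <- dNX[, 1]
      B[2, seq(2, 12, 2)] <- dNX[, 2]
      B[3, seq(1, 12, 2)] <- dNX[, 2]
      B[3, seq(2, 12, 2)] <- dNX[, 1]
      Ke <- Ke + t(B) %*% D %*% B * qw * detJ
      N <- shape(qp[q, 1], qp[q, 2])
      bf <- rho[e] * load$g * 1e-3
      fe[seq(1, 12, 2)] <- fe[seq(1, 12, 2)] + N * bf[1] * qw * detJ
      fe[seq(2, 12, 2)] <- fe[seq(2, 12, 2)] + N * bf[2] * qw * detJ
    }
    ii[[e]] <- rep(dofs, each = 12); jj[[e]] <- rep(dofs, times = 12)
    xx[[e]] <- as.vector(t(Ke))
    fvec[dofs] <- fvec[dofs] + fe
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(2 * nn, 2 * nn))
  cw <- mesh$belem[mesh$belem[, "marker"] == 2L, , drop = FALSE]
  clamped <- unique(as.vector(cw[, c("n1", "n2", "mid")]))
  free <- setdiff(seq_len(2 * nn), c(2 * clamped - 1, 2 * clamped))
  u <- numeric(2 * nn)
  u[free] <- as.vector(Matrix::solve(K[free, free], fvec[free]))
  u
}
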