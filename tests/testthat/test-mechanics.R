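test_that("moduli derivation follows the isotropic elasticity relations", {
  m <- derive_moduli(3.7, 0.49)
  expect_equal(unname(m["mu"]), 3.7 / (2 * 1.49), tolerance = 1e-12)
  expect_equal(unname(m["K"]), 3.7 / (3 * 0.02), tolerance = 1e-12)
  expect_equal(unname(m["mu"]), 1.2416, tolerance = 1e-4)
  expect_equal(unname(m["K"]), 61.67, tolerance = 1e-3)
  m2 <- derive_moduli(1, 1e-12)
  expect_equal(unname(m2["mu"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(m2["K"]), 1 / 3, tolerance = 1e-9)
  expect_equal(unname(derive_moduli(80, 0.49)["mu"]), 26.85, tolerance = 1e-3)
  expect_error(derive_moduli(1, 0.5), "Poisson")
})

test_that("the strain energy density matches its closed form", {
  expect_identical(strain_energy(3, 1, 1, 10), 0)
  ## isochoric plane stretch diag(1.1, 1/1.1, 1): J = 1
  I1 <- 1.1^2 + 1.1^-2 + 1
  expect_equal(strain_energy(I1, 1, 1, 100), (I1 - 3) / 2, tolerance = 1e-12)
  expect_equal(strain_energy(I1, 1, 1, 100), 0.01822314, tolerance = 1e-6)
  ## pure dilation with mu = 0: only the volumetric term remains
  expect_equal(strain_energy(3 * 1.01^(2 / 3), 1.01, 0, 2), 1e-4,
               tolerance = 1e-9)
  expect_error(strain_energy(3, 0, 1, 1), "positive")
})

test_that("assembled tangent matches finite differences of the residual", {
  mesh <- build_mesh(block_map(4, 4, 1), 1)
  setup <- bctshape:::fe_setup(mesh)
  mats <- material_params()
  props <- bctshape:::element_properties(mesh, mats, load_case("seated"))
  set.seed(1)
  u <- rnorm(2 * nrow(mesh$nodes), 0, 0.05)
  asm <- bctshape:::fe_assemble(mesh, setup, props, 0, u, TRUE)
  K <- as.matrix(asm$Kmat)
  eps <- 1e-6
  for (j in sample(setup$nfree, 12)) {
    up <- u; up[setup$free[j]] <- up[setup$free[j]] + eps
    um <- u; um[setup$free[j]] <- um[setup$free[j]] - eps
    col_fd <- (bctshape:::fe_assemble(mesh, setup, props, 0, up, FALSE)$res -
                 bctshape:::fe_assemble(mesh, setup, props, 0, um, FALSE)$res) /
      (2 * eps)
    expect_lt(max(abs(K[, j] - col_fd)), 1e-5 * max(1, max(abs(K[, j]))))
  }
})

test_that("zero load gives the trivial equilibrium", {
  mesh <- cantilever_mesh()
  st <- solve_equilibrium(mesh, material_params(), load_case("none"))
  expect_lt(max(abs(st$u)), 1e-10)
  expect_equal(normalized_stress(st), rep(0, nrow(mesh$tri)))
})

test_that("small loads reproduce the linear-elastic oracle", {
  mesh <- cantilever_mesh(len = 16, thick = 6)
  mats <- material_params(E_fat = 5, nu = 0.3)
  tiny <- load_case("seated", gravity = 9.81e-3)
  st <- solve_equilibrium(mesh, mats, tiny)
  u_lin <- linear_elastic_solve(mesh, mats, tiny)
  scale <- max(abs(u_lin))
  expect_lt(max(abs(st$u - u_lin)) / scale, 0.01)
})

test_that("rigid rotation carries zero strain energy", {
  mesh <- build_mesh(block_map(6, 6, 1), 1)
  th <- 0.4
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  xy <- mesh$nodes %*% t(R)
  u <- as.vector(t(xy - mesh$nodes))
  mats <- material_params()
  props <- bctshape:::element_properties(mesh, mats, load_case("none"))
  f <- bctshape:::nh_fields(mesh$nodes, mesh$tri, u, props$mu, props$K)
  expect_lt(max(abs(f[, 1])), 1e-12)             # W
  expect_lt(max(abs(f[, 2] - 1)), 1e-10)         # J
})

test_that("a stressed cantilever concentrates energy at the clamp", {
  mesh <- cantilever_mesh(len = 20, thick = 4)
  st <- solve_equilibrium(mesh, material_params(E_fat = 5),
                          load_case("seated"))
  Eh <- normalized_stress(st)
  expect_equal(max(Eh), 1)
  ctr <- (mesh$nodes[mesh$tri[, 1], 1] + mesh$nodes[mesh$tri[, 2], 1] +
            mesh$nodes[mesh$tri[, 3], 1]) / 3
  expect_lt(ctr[which.max(Eh)], quantile(ctr, 0.25))
})

test_that("stiffening every tissue reduces the gravity sag monotonically", {
  study <- default_study()
  mesh <- study$mesh0
  drop_for <- function(lambda) {
    mats <- material_params(E_fat = 3.7 * lambda, E_glandular = 9.5 * lambda,
                            E_skin = 25 * lambda)
    st <- solve_equilibrium(mesh, mats, load_case("seated"))
    nip0 <- nipple_landmark(mesh_skin_contour(mesh))
    ## track the same material point: the reference nipple node
    i <- which.max(mesh$nodes[, 1])
    -st$u[2 * i]
  }
  drops <- vapply(c(1, 1.5, 2.5), drop_for, numeric(1))
  expect_true(all(diff(drops) < 0))
  expect_gt(drops[1], 0)
})

test_that("seroma pressure inflates the cavity", {
  study <- default_study()
  mats <- material_params()
  mesh <- study$mesh_cav
  s0 <- solve_equilibrium(mesh, mats, load_case("none", pressure = 0))
  sP <- solve_equilibrium(mesh, mats, load_case("none", pressure = 200))
  a0 <- abs(polygon_area(cavity_wall_contour(mesh, s0$u)))
  aP <- abs(polygon_area(cavity_wall_contour(mesh, sP$u)))
  expect_gt(aP, a0 * 1.05)
})

test_that("the unloaded-state estimate matches a linear sign-flip check", {
  mesh <- cantilever_mesh(len = 12, thick = 5)
  mats <- material_params(E_fat = 5, nu = 0.3)
  tiny <- load_case("seated", gravity = 9.81e-3)
  ## observed = loaded configuration of the block
  st <- solve_equilibrium(mesh, mats, tiny)
  obs <- mesh
  obs$nodes <- st$deformed
  est <- estimate_unloaded(obs, mats, tiny, tol = 1e-4)
  expect_lt(max(abs(est$mesh$nodes - mesh$nodes)), 1e-3)
  ## in the linear regime the inverse equals loading with flipped gravity
  flip <- structure(list(posture = "custom", g = c(0, 9.81e-3),
                         pressure = 0), class = "load_case")
  u_flip <- linear_elastic_solve(obs, mats, flip)
  est_lin <- obs$nodes + matrix(u_flip, ncol = 2, byrow = TRUE)
  expect_lt(max(abs(est_lin - mesh$nodes)) / max(abs(st$u)), 0.02)
})
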