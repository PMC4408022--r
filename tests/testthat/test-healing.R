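test_that("healing initialisation lays out wound, tissue and active layer", {
  r <- 6; h <- 0.5
  st <- circle_state(radius = r, spacing = h)
  a_site <- st$lattice$site_area
  n_empty <- sum(!st$occupied)
  expect_lt(abs(n_empty * a_site - pi * r^2) / (pi * r^2), 0.10)

  w <- st$params$active_width
  n_active <- sum(st$active)
  expected <- 2 * pi * r * w / a_site
  expect_lt(abs(n_active - expected) / expected, 0.20)

  ## every wound-edge site is empty and touches an occupied site
  edge <- wound_edge(st)
  expect_true(all(!st$occupied[edge]))
  expect_true(all(st$occupied[st$active]))  # active layer is tissue

  ## spacing coarser than a quarter of the minor radius is refused
  expect_error(bctshape:::new_healing_state(
    cbind(c(-3, 3, 3, -3), c(-3, -3, 3, 3)), 2, healing_params(), 5),
    "spacing")
})

test_that("growth-factor solver reproduces closed-form balances", {
  ## uniform source, decay 1/day, no flux anywhere -> steady c = chi/Lambda
  st <- circle_state(radius = 4, spacing = 0.5,
                     params = healing_params(Lambda = 1))
  st$active <- st$occupied          # source everywhere
  st$dirichlet[] <- FALSE           # no far-field sink
  st <- solve_growth_factor(st, steady = TRUE)
  expect_lt(max(abs(st$c[st$occupied] - 1)), 1e-6)

  ## no decay, no flux: uniform growth c = t exactly
  st2 <- circle_state(radius = 4, spacing = 0.5,
                      params = healing_params(Lambda = 0))
  st2$active <- st2$occupied
  st2$dirichlet[] <- FALSE
  st2 <- solve_growth_factor(st2, duration = 5, dt = 1)
  expect_lt(max(abs(st2$c[st2$occupied] - 5)), 1e-9)
})

test_that("the 1D source-free tail decays as the analytic boundary layer", {
  h <- 0.02
  lat <- chain_lattice(20, h)
  n <- nrow(lat$centers)
  D_mm <- 0.4; Lambda <- 0.1       # decay length sqrt(D/Lambda) = 2 mm
  st <- structure(list(
    lattice = lat, occupied = rep(TRUE, n), c = rep(0, n),
    active = lat$centers[, 1] < 2, dirichlet = rep(FALSE, n),
    params = healing_params(D = D_mm / 100, Lambda = Lambda),
    time = 0, mesh = NULL, Ehat = rep(0, n)), class = "healing_state")
  st$dirichlet[n] <- TRUE          # far-field sink
  st <- solve_growth_factor(st, steady = TRUE, dt = 10)
  x <- lat$centers[, 1]; cc <- st$c
  ell <- sqrt(D_mm / Lambda)
  sel <- x > 4 & x < 12            # source-free tail, away from both ends
  x0 <- x[sel][1]; c0 <- cc[sel][1]
  ratio <- cc[sel] / c0
  ref <- exp(-(x[sel] - x0) / ell)
  expect_lt(max(abs(ratio - ref) / ref), 1e-3)
})

test_that("division probability applies the concentration gate", {
  p <- healing_params(alpha0 = 0.17, alpha1 = 0, c_threshold = 0.5)
  expect_equal(division_probability(c(0.1, 0.4), c(0, 1), p), c(0, 0))
  expect_equal(division_probability(c(0.6, 2), c(0, 1), p), c(0.17, 0.17))
  p2 <- healing_params(alpha0 = 0.1, alpha1 = 0.2, c_threshold = 0.5)
  expect_equal(division_probability(1, 1, p2), 0.3)
  p3 <- healing_params(alpha0 = 0.6, alpha1 = 0.9, c_threshold = 0.5)
  expect_equal(division_probability(1, 1, p3), 1)  # clamped
})

test_that("the CA step fills edges reproducibly and never reopens wound", {
  st <- ring_void_state(k = 4, spacing = 1)
  n <- length(st$occupied)
  ## p = 0: nothing happens
  st0 <- step_ca(st, rep(0, n), seed = 1)
  expect_identical(st0$occupied, st$occupied)

  ## p = 1: one full ring per step, closed in <= k steps
  stk <- st
  for (s in 1:4) {
    before <- sum(!stk$occupied)
    stk <- step_ca(stk, rep(1, n), seed = s)
    expect_lt(sum(!stk$occupied), max(before, 1))
  }
  expect_identical(sum(!stk$occupied), 0L)

  ## determinism and monotone wound area at intermediate p
  a <- step_ca(st, rep(0.3, n), seed = 42)
  b <- step_ca(st, rep(0.3, n), seed = 42)
  expect_identical(a$occupied, b$occupied)
  expect_lte(wound_area(a), wound_area(st))
})

test_that("mean CA closure matches the edge-fill expectation", {
  st <- circle_state(radius = 5, spacing = 0.5)
  n <- length(st$occupied)
  p <- rep(0.17, n)
  expected <- expected_fill_area(st, p)
  dec <- vapply(1:200, function(s)
    wound_area(st) - wound_area(step_ca(st, p, seed = s)), numeric(1))
  expect_lt(abs(mean(dec) - expected) / expected, 0.10)
})

test_that("level-set reference shrinks a circle at the exact rate", {
  th <- seq(0, 2 * pi, length.out = 241)[-1]
  poly <- cbind(10 * cos(th), 10 * sin(th))
  out0 <- level_set_reference(poly, speed = 0, duration = 5)
  expect_equal(out0$polygon, poly, tolerance = 1e-12)
  out <- level_set_reference(poly, speed = 0.5, duration = 8, dt = 0.1)
  r_end <- sqrt(abs(polygon_area(out$polygon)) / pi)
  expect_lt(abs(r_end - (10 - 0.5 * 8)), 0.02)
  ## collapse is reported as an empty wound
  gone <- level_set_reference(poly, speed = 2, duration = 10, dt = 0.1)
  expect_null(gone$polygon)
  expect_identical(utils::tail(gone$trajectory$area, 1), 0)
})

test_that("CA and level-set area trajectories agree on a circular wound", {
  st <- circle_state(radius = 6, spacing = 0.5)
  n <- length(st$occupied)
  pval <- 0.5
  p <- rep(pval, n)
  v <- expected_fill_area(st, p) /
    (2 * pi * sqrt(wound_area(st) / pi))     # speed from the expectation
  th <- seq(0, 2 * pi, length.out = 241)[-1]
  r0 <- sqrt(wound_area(st) / pi)
  poly <- cbind(r0 * cos(th), r0 * sin(th))
  ca_areas <- c(); ls_areas <- c()
  stk <- st
  lsp <- poly
  for (s in 1:8) {
    stk <- step_ca(stk, p, seed = 100 + s)
    out <- level_set_reference(lsp, speed = v, duration = 1, dt = 0.25)
    lsp <- out$polygon
    ca_areas <- c(ca_areas, wound_area(stk))
    ls_areas <- c(ls_areas, if (is.null(lsp)) 0 else abs(polygon_area(lsp)))
    if (is.null(lsp) || ca_areas[length(ca_areas)] == 0) break
  }
  rel <- abs(ca_areas - ls_areas) / wound_area(st)
  expect_lt(max(rel), 0.15)
})

test_that("the coupling loop is conservative without division and seeded", {
  study <- default_study()
  mats <- material_params()
  hp0 <- healing_params(alpha0 = 0, alpha1 = 0)
  tr0 <- coupling_loop(study$mesh_cav, mats, hp0, weeks = 3, seed = 1)
  areas <- vapply(tr0$records, `[[`, numeric(1), "wound_area")
  expect_equal(diff(areas), rep(0, length(areas) - 1))

  hp <- healing_params(alpha0 = 0.17)
  t1 <- coupling_loop(study$mesh_cav, mats, hp, weeks = 3, seed = 9)
  t2 <- coupling_loop(study$mesh_cav, mats, hp, weeks = 3, seed = 9)
  a1 <- vapply(t1$records, `[[`, numeric(1), "wound_area")
  a2 <- vapply(t2$records, `[[`, numeric(1), "wound_area")
  expect_identical(a1, a2)
  expect_identical(t1$state$occupied, t2$state$occupied)
  expect_true(all(diff(a1) <= 0))
  expect_lt(a1[length(a1)], a1[1])
})
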