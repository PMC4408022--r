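test_that("rasterisation marks the cells a contour crosses", {
  roi <- list(origin = c(0, 0), size = 20)
  seg <- cbind(c(2, 14.5), c(5, 5))       # horizontal, length 12.5
  r <- rasterize_contour(seg, roi, resolution = 1)
  ## the closing edge retraces the segment, so the crossed cells are the
  ## ceiling of the length plus at most one boundary cell
  expect_gte(sum(r$grid), ceiling(12.5 / 1) - 1)
  expect_lte(sum(r$grid), ceiling(12.5 / 1) + 1)

  expect_error(rasterize_contour(cbind(numeric(0), numeric(0)), roi, 1),
               "empty")
  expect_error(rasterize_contour(cbind(50, 50), roi, 1), "empty|ROI")

  ## halving the cell size roughly doubles the crossed-cell count
  sq <- cbind(c(2, 12, 12, 2), c(2, 2, 12, 12))
  n1 <- sum(rasterize_contour(sq, roi, 1)$grid)
  n2 <- sum(rasterize_contour(sq, roi, 0.5)$grid)
  expect_gt(n2 / n1, 1.8); expect_lt(n2 / n1, 2.2)
})

test_that("the contour objective counts mismatched cells", {
  sq <- cbind(c(10, 30, 30, 10), c(10, 10, 30, 30))
  expect_identical(objective_f(sq, sq, s = 1, resolution = 1), 0L)
  ## vertex relabelling leaves f unchanged
  sq_rot <- sq[c(3, 4, 1, 2), ]
  expect_identical(objective_f(sq, sq_rot, s = 1, resolution = 1), 0L)

  ## s absorbs a common scale about the centroid
  half <- bctshape:::scale_contour(sq, 0.5)
  expect_identical(objective_f(sq, half, s = 2, resolution = 1), 0L)
  expect_gt(objective_f(sq, half, s = 1, resolution = 1), 0)

  ## a one-cell shift mismatches two opposite edge bands: brute-force
  ## count on the axis-aligned square is 2 sides x (side + 1) cells x 2
  shifted <- sq + cbind(rep(1, 4), rep(0, 4))
  roi <- list(origin = c(0, 0), size = 40)
  g1 <- rasterize_contour(sq, roi, 1)$grid
  g2 <- rasterize_contour(shifted, roi, 1)$grid
  brute <- sum(g1 != g2)
  expect_identical(objective_f(sq, shifted, s = 1, roi = roi,
                               resolution = 1), brute)

  ## rigid common translation of both contours leaves f unchanged
  t_vec <- c(3.2, -2.7)
  f0 <- objective_f(sq, half, s = 1.3, resolution = 1)
  f1 <- objective_f(sweep(sq, 2, t_vec, "+"),
                    sweep(half, 2, t_vec, "+"), s = 1.3, resolution = 1)
  expect_identical(f0, f1)
})

test_that("phase forward models honour their parameter identities", {
  study <- default_study()
  ## rigid limit: scaling all moduli far up freezes the contour at the
  ## unloaded shape
  stiff <- simulate_phase(study, "0", c(3.7, 9.5, 25) * 100)
  ref <- mesh_skin_contour(study$mesh0)
  expect_lt(max(sqrt(rowSums((stiff - ref)^2))), 0.5)

  ## phase I at lambda1 = 1, P = 0 minus the inflamed ring equals the
  ## baseline solve on the cavity mesh
  mats <- material_params()
  st <- solve_equilibrium(study$mesh_cav, mats, load_case("seated"))
  plain <- mesh_skin_contour(study$mesh_cav, st$u)
  study2 <- study
  study2$inflamed_width <- 0     # no inflamed ring
  p1 <- simulate_phase(study2, "I", c(1, 0))
  expect_lt(max(abs(p1 - plain)), 1e-6)

  ## phase I at the fitted regime: bulge and nipple elevation vs baseline
  p0 <- simulate_phase(study, "0", c(3.7, 9.5, 25))
  pI <- simulate_phase(study, "I", c(2.0, 120))
  expect_gt(nipple_landmark(pI)[2], nipple_landmark(p0)[2])
})

test_that("grid search recovers an off-grid truth within one cell", {
  study <- default_study()
  truth <- c(2.11, 130)           # off the lambda1/P grid
  obs <- generate_observation(study, "I", truth, seed = 21)
  grid <- list(lambda1 = seq(1.6, 2.6, by = 0.2), P = seq(40, 240, by = 50))
  fit <- fit_phase(study, "I", obs, grid)
  expect_lte(abs(fit$argmin[["lambda1"]] - truth[1]), 0.2)
  expect_lte(abs(fit$argmin[["P"]] - truth[2]), 50)
  ## the surface attains its minimum at the argmin
  expect_identical(min(fit$surface), fit$f_min)
})

test_that("study orchestration validates its configuration", {
  study <- default_study()
  des <- default_study_design()
  expect_error(run_full_study(study, des$truths[c("I", "0", "II", "III")],
                              des$grids),
               "order")
})
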