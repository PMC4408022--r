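test_that("meshing a unit square reproduces its area and quality bounds", {
  map <- block_map(10, 10, pitch = 0.1)
  mesh <- build_mesh(map, 0.1)
  expect_equal(mesh_area(mesh), 1, tolerance = 1e-6)
  expect_true(all(bctshape:::element_areas(mesh$nodes, mesh$tri) > 0))
  expect_gte(mesh_min_angle(mesh), 20)
})

test_that("phantom meshes conserve area and material composition", {
  map <- default_map()
  ## at the native pixel pitch the cells are the pixels
  mesh <- build_mesh(map, map$pixel_pitch)
  fg_area <- sum(map$labels %in% c(1L, 2L, 3L)) * map$pixel_pitch^2
  expect_lt(abs(mesh_area(mesh) - fg_area) / fg_area, 0.01)
  for (cls in c(fat = 1L, glandular = 2L, skin = 3L)) {
    a_mesh <- sum(bctshape:::element_areas(mesh$nodes, mesh$tri)[
      mesh$material == cls])
    a_map <- sum(map$labels == cls) * map$pixel_pitch^2
    expect_lt(abs(a_mesh - a_map) / fg_area, 0.05)
  }
  ## deterministic rebuild
  mesh2 <- build_mesh(map, map$pixel_pitch)
  expect_identical(mesh$nodes, mesh2$nodes)
  expect_identical(mesh$tri, mesh2$tri)
  expect_identical(mesh$material, mesh2$material)
})

test_that("virtual lumpectomy removes the effective ellipse", {
  study <- default_study()
  mesh <- study$mesh0
  ctr <- study$spec$tumor_center
  cav0 <- cavity_spec(ctr, bed_axes = c(12, 9), margin = 0,
                      orientation = pi / 2)
  ## margin 0 at the coarse mesh needs finer cells to resolve; use a
  ## fine mesh for the bed-only case
  fine <- build_mesh(study$map, 1)
  m0 <- apply_virtual_lumpectomy(fine, cav0)
  expect_lt(abs(cavity_area(m0) - pi * 6 * 4.5) / (pi * 6 * 4.5), 0.03)

  cav5 <- cavity_spec(ctr, bed_axes = c(12, 9), margin = 5,
                      orientation = pi / 2)
  m5 <- apply_virtual_lumpectomy(mesh, cav5)
  expect_lt(abs(cavity_area(m5) - pi * 11 * 9.5) / (pi * 11 * 9.5), 0.03)
  ## cavity wall forms a closed loop
  wall <- cavity_wall_contour(m5)
  expect_gt(nrow(wall), 8)

  huge <- cavity_spec(ctr, bed_axes = c(12, 9), margin = 60)
  expect_error(apply_virtual_lumpectomy(mesh, huge), "skin|chest")
})

test_that("remeshing after healing keeps the area bookkeeping consistent", {
  study <- default_study()
  mesh <- study$mesh_cav
  total0 <- mesh_area(mesh) + cavity_area(mesh)

  ## no-op: rewound with the current cavity wall
  m_same <- remesh_from_wound(mesh, cavity_wall_contour(mesh))
  expect_lt(abs(cavity_area(m_same) - cavity_area(mesh)) / cavity_area(mesh),
            0.01)
  expect_lt(abs(mesh_area(m_same) + cavity_area(m_same) - total0) / total0,
            0.01)

  ## shrink the wound to half area (scale the wall by sqrt(0.5))
  wall <- cavity_wall_contour(mesh)
  c0 <- polygon_centroid(wall)
  half <- sweep(sweep(wall, 2, c0), 2, rep(sqrt(0.5), 2), `*`) +
    rep(c0, each = nrow(wall))
  m_half <- remesh_from_wound(mesh, half)
  expect_lt(abs(cavity_area(m_half) - 0.5 * cavity_area(mesh)) /
              cavity_area(mesh), 0.05)
  scar <- sum(bctshape:::element_areas(m_half$nodes, m_half$tri)[
    m_half$material == 5L])
  expect_lt(abs(scar - 0.5 * cavity_area(mesh)) / cavity_area(mesh), 0.05)
  expect_lt(abs(mesh_area(m_half) + cavity_area(m_half) - total0) / total0,
            0.01)

  ## closed wound: cavity disappears, scar fills it
  m_closed <- remesh_from_wound(mesh, NULL)
  expect_identical(cavity_area(m_closed), 0)
  expect_identical(sum(m_closed$belem[, "marker"] == 3L), 0L)
  scar_full <- sum(bctshape:::element_areas(m_closed$nodes, m_closed$tri)[
    m_closed$material == 5L])
  expect_lt(abs(scar_full - cavity_area(mesh)) / cavity_area(mesh), 0.01)
  expect_gte(mesh_min_angle(m_closed), 20)
})

test_that("the inflamed ring surrounds the cavity without touching skin", {
  study <- default_study()
  m <- mark_inflamed_ring(study$mesh_cav, width = 5)
  ring <- which(m$material == 6L)
  expect_gt(length(ring), 0)
  ## ring elements lie within ~ width + cell of the cavity wall
  wall <- cavity_wall_contour(m)
  ctrds <- (m$nodes[m$tri[ring, 1], , drop = FALSE] +
              m$nodes[m$tri[ring, 2], , drop = FALSE] +
              m$nodes[m$tri[ring, 3], , drop = FALSE]) / 3
  d <- apply(ctrds, 1, function(p)
    min(sqrt((wall[, 1] - p[1])^2 + (wall[, 2] - p[2])^2)))
  expect_lt(max(d), 5 + 2 * m$h)
})

test_that("mesh files round-trip through MSH and export to VTK", {
  mesh <- build_mesh(block_map(6, 6, 1, chest_cols = 1L), 1)
  p <- withr::local_tempfile(fileext = ".msh")
  write_mesh_msh(mesh, p)
  back <- read_mesh_msh(p)
  expect_equal(back$nodes, unname(mesh$nodes), tolerance = 1e-9)
  expect_identical(back$tri, unname(mesh$tri))
  expect_identical(back$material, as.integer(mesh$material))
  expect_identical(back$belem[, "marker"], mesh$belem[, "marker"])

  v <- withr::local_tempfile(fileext = ".vtk")
  write_mesh_vtk(mesh, v)
  head <- readLines(v, n = 5)
  expect_identical(head[4], "DATASET UNSTRUCTURED_GRID")
})

test_that("PGM and contour CSV round-trip", {
  img <- matrix(sample(0:255, 60, TRUE), 6, 10)
  p <- withr::local_tempfile(fileext = ".pgm")
  write_pgm(img, p)
  expect_identical(read_pgm(p), img + 0)

  ctr <- cbind(x = c(0, 3, 3, 0), y = c(0, 0, 2, 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_contour_csv(ctr, f)
  expect_equal(read_contour_csv(f), as.matrix(
    data.frame(x_mm = c(0, 3, 3, 0), y_mm = c(0, 0, 2, 2))),
    ignore_attr = TRUE)
})
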