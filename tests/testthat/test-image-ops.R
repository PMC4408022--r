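test_that("fuzzy C-means separates well-separated constant regions", {
  img <- matrix(rep(c(60, 120, 200), each = 30), nrow = 9)
  res <- fuzzy_cmeans(img, n_classes = 3, seed = 1)
  expect_equal(res$centroids, c(60, 120, 200), tolerance = 1e-3)
  expect_true(all(abs(res$membership - round(res$membership)) < 1e-2))
  expect_true(all(abs(rowSums(res$membership) - 1) < 1e-12))
  expect_identical(res$labels,
                   matrix(rep(1:3, each = 30), nrow = 9))
})

test_that("fuzzy C-means matches a hand-rolled iteration on a small signal", {
  x <- c(1, 2, 3, 10, 11, 12)
  ## brute-force FCM (m = 2) from the same initial centroids
  set.seed(1)
  v <- sort(stats::quantile(x, c(0.25, 0.75), names = FALSE) +
              stats::rnorm(2, 0, diff(range(x)) * 0.01))
  for (it in 1:200) {
    d <- pmax(abs(outer(x, v, "-")), 1e-12)
    u <- (1 / d^2) / rowSums(1 / d^2)
    v_new <- colSums(u^2 * x) / colSums(u^2)
    if (max(abs(v_new - v)) < 1e-5) { v <- v_new; break }
    v <- v_new
  }
  res <- fuzzy_cmeans(matrix(x, 1), n_classes = 2, m = 2, tol = 1e-5,
                      seed = 1)
  expect_equal(res$centroids, v, tolerance = 1e-6)
  expect_equal(as.vector(res$membership), as.vector(u), tolerance = 1e-4)
})

test_that("fuzzy C-means agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(42)
  x <- c(rnorm(150, 60, 6), rnorm(150, 130, 6), rnorm(100, 210, 6))
  res <- fuzzy_cmeans(matrix(x, 10), n_classes = 3, seed = 2)
  ref <- e1071::cmeans(matrix(x), centers = 3, m = 2)
  expect_equal(res$centroids, sort(as.vector(ref$centers)),
               tolerance = 1e-2)
})

test_that("the FCM objective is non-increasing along the iteration", {
  set.seed(5)
  img <- matrix(sample(c(50, 120, 190), 200, TRUE) + rnorm(200, 0, 8), 10)
  objs <- vapply(1:8, function(k) {
    r <- fuzzy_cmeans(img, n_classes = 3, max_iter = k, tol = 0, seed = 9)
    bctshape:::fcm_objective(img, r$membership, r$centroids)
  }, numeric(1))
  expect_true(all(diff(objs) < 1e-8))
})

test_that("segmentation of a noisy phantom image recovers tissue labels", {
  map <- default_map()
  ## merge the thin interface classes into their intensity neighbours so
  ## the image carries the three FCM classes
  img <- generate_mri_image(map,
                            class_means = c(background = 20, fat = 200,
                                            glandular = 120, skin = 200,
                                            chest = 20),
                            noise_sd = 10, seed = 8)
  res <- fuzzy_cmeans(img, n_classes = 3, seed = 1)
  truth <- matrix(1L, nrow(img), ncol(img))       # background/chest
  truth[map$labels == 2L] <- 2L                   # glandular
  truth[map$labels %in% c(1L, 3L)] <- 3L          # fat/skin
  for (cls in 1:3) {
    a <- res$labels == cls; b <- truth == cls
    dice <- 2 * sum(a & b) / (sum(a) + sum(b))
    expect_gt(dice, 0.9)
  }
})

test_that("Tikhonov smoothing solves the curvature-penalised problem", {
  prof <- c(1, 2, 3, 4, 5)
  expect_identical(tikhonov_smooth(prof, 0), prof)
  expect_equal(tikhonov_smooth(rep(3, 10), 25), rep(3, 10), tolerance = 1e-10)

  set.seed(3)
  d <- seq(0, 3, length.out = 10) + rnorm(10, 0, 0.3)
  ## dense normal-equations oracle
  D2 <- matrix(0, 8, 10)
  for (k in 1:8) D2[k, k:(k + 2)] <- c(1, -2, 1)
  u_ref <- solve(diag(10) + 1 * t(D2) %*% D2, d)
  expect_equal(tikhonov_smooth(d, 1), as.vector(u_ref), tolerance = 1e-10)

  ## curvature shrinks, and the map is linear
  curv <- function(u) sum((D2 %*% u)^2)
  expect_lte(curv(tikhonov_smooth(d, 1)), curv(d))
  a <- tikhonov_smooth(d, 2); b <- tikhonov_smooth(2 * d, 2)
  expect_equal(2 * a, b, tolerance = 1e-10)
})

test_that("contour extraction is exactly area-consistent", {
  mask <- matrix(FALSE, 10, 14)
  mask[3:7, 4:9] <- TRUE      # 5 x 6 pixel rectangle
  ctr <- extract_contour(mask, pixel_pitch = 0.5)
  per <- sum(sqrt(rowSums((ctr - ctr[c(2:nrow(ctr), 1), ])^2)))
  expect_equal(per, 2 * (5 + 6) * 0.5, tolerance = 1e-9)
  expect_equal(polygon_area(ctr), 30 * 0.25, tolerance = 1e-9)

  single <- matrix(FALSE, 3, 3); single[2, 2] <- TRUE
  ctr1 <- extract_contour(single, pixel_pitch = 1)
  expect_equal(abs(polygon_area(ctr1)), 1, tolerance = 1e-9)

  expect_error(extract_contour(matrix(FALSE, 3, 3)), "foreground")
  two <- matrix(FALSE, 5, 5); two[1, 1] <- TRUE; two[5, 5] <- TRUE
  expect_error(extract_contour(two), "single connected")

  map <- default_map()
  ctr2 <- extract_contour(map)
  expect_equal(polygon_area(ctr2),
               sum(tissue_mask(map)) * map$pixel_pitch^2,
               tolerance = 1e-9)
})
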