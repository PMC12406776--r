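test_that("nearest-neighbor distances on simple configurations", {
  out <- nearest_neighbor_distances(data.frame(x = c(0, 1, 3), y = 0))
  expect_equal(out$nn_distance, c(1, 1, 2))

  pair <- nearest_neighbor_distances(data.frame(x = c(0, 5), y = c(0, 0)))
  expect_equal(pair$nn_distance, c(5, 5))

  expect_error(nearest_neighbor_distances(data.frame(x = 1, y = 1)), "2 points")
})

test_that("nearest and k-neighbor distances match an all-pairs brute force", {
  for (s in 1:50) {
    pts <- withr::with_seed(s, data.frame(x = runif(20, 0, 100), y = runif(20, 0, 100)))
    nn <- nearest_neighbor_distances(pts)$nn_distance
    km <- k_neighbor_mean_distances(pts, k = 9)$k_mean_distance
    for (i in seq_len(nrow(pts))) {
      dd <- sqrt((pts$x - pts$x[i])^2 + (pts$y - pts$y[i])^2)[-i]
      expect_equal(nn[i], min(dd))
      expect_equal(km[i], mean(sort(dd)[1:9]))
    }
  }
})

test_that("k-neighbor means on hand-enumerable points", {
  out <- k_neighbor_mean_distances(data.frame(x = c(0, 1, 3), y = 0), k = 2)
  expect_equal(out$k_mean_distance, c(2, 1.5, 2.5))

  pts <- data.frame(x = c(0, 2, 7, 11), y = 0)
  expect_equal(k_neighbor_mean_distances(pts, k = 1)$k_mean_distance,
               nearest_neighbor_distances(pts)$nn_distance)
  expect_error(k_neighbor_mean_distances(pts, k = 4), "k <")
})

test_that("distances are rigid-motion invariant and scale linearly", {
  pts <- withr::with_seed(7, data.frame(x = runif(15, 0, 50), y = runif(15, 0, 50)))
  base_nn <- nearest_neighbor_distances(pts)$nn_distance
  base_k <- k_neighbor_mean_distances(pts, 9)$k_mean_distance
  th <- 0.83
  rot <- data.frame(x = pts$x * cos(th) - pts$y * sin(th) + 12.5,
                    y = pts$x * sin(th) + pts$y * cos(th) - 3.1)
  expect_equal(nearest_neighbor_distances(rot)$nn_distance, base_nn, tolerance = 1e-9)
  expect_equal(k_neighbor_mean_distances(rot, 9)$k_mean_distance, base_k, tolerance = 1e-9)
  sc <- data.frame(x = pts$x * 2.5, y = pts$y * 2.5)
  expect_equal(nearest_neighbor_distances(sc)$nn_distance, base_nn * 2.5, tolerance = 1e-9)
})

test_that("cluster areas respect the strict area floor", {
  img <- matrix(0, 80, 80)
  img[11:40, 11:30] <- 1          # 30 x 20 = 600 px
  expect_equal(cluster_areas(img, blur_sigma = 0, threshold = 0.5)$area_px, 600L)
  expect_equal(nrow(cluster_areas(img, blur_sigma = 0, threshold = 0.5,
                                  min_area = 600)), 0L)
  img[51:70, 51:70] <- 1          # second cluster, 400 px
  out <- cluster_areas(img, blur_sigma = 0, threshold = 0.5)
  expect_equal(out$area_px, 600L)
  # raising min_area never adds a component
  lo <- cluster_areas(img, blur_sigma = 0, threshold = 0.5, min_area = 100)
  hi <- cluster_areas(img, blur_sigma = 0, threshold = 0.5, min_area = 500)
  expect_true(all(hi$area_px %in% lo$area_px))
  expect_lte(nrow(hi), nrow(lo))
})

test_that("cluster areas max-project multi-page input and blur smooths it", {
  p1 <- matrix(0, 60, 60); p1[11:40, 11:30] <- 100
  p2 <- matrix(0, 60, 60); p2[45:54, 45:54] <- 100   # 100 px, below floor
  out <- cluster_areas(list(p1, p2), blur_sigma = 1, threshold = 50, min_area = 400)
  expect_equal(nrow(out), 1L)
  expect_lt(abs(out$area_px - 600), 40)   # blur moves the boundary slightly
})

test_that("KS statistic equals the step-point enumeration", {
  expect_equal(ks_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_statistic(c(0, 1), c(2, 3)), 1)
  expect_equal(ks_statistic(c(1, 2, 3, 4), c(2, 3, 4, 5)), 0.25)
  expect_error(ks_statistic(numeric(0), 1), "non-empty")
})

test_that("KS statistic is symmetric and matches the reference test", {
  for (s in 1:20) {
    a <- withr::with_seed(s, rnorm(37))
    b <- withr::with_seed(1000 + s, rnorm(23, 0.4))
    d1 <- ks_statistic(a, b)
    expect_equal(d1, ks_statistic(b, a))
    ref <- suppressWarnings(stats::ks.test(a, b)$statistic)
    expect_equal(d1, unname(ref))
  }
  expect_equal(ks_statistic(c(2, 2, 3), c(2, 2, 3)), 0)
})

test_that("combined neighbor stats join both metrics", {
  pts <- withr::with_seed(3, data.frame(x = runif(12), y = runif(12)))
  ns <- neighbor_stats(pts, k = 5)
  expect_equal(names(ns), c("point", "nn_distance", "k_mean_distance"))
  expect_equal(ns$nn_distance, nearest_neighbor_distances(pts)$nn_distance)
  expect_equal(attr(ns, "k"), 5L)
})
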