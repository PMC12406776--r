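test_that("noise estimate is zero on constant images and errors on tiny ones", {
  expect_equal(estimate_noise(matrix(7, 16, 16)), 0)
  expect_error(estimate_noise(matrix(1, 1, 3)), "too small")
})

test_that("noise estimate recovers the simulated standard deviation", {
  field <- withr::with_seed(42, matrix(50 + rnorm(256 * 256, 0, 5), 256, 256))
  truth <- sd(field - 50)                      # oracle: sample sd of the field
  est <- estimate_noise(field)
  expect_gt(est, 4.5)
  expect_lt(est, 5.5)
  expect_lt(abs(est - truth), 0.5)
})

test_that("noise estimate ignores a smooth one-directional ramp", {
  ramp <- matrix(rep(1:50, each = 30), 30, 50)
  expect_lte(estimate_noise(ramp), 1)
})

test_that("component tree reflects the nesting of threshold components", {
  # constant image: a single candidate covering everything
  tr <- build_component_tree(matrix(3, 8, 8))
  expect_equal(nrow(tr$nodes), 1L)
  expect_equal(tr$nodes$area, 64L)

  # two disjoint squares: one chain per square
  tr <- build_component_tree(two_square_image())
  nonroot <- tr$nodes[!is.na(tr$nodes$parent), ]
  expect_equal(nrow(nonroot), 2L)
  expect_setequal(nonroot$area, c(100L, 225L))

  # bright core nested in a ring: the core's parent contains it
  img <- rect_image(c(30L, 30L), list(
    list(rows = 8:21, cols = 8:21, value = 100),
    list(rows = 12:17, cols = 12:17, value = 200)
  ))
  tr <- build_component_tree(img)
  core <- which(tr$nodes$level == 200)
  expect_length(core, 1L)
  outer_node <- tr$nodes$parent[core]
  expect_true(all(tr$pixels[[core]] %in% tr$pixels[[outer_node]]))
  expect_lt(tr$nodes$level[outer_node], 200)
})

test_that("significance score follows the two-sample z formula", {
  img <- rect_image(c(40L, 40L), list(list(rows = 11:20, cols = 11:20, value = 100)))
  px <- which(img == 100)
  # oracle: enumerate the ring by brute force and apply the formula
  d <- dim(img)
  ring <- c()
  for (p in px) {
    r0 <- ((p - 1) %% d[1]) + 1; c0 <- ((p - 1) %/% d[1]) + 1
    for (dr in -2:2) for (dc in -2:2) {
      r <- r0 + dr; c <- c0 + dc
      if (r >= 1 && r <= d[1] && c >= 1 && c <= d[2]) ring <- c(ring, (c - 1) * d[1] + r)
    }
  }
  ring <- setdiff(unique(ring), px)
  expected <- (100 - 0) / (1 * sqrt(1 / length(px) + 1 / length(ring)))
  expect_equal(score_region(img, px, sigma = 1), expected)
  expect_gt(expected, 500)   # same order as the canonical 707.1 example

  # doubling sigma exactly halves the score
  expect_equal(score_region(img, px, sigma = 2), expected / 2)
  # region mean equal to ring mean scores zero
  expect_equal(score_region(matrix(5, 40, 40), px, sigma = 1), 0)
})

test_that("significance score is shift invariant and interior-monotone", {
  img <- rect_image(c(40L, 40L), list(list(rows = 11:20, cols = 11:20, value = 100)))
  px <- which(img == 100)
  z0 <- score_region(img, px, sigma = 3)
  expect_equal(score_region(img + 55, px, sigma = 3), z0)
  brighter <- img; brighter[px] <- brighter[px] + 10
  expect_gt(score_region(brighter, px, sigma = 3), z0)
})

test_that("score errors when the region has no boundary context", {
  img <- matrix(9, 10, 10)
  expect_error(score_region(img, seq_along(img), sigma = 1), "no boundary context")
})

test_that("detection recovers zero-noise objects exactly and rejects flats", {
  expect_equal(nrow(detect_regions(matrix(4, 50, 50), min_area = 5)), 0L)

  img <- two_square_image()
  fr <- detect_regions(img, min_area = 5)
  expect_equal(nrow(fr), 2L)
  sq1 <- which(img == 200); sq2 <- which(img == 100)
  iou <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  expect_equal(iou(fr$pixels[[1]], sq1), 1)
  expect_equal(iou(fr$pixels[[2]], sq2), 1)
  # output is sorted by decreasing area
  expect_true(all(diff(fr$area_px) <= 0))
})

test_that("per-chain selection picks the candidate the score table dictates", {
  img <- rect_image(c(30L, 30L), list(
    list(rows = 8:21, cols = 8:21, value = 100),
    list(rows = 12:17, cols = 12:17, value = 200)
  ))
  sigma <- 40    # high noise floor: contrast matters, not Inf scores
  tr <- build_component_tree(img)
  cand <- tr$nodes[!is.na(tr$nodes$parent), ]
  zs <- vapply(cand$node_id, function(k) score_region(img, tr$pixels[[k]], sigma),
               numeric(1))
  best <- cand$node_id[which.max(zs)]
  fr <- detect_regions(img, min_area = 5, sigma = sigma, alpha = 0.5,
                       min_contrast = 0)
  expect_equal(nrow(fr), 1L)
  expect_setequal(fr$pixels[[1]], tr$pixels[[best]])
})

test_that("adding a global constant changes no detection", {
  img <- two_square_image()
  a <- detect_regions(img, min_area = 5, sigma = 4)
  b <- detect_regions(img + 31, min_area = 5, sigma = 4)
  expect_equal(a$area_px, b$area_px)
  expect_equal(a$pixels, b$pixels)
})
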