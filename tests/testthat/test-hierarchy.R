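test_that("skeleton of a bar runs along its midline with the right width", {
  bar <- matrix(FALSE, 9, 25); bar[3:7, 3:23] <- TRUE
  sk <- skeletonize_mask(bar)
  rows <- ((sk$idx - 1) %% 9) + 1
  expect_true(all(abs(rows - 5) <= 1))
  interior <- sk$width[sk$width == max(sk$width)]
  expect_true(all(interior >= 4 & interior <= 6))
})

test_that("skeleton width at a disk centre matches its diameter", {
  m <- disk_mask(10L)
  sk <- skeletonize_mask(m)
  expect_gte(max(sk$width), 18)
  expect_lte(max(sk$width), 20)
})

test_that("skeletonization requires a connected mask", {
  m <- matrix(FALSE, 20, 20)
  m[2:6, 2:6] <- TRUE; m[14:18, 14:18] <- TRUE
  expect_error(skeletonize_mask(m), "connected")
})

test_that("a plus-shape decomposes into one junction and four leaf branches", {
  m <- matrix(FALSE, 41, 41)
  m[19:23, 5:37] <- TRUE
  m[5:37, 19:23] <- TRUE
  bg <- build_branch_graph(skeletonize_mask(m))
  expect_equal(nrow(bg$nodes), 1L)
  expect_equal(nrow(bg$branches), 4L)
  expect_equal(bg$n_endpoints, 4L)
  expect_true(all(bg$branches$is_leaf))
})

test_that("a straight bar yields a single branch with two endpoints", {
  bar <- matrix(FALSE, 9, 40); bar[4:6, 3:38] <- TRUE
  bg <- build_branch_graph(skeletonize_mask(bar))
  expect_equal(nrow(bg$branches), 1L)
  expect_equal(nrow(bg$nodes), 0L)
  expect_equal(bg$n_endpoints, 2L)
})

test_that("a bare disk is all soma: no secondary, fine or terminal branches", {
  arbor <- classify_branches(build_branch_graph(skeletonize_mask(disk_mask(10L))))
  bc <- branch_counts(arbor)
  expect_equal(bc$branch_count[bc$type == "SOMA_PRIMARY"], 1L)
  expect_equal(sum(bc$branch_count[bc$type != "SOMA_PRIMARY"]), 0L)
})

test_that("a thin bar off a soma is fine with a terminal tip", {
  m <- disk_with_bar(radius = 9L, bar_len = 35L, bar_width = 2L)
  arbor <- classify_branches(build_branch_graph(skeletonize_mask(m)))
  bc <- branch_counts(arbor)
  expect_equal(bc$branch_count[bc$type == "SOMA_PRIMARY"], 1L)  # soma only
  expect_equal(bc$branch_count[bc$type == "FINE"], 1L)
  expect_equal(bc$branch_count[bc$type == "TERMINAL"], 1L)
})

test_that("a wide bar off a soma is a primary process", {
  m <- disk_with_bar(radius = 9L, bar_len = 35L, bar_width = 8L)
  arbor <- classify_branches(build_branch_graph(skeletonize_mask(m)))
  bc <- branch_counts(arbor)
  expect_equal(bc$branch_count[bc$type == "SOMA_PRIMARY"], 2L)  # soma + 1 primary
})

test_that("territory partitions the mask and segments partition the skeleton", {
  sim <- simulate_astrocyte(seed = 5, noise_sd = 0)
  res <- run_pipeline(sim$cell, verbose = FALSE)
  arbor <- res$arbors[[1]]
  # every mask pixel labelled exactly once
  expect_true(all(arbor$territory[arbor$mask_idx] > 0L))
  expect_true(all(arbor$territory[-arbor$mask_idx] == 0L))
  # no skeleton pixel in two segments
  allseg <- unlist(arbor$segments$pixels[arbor$segments$role != "soma"])
  expect_equal(anyDuplicated(allseg), 0L)
  # every terminal segment sits on a leaf branch
  segs <- arbor$segments
  tips <- segs[segs$role == "tip", ]
  expect_true(all(tips$type == "TERMINAL"))
})

test_that("upscaling a mask doubles widths and keeps topology", {
  m <- disk_with_bar(radius = 8L, bar_len = 30L, bar_width = 4L)
  up <- m[rep(seq_len(nrow(m)), each = 2L), rep(seq_len(ncol(m)), each = 2L)]
  bg1 <- build_branch_graph(skeletonize_mask(m))
  bg2 <- build_branch_graph(skeletonize_mask(up))
  a1 <- classify_branches(bg1); a2 <- classify_branches(bg2)
  expect_equal(nrow(bg1$branches), nrow(bg2$branches))
  w1 <- max(bg1$branches$mean_width_px); w2 <- max(bg2$branches$mean_width_px)
  expect_gt(w2 / w1, 2 * 0.85)
  expect_lt(w2 / w1, 2 * 1.15)
  expect_gt(a2$soma_width_px / a1$soma_width_px, 2 * 0.85)
  expect_lt(a2$soma_width_px / a1$soma_width_px, 2 * 1.15)
})

test_that("branch-type classification recovers generator labels", {
  # agreement measured per typed segment against the rendered label raster
  ok <- 0L; n <- 0L
  for (sd in c(2, 9)) {
    sim <- simulate_astrocyte(seed = sd, noise_sd = 0)
    res <- run_pipeline(sim$cell, verbose = FALSE)
    arbor <- res$arbors[[1]]
    segs <- arbor$segments[arbor$segments$role != "soma", ]
    for (i in seq_len(nrow(segs))) {
      gtl <- sim$type_map[segs$pixels[[i]]]
      gtl <- gtl[gtl > 0L]
      if (length(gtl) == 0L) next
      want <- branch_types()[as.integer(names(which.max(table(gtl))))]
      n <- n + 1L
      if (want == segs$type[i] ||
          (segs$role[i] == "primary_ext" && want == "SOMA_PRIMARY")) ok <- ok + 1L
    }
  }
  expect_gte(ok / n, 0.9)
})
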