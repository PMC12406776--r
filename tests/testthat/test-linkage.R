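test_that("brightest path on a 1x5 strip includes both terminal pixels", {
  strip <- matrix(c(100, 80, 10, 90, 100), 1, 5)
  bp <- brightest_path(strip, 1L, 5L)
  expect_equal(bp$weight, mean(c(100, 80, 10, 90, 100)))
  expect_equal(bp$bottleneck, 10)
  expect_equal(bp$path, 1:5)
})

test_that("bottleneck routing prefers the higher-floor corridor", {
  # two corridors between the end pixels: top constant 50, bottom 90/20/90
  img <- matrix(0, 3, 5)
  img[1, ] <- 50
  img[3, ] <- c(0, 90, 20, 90, 0)
  img[2, 1] <- 50; img[2, 5] <- 50            # connect ends to both corridors
  a <- rc_to_idx_test(2, 1, dim(img)); b <- rc_to_idx_test(2, 5, dim(img))
  bp <- brightest_path(img, a, b)
  expect_equal(bp$bottleneck, brute_bottleneck(img, a, b))
  expect_equal(bp$bottleneck, 50)
  rows <- ((bp$path - 1) %% 3) + 1
  expect_true(all(rows <= 2))                 # stays off the dim corridor
})

test_that("4-adjacent fragments link through their two facing pixels", {
  img <- matrix(c(10, 20), 1, 2)
  bp <- brightest_path(img, 1L, 2L)
  expect_equal(bp$path, c(1L, 2L))
  expect_equal(bp$weight, 15)
})

test_that("returned bottleneck matches brute force on random grids", {
  for (s in 1:30) {
    img <- withr::with_seed(s, matrix(sample(1:100, 25, replace = TRUE), 5, 5))
    a <- 1L; b <- 25L
    bp <- brightest_path(img, a, b)
    expect_equal(bp$bottleneck, threshold_bottleneck(img, a, b))
  }
})

test_that("fragment graph holds one brightest-path edge per pair", {
  img <- rect_image(c(40L, 40L), list(
    list(rows = 5:9, cols = 5:9, value = 100),
    list(rows = 5:9, cols = 30:34, value = 100),
    list(rows = 30:34, cols = 18:22, value = 100)
  ), background = 10)
  fr <- detect_regions(img, min_area = 5, sigma = 2)
  expect_equal(nrow(fr), 3L)
  g <- build_fragment_graph(img, fr)
  expect_equal(nrow(g), 3L)
  for (e in seq_len(nrow(g))) {
    i <- match(g$frag_a[e], fr$id); k <- match(g$frag_b[e], fr$id)
    bp <- brightest_path(img, fr$pixels[[i]], fr$pixels[[k]])
    expect_equal(g$weight[e], bp$weight)
  }
  g1 <- build_fragment_graph(img, fr[1, ])
  expect_equal(nrow(g1), 0L)
})

test_that("spanning-tree linkage maximises total weight", {
  tri <- tibble::tibble(frag_a = c(1L, 1L, 2L), frag_b = c(2L, 3L, 3L),
                        weight = c(3, 2, 1))
  lk <- link_fragments(tri)
  expect_equal(sum(lk$in_tree), 2L)
  expect_equal(attr(lk, "total_weight"), 5)
  expect_true(all(lk$in_tree[lk$weight %in% c(3, 2)]))

  single <- tibble::tibble(frag_a = 1L, frag_b = 2L, weight = 5)
  lk1 <- link_fragments(single)
  expect_true(lk1$in_tree)
  expect_equal(attr(lk1, "total_weight"), 5)

  # complete 4-node graph against full enumeration
  for (s in 1:25) {
    pr <- t(utils::combn(4L, 2L))
    edges <- withr::with_seed(s, tibble::tibble(
      frag_a = pr[, 1], frag_b = pr[, 2],
      weight = sample(seq_len(60), 6)))
    lk <- link_fragments(edges)
    expect_equal(attr(lk, "total_weight"), brute_max_spanning(edges, 4L))
  }
})

test_that("spanning-tree linkage agrees with an independent MST solver", {
  skip_if_not_installed("igraph")
  for (s in 1:10) {
    n <- 7L
    pr <- t(utils::combn(n, 2L))
    edges <- withr::with_seed(100 + s, tibble::tibble(
      frag_a = pr[, 1], frag_b = pr[, 2],
      weight = runif(nrow(pr), 1, 50)))
    lk <- link_fragments(edges)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    mst <- igraph::mst(g, weights = max(edges$weight) - edges$weight)
    sel <- igraph::as_data_frame(mst)
    expect_equal(attr(lk, "total_weight"),
                 sum(edges$weight[match(paste(sel$from, sel$to),
                                        paste(edges$frag_a, edges$frag_b))]))
  }
})

test_that("cell assembly honours the linkage cut", {
  img <- rect_image(c(40L, 80L), list(
    list(rows = 15:24, cols = 5:14, value = 100),
    list(rows = 15:24, cols = 25:34, value = 100),
    list(rows = 15:24, cols = 65:74, value = 100)
  ), background = 20)
  img[18:21, 15:24] <- 90      # bright bridge between fragments 1 and 2
  img[, 35:64] <- 10           # wide dim band isolating fragment 3
  fr <- detect_regions(img, min_area = 5, sigma = 2, max_area = 150)
  expect_equal(nrow(fr), 3L)
  g <- build_fragment_graph(img, fr)
  tree <- link_fragments(g)

  all_linked <- assemble_cells(img, fr, tree, min_link_weight = 0)
  expect_equal(nrow(all_linked), 1L)
  expect_true(all(unlist(fr$pixels) %in% all_linked$pixels[[1]]))

  cut <- assemble_cells(img, fr, tree, min_link_weight = 60)
  expect_equal(nrow(cut), 2L)

  empty <- assemble_cells(img, fr[0, ], tree, min_link_weight = 0)
  expect_equal(nrow(empty), 0L)
})

test_that("a cell mask is internally connected and re-links to one component", {
  img <- rect_image(c(40L, 40L), list(
    list(rows = 10:19, cols = 5:14, value = 100),
    list(rows = 10:19, cols = 25:34, value = 100)
  ), background = 20)
  img[14:15, 15:24] <- 80
  fr <- detect_regions(img, min_area = 5, sigma = 2, max_area = 200)
  tree <- link_fragments(build_fragment_graph(img, fr))
  cells <- assemble_cells(img, fr, tree, min_link_weight = 0)
  expect_equal(nrow(cells), 1L)
  d <- dim(img)
  m <- matrix(FALSE, d[1], d[2]); m[cells$pixels[[1]]] <- TRUE
  expect_equal(max(astroseg:::label_components(m, 8L)), 1L)

  # re-detect restricted to the mask, re-link: still a single component
  img2 <- img; img2[!m] <- 0
  fr2 <- detect_regions(img2, min_area = 5, sigma = 2, max_area = 200)
  tree2 <- link_fragments(build_fragment_graph(img2, fr2))
  cells2 <- assemble_cells(img2, fr2, tree2, min_link_weight = 0)
  expect_equal(nrow(cells2), 1L)
})
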