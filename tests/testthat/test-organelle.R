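# minimal hand-built arbor for assignment tests: a 20x30 mask split into
# a SECONDARY territory (left half) and a FINE territory (right half),
# with a small soma strip at the far left
toy_arbor <- function() {
  d <- c(20L, 30L)
  territory <- matrix(0L, d[1L], d[2L])
  territory[, 1:4] <- 1L      # soma
  territory[, 5:15] <- 2L     # secondary
  territory[, 16:30] <- 3L    # fine
  segments <- tibble::tibble(
    segment_id = 1:3,
    branch_id = c(NA_integer_, 1L, 2L),
    type = c("SOMA_PRIMARY", "SECONDARY", "FINE"),
    length_px = c(NA_integer_, 11L, 15L),
    mean_width_px = c(10, 4, 2),
    pixels = list(which(territory == 1L), which(territory == 2L),
                  which(territory == 3L)),
    role = c("soma", "branch", "branch"),
    node_a = NA_integer_, node_b = NA_integer_
  )
  structure(list(segments = segments, territory = territory,
                 soma_nodes = integer(0), soma_idx = which(territory == 1L),
                 soma_width_px = 10, dim = d, mask_idx = which(territory > 0L),
                 params = list()),
            class = "astro_arbor")
}

mk_mito <- function(pixels, dim) {
  out <- tibble::tibble(mito_id = seq_along(pixels),
                        size_px = lengths(pixels),
                        mean_intensity = 100, zscore = 10,
                        centroid_row = 0, centroid_col = 0,
                        pixels = pixels)
  attr(out, "dim_img") <- dim
  class(out) <- c("astro_mitos", class(out))
  out
}

test_that("mitochondria are detected only inside the cell mask", {
  d <- c(50L, 50L)
  mask <- matrix(FALSE, d[1L], d[2L]); mask[10:40, 10:40] <- TRUE
  blank <- matrix(20, d[1L], d[2L])
  expect_equal(nrow(detect_mitochondria(blank, mask)), 0L)

  img <- matrix(20, d[1L], d[2L])
  img[12:14, 12:15] <- 220   # inside, 12 px
  img[20:22, 20:23] <- 220   # inside
  img[30:32, 30:33] <- 220   # inside
  img[44:46, 44:47] <- 220   # outside mask
  mt <- detect_mitochondria(img, mask, sigma = 4)
  expect_equal(nrow(mt), 3L)
  expect_true(all(unlist(mt$pixels) %in% which(mask)))
  expect_equal(sort(mt$size_px), c(12L, 12L, 12L))
})

test_that("shape mismatch between channels is an error", {
  expect_error(detect_mitochondria(matrix(0, 10, 10), matrix(TRUE, 12, 12)),
               "different shapes")
})

test_that("assignment follows pixel plurality with fine-ward ties", {
  arbor <- toy_arbor()
  d <- arbor$dim
  fine_px <- rc_to_idx_test(rep(8:10, 3), rep(20:22, each = 3), d)      # all FINE
  straddle <- c(rc_to_idx_test(rep(9, 3), 13:15, d),                    # 3 SECONDARY
                rc_to_idx_test(rep(9, 3), 16:18, d))                    # 3 FINE: tie
  sec_px <- rc_to_idx_test(rep(9, 4), 6:9, d)                           # all SECONDARY
  soma_px <- rc_to_idx_test(rep(9, 4), 1:4, d)                          # soma
  mt <- assign_mitochondria(mk_mito(list(fine_px, straddle, sec_px, soma_px), d), arbor)
  expect_equal(as.character(mt$assigned_type),
               c("FINE", "FINE", "SECONDARY", "SOMA_PRIMARY"))
  expect_equal(mt$excluded, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("a mitochondrion outside the cell is an error", {
  arbor <- toy_arbor()
  bad <- mk_mito(list(100000L), arbor$dim)  # out of territory
  bad$pixels[[1]] <- rc_to_idx_test(1, 1, arbor$dim)
  arbor$territory[1, 1] <- 0L
  expect_error(assign_mitochondria(bad, arbor), "outside cell")
})

test_that("profile statistics report only non-soma types and conserve counts", {
  arbor <- toy_arbor()
  d <- arbor$dim
  px <- list(rc_to_idx_test(rep(5, 4), 20:23, d),   # FINE size 4
             rc_to_idx_test(rep(15, 6), 20:25, d),  # FINE size 6
             rc_to_idx_test(rep(5, 5), 6:10, d),    # SECONDARY size 5
             rc_to_idx_test(rep(5, 3), 1:3, d))     # soma -> excluded
  mt <- assign_mitochondria(mk_mito(px, d), arbor)
  prof <- mito_stats(mt, arbor = arbor, cell_id = 1L, pixel_size = 0.5)
  expect_equal(prof$mito_count[prof$type == "FINE"], 2L)
  expect_equal(prof$mito_mean_size_px[prof$type == "FINE"], 5)
  expect_equal(prof$mito_mean_size_um2[prof$type == "FINE"], 5 * 0.25)
  expect_equal(prof$mito_count[prof$type == "SECONDARY"], 1L)
  expect_true(is.na(prof$mito_count[prof$type == "SOMA_PRIMARY"]))
  expect_true(is.na(prof$mito_mean_size_px[prof$type == "SOMA_PRIMARY"]))
  expect_equal(prof$mito_count[prof$type == "TERMINAL"], 0L)
  expect_true(is.na(prof$mito_mean_size_px[prof$type == "TERMINAL"]))
  # conservation: reported + excluded = total
  expect_equal(sum(prof$mito_count, na.rm = TRUE) +
                 attr(prof, "excluded_mito_count"), nrow(mt))
})

test_that("random assignment fixtures match a brute-force recount", {
  arbor <- toy_arbor()
  d <- arbor$dim
  for (s in 1:5) {
    pxs <- withr::with_seed(s, {
      lapply(1:30, function(i) {
        r <- sample(2:19, 1); c <- sample(2:28, 1)
        unique(rc_to_idx_test(c(r, r, r + 1), c(c, c + 1, c), d))
      })
    })
    mt <- assign_mitochondria(mk_mito(pxs, d), arbor)
    prof <- mito_stats(mt, arbor = arbor)
    # independent recount straight from the territory map
    types <- vapply(pxs, function(p) {
      lab <- arbor$territory[p]
      tys <- arbor$segments$type[match(lab, arbor$segments$segment_id)]
      tt <- table(tys)
      cand <- names(tt)[tt == max(tt)]
      ord <- c(SOMA_PRIMARY = 1, SECONDARY = 2, FINE = 3, TERMINAL = 4)
      cand[which.max(ord[cand])]
    }, character(1))
    for (ty in c("SECONDARY", "FINE", "TERMINAL"))
      expect_equal(prof$mito_count[prof$type == ty], sum(types == ty))
    expect_equal(attr(prof, "excluded_mito_count"), sum(types == "SOMA_PRIMARY"))
    expect_equal(sum(prof$mito_count, na.rm = TRUE) +
                   attr(prof, "excluded_mito_count"), 30L)
  }
})

test_that("generator placements are recovered type-for-type at zero noise", {
  for (sd in c(4, 11)) {
    sim <- simulate_astrocyte(seed = sd, noise_sd = 0)
    res <- run_pipeline(sim$cell, verbose = FALSE)
    mt <- detect_mitochondria(sim$mito, res$cells)
    mt <- assign_mitochondria(mt, res$arbors[[1]])
    expect_equal(nrow(mt), nrow(sim$gt$mitos))
    ok <- 0L
    for (i in seq_len(nrow(mt))) {
      inst <- sim$mito_map[mt$pixels[[i]]]
      inst <- inst[inst > 0L]
      gti <- as.integer(names(which.max(table(inst))))
      if (sim$gt$mitos$intended_type[gti] == as.character(mt$assigned_type[i]))
        ok <- ok + 1L
    }
    expect_equal(ok, nrow(mt))
  }
})
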