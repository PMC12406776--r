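# fixture builders shared across the suite; everything is generated in
# code so the repository carries no binary test data

# image with axis-aligned constant-intensity rectangles on a flat background
rect_image <- function(dim = c(60L, 60L), rects = list(), background = 0) {
  img <- matrix(background, dim[1L], dim[2L])
  for (r in rects) img[r$rows, r$cols] <- r$value
  img
}

two_square_image <- function() {
  rect_image(c(60L, 60L), list(
    list(rows = 5:14, cols = 5:14, value = 100),
    list(rows = 30:44, cols = 30:44, value = 200)
  ))
}

# integer-valued pseudo-normal noise field (16-bit-like camera counts)
noise_image <- function(dim = c(128L, 128L), mean = 50, sd = 5, seed = 1L) {
  withr::with_seed(seed, {
    matrix(pmax(0, round(rnorm(prod(dim), mean, sd))), dim[1L], dim[2L])
  })
}

# solid disk mask
disk_mask <- function(radius = 10L, pad = 5L) {
  n <- 2L * (radius + pad) + 1L
  ctr <- radius + pad + 1L
  outer(seq_len(n), seq_len(n), function(r, c) (r - ctr)^2 + (c - ctr)^2 <= radius^2)
}

# disk with one horizontal bar of the given width attached to its right
disk_with_bar <- function(radius = 9L, bar_len = 40L, bar_width = 2L, pad = 6L) {
  h <- 2L * (radius + pad) + 1L
  w <- h + bar_len + pad
  m <- matrix(FALSE, h, w)
  ctr <- radius + pad + 1L
  for (r in seq_len(h)) for (c in seq_len(h))
    if ((r - ctr)^2 + (c - ctr)^2 <= radius^2) m[r, c] <- TRUE
  rows <- (ctr - floor(bar_width / 2)):(ctr + ceiling(bar_width / 2) - 1L)
  m[rows, (ctr + radius - 1L):(ctr + radius + bar_len)] <- TRUE
  m
}

# brute-force maximum bottleneck over all simple 8-connected paths
brute_bottleneck <- function(img, from, to) {
  d <- dim(img)
  best <- -Inf
  path_min <- function(idx, visited, mn) {
    if (idx == to) { best <<- max(best, mn); return(invisible()) }
    rc <- c(((idx - 1L) %% d[1L]) + 1L, ((idx - 1L) %/% d[1L]) + 1L)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      r <- rc[1L] + dr; c <- rc[2L] + dc
      if (r < 1L || r > d[1L] || c < 1L || c > d[2L]) next
      nxt <- (c - 1L) * d[1L] + r
      if (visited[nxt]) next
      visited[nxt] <- TRUE
      path_min(nxt, visited, min(mn, img[nxt]))
      visited[nxt] <- FALSE
    }
  }
  v <- rep(FALSE, length(img)); v[from] <- TRUE
  path_min(from, v, img[from])
  best
}

# brute-force maximum spanning tree weight by enumerating all edge subsets
# of size n-1 that connect the graph
brute_max_spanning <- function(edges, n) {
  m <- nrow(edges)
  best <- -Inf
  for (comb in utils::combn(m, n - 1L, simplify = FALSE)) {
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ok <- TRUE
    for (e in comb) {
      ra <- find(edges$frag_a[e]); rb <- find(edges$frag_b[e])
      if (ra == rb) { ok <- FALSE; break }
      parent[max(ra, rb)] <- min(ra, rb)
    }
    if (ok) best <- max(best, sum(edges$weight[comb]))
  }
  best
}

rc_to_idx_test <- function(r, c, dim) (c - 1L) * dim[1L] + r

# independent max-bottleneck oracle: the bottleneck equals the highest
# threshold at which both endpoints lie in one 8-connected component of
# the upper-threshold set (a different algorithm from the path search)
threshold_bottleneck <- function(img, from, to) {
  for (t in sort(unique(as.vector(img)), decreasing = TRUE)) {
    lab <- astroseg:::label_components(img >= t, 8L)
    if (lab[from] > 0L && lab[from] == lab[to]) return(t)
  }
  NA_real_
}
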