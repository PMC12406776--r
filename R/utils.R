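# internal helpers shared across modules

# validate an intensity image; returns the matrix
check_image <- function(img, arg = "img") {
  if (inherits(img, "Image")) img <- EBImage::imageData(img)
  if (!is.matrix(img) || !is.numeric(img))
    abort(sprintf("`%s` must be a numeric matrix", arg))
  if (nrow(img) < 1L || ncol(img) < 1L)
    abort(sprintf("`%s` must have at least one row and one column", arg))
  if (any(!is.finite(img)))
    abort(sprintf("`%s` must contain only finite values", arg))
  if (any(img < 0))
    abort(sprintf("`%s` must be non-negative", arg))
  img
}

# evaluate code under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# linear index <-> (row, col); all internal indices are R-style 1-based,
# user-facing tables report 0-based coordinates with row 0 at the top
idx_to_rc <- function(idx, dim) {
  cbind(row = ((idx - 1L) %% dim[1L]) + 1L,
        col = ((idx - 1L) %/% dim[1L]) + 1L)
}

rc_to_idx <- function(row, col, dim) {
  (col - 1L) * dim[1L] + row
}

# connected-component labelling of a logical matrix.
# 4-connectivity via EBImage::bwlabel; 8-connectivity merges labels that
# touch diagonally with a union-find pass.
label_components <- function(mask, connectivity = 4L) {
  stopifnot(connectivity %in% c(4L, 8L))
  lab <- EBImage::imageData(EBImage::bwlabel(mask * 1))
  storage.mode(lab) <- "integer"
  nlab <- max(lab)
  if (connectivity == 4L || nlab < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- NULL
  # diagonal adjacencies down-right and down-left
  a <- lab[-nr, -nc]; b <- lab[-1L, -1L]
  sel <- a > 0L & b > 0L & a != b
  if (any(sel)) pairs <- cbind(a[sel], b[sel])
  a <- lab[-nr, -1L]; b <- lab[-1L, -nc]
  sel <- a > 0L & b > 0L & a != b
  if (any(sel)) pairs <- rbind(pairs, cbind(a[sel], b[sel]))
  if (is.null(pairs)) return(lab)
  parent <- seq_len(nlab)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs[i, 1L]); rb <- find(pairs[i, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(root, sort(unique(root)))
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  lab
}

# boundary ring of a region: offset loops for small regions, EBImage
# dilation on the bounding-box crop for large ones
region_ring <- function(idx, dim, w = 2L) {
  if (length(idx) <= 500L) return(ring_pixels(idx, dim, w))
  rc <- idx_to_rc(idx, dim)
  r0 <- max(1L, min(rc[, 1L]) - w); r1 <- min(dim[1L], max(rc[, 1L]) + w)
  c0 <- max(1L, min(rc[, 2L]) - w); c1 <- min(dim[2L], max(rc[, 2L]) + w)
  sub <- matrix(0, r1 - r0 + 1L, c1 - c0 + 1L)
  sub[cbind(rc[, 1L] - r0 + 1L, rc[, 2L] - c0 + 1L)] <- 1
  dil <- EBImage::imageData(EBImage::dilate(sub, EBImage::makeBrush(2L * w + 1L, "box")))
  ringsub <- which(dil > 0 & sub == 0)
  rr <- ((ringsub - 1L) %% nrow(sub)) + r0
  cc <- ((ringsub - 1L) %/% nrow(sub)) + c0
  rc_to_idx(rr, cc, dim)
}

# pixel indices within Chebyshev distance `w` of `idx`, outside `idx`,
# inside the image: the boundary ring used by the significance score
ring_pixels <- function(idx, dim, w = 2L) {
  rc <- idx_to_rc(idx, dim)
  out <- idx
  for (dr in -w:w) for (dc in -w:w) {
    if (dr == 0L && dc == 0L) next
    r <- rc[, 1L] + dr; c <- rc[, 2L] + dc
    ok <- r >= 1L & r <= dim[1L] & c >= 1L & c <= dim[2L]
    if (any(ok)) out <- c(out, rc_to_idx(r[ok], c[ok], dim))
  }
  setdiff(unique(out), idx)
}

# dilate a set of pixel indices by `w` (Chebyshev), clipped to the image
dilate_idx <- function(idx, dim, w = 1L) {
  rc <- idx_to_rc(idx, dim)
  out <- idx
  for (dr in -w:w) for (dc in -w:w) {
    if (dr == 0L && dc == 0L) next
    r <- rc[, 1L] + dr; c <- rc[, 2L] + dc
    ok <- r >= 1L & r <= dim[1L] & c >= 1L & c <= dim[2L]
    if (any(ok)) out <- c(out, rc_to_idx(r[ok], c[ok], dim))
  }
  unique(out)
}

# 0-based centroid of a pixel set
centroid_rc0 <- function(idx, dim) {
  rc <- idx_to_rc(idx, dim)
  c(row = mean(rc[, 1L]) - 1, col = mean(rc[, 2L]) - 1)
}
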