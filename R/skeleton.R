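# shift a matrix by (dr, dc), padding with `fill`
shift_mat <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

NB8 <- cbind(dr = c(-1, -1, 0, 1, 1, 1, 0, -1),
             dc = c(0, 1, 1, 1, 0, -1, -1, -1))

# Zhang-Suen topology-preserving thinning of a logical matrix
thin_mask <- function(mask) {
  p <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  # neighbour order P2..P9 clockwise from north
  get_nb <- function(p) list(
    n  = shift_mat(p,  1L,  0L), ne = shift_mat(p,  1L, -1L),
    e  = shift_mat(p,  0L, -1L), se = shift_mat(p, -1L, -1L),
    s  = shift_mat(p, -1L,  0L), sw = shift_mat(p, -1L,  1L),
    w  = shift_mat(p,  0L,  1L), nw = shift_mat(p,  1L,  1L))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- get_nb(p)
      seq8 <- list(nb$n, nb$ne, nb$e, nb$se, nb$s, nb$sw, nb$w, nb$nw)
      B <- Reduce(`+`, seq8)
      A <- matrix(0L, nrow(p), ncol(p))
      for (i in 1:8) {
        j <- if (i == 8L) 1L else i + 1L
        A <- A + (seq8[[i]] == 0L & seq8[[j]] == 1L)
      }
      if (step == 1L) {
        cond <- (nb$n * nb$e * nb$s == 0L) & (nb$e * nb$s * nb$w == 0L)
      } else {
        cond <- (nb$n * nb$e * nb$w == 0L) & (nb$n * nb$s * nb$w == 0L)
      }
      del <- p == 1L & B >= 2L & B <= 6L & A == 1L & cond
      if (any(del)) { p[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  remove_simple_excess(p == 1L)
}

# sequential removal of redundant skeleton pixels: parallel-run Zhang-Suen
# leaves 2-px-wide diagonal runs whose pixels are 8-simple; deleting a
# pixel whose foreground neighbours stay 8-connected without it (and
# which is neither an endpoint nor an interior pixel) thins these to a
# true 1-px line while preserving topology
remove_simple_excess <- function(sk) {
  d <- dim(sk)
  nb_of <- function(r, c) {
    rr <- r + NB8[, 1L]; cc <- c + NB8[, 2L]
    ok <- rr >= 1L & rr <= d[1L] & cc >= 1L & cc <= d[2L]
    cbind(rr[ok], cc[ok])
  }
  queue <- which(sk)
  while (length(queue) > 0L) {
    queue <- sort(unique(queue))
    requeue <- integer(0)
    for (idx in queue) {
      if (!sk[idx]) next
      r <- ((idx - 1L) %% d[1L]) + 1L; c <- ((idx - 1L) %/% d[1L]) + 1L
      nb <- nb_of(r, c)
      fg <- nb[sk[nb[, 1L] + (nb[, 2L] - 1L) * d[1L]], , drop = FALSE]
      B <- nrow(fg)
      if (B < 2L || B > 6L) next
      # interior pixels (all four orthogonal neighbours set) are kept
      if (r > 1L && r < d[1L] && c > 1L && c < d[2L] &&
          sk[r - 1L, c] && sk[r + 1L, c] && sk[r, c - 1L] && sk[r, c + 1L]) next
      # foreground neighbours must form one 8-connected set without p
      comp <- seq_len(B)
      for (i in seq_len(B)) for (j in seq_len(B)) {
        if (i < j && max(abs(fg[i, ] - fg[j, ])) <= 1L) {
          ci <- comp[i]; cj <- comp[j]
          if (ci != cj) comp[comp == max(ci, cj)] <- min(ci, cj)
        }
      }
      if (length(unique(comp)) != 1L) next
      sk[idx] <- FALSE
      requeue <- c(requeue, fg[, 1L] + (fg[, 2L] - 1L) * d[1L])
    }
    queue <- requeue
  }
  sk
}

# number of 8-neighbours each TRUE pixel has within the mask
degree8 <- function(skmat) {
  deg <- matrix(0L, nrow(skmat), ncol(skmat))
  for (i in seq_len(nrow(NB8)))
    deg <- deg + shift_mat(matrix(as.integer(skmat), nrow(skmat)),
                           NB8[i, 1L], NB8[i, 2L])
  deg[!skmat] <- 0L
  deg
}

# coerce various mask representations to a logical matrix
as_mask_matrix <- function(mask, cell_id = 1L, dim_img = NULL) {
  if (inherits(mask, "astro_cells")) {
    d <- attr(mask, "dim_img")
    m <- matrix(FALSE, d[1L], d[2L])
    m[mask$pixels[[cell_id]]] <- TRUE
    return(m)
  }
  if (is.list(mask) && !is.null(mask$pixels) && !is.null(mask$dim)) {
    m <- matrix(FALSE, mask$dim[1L], mask$dim[2L])
    m[mask$pixels] <- TRUE
    return(m)
  }
  if (is.matrix(mask)) return(mask > 0)
  if (is.numeric(mask) && !is.null(dim_img)) {
    m <- matrix(FALSE, dim_img[1L], dim_img[2L])
    m[mask] <- TRUE
    return(m)
  }
  abort("cannot interpret `mask`")
}

#' Medial-axis skeleton of a cell mask with local widths
#'
#' Thins a connected binary mask to a topology-preserving medial-axis
#' skeleton (Zhang-Suen thinning) and attaches to every skeleton pixel
#' its local full width, `2 * d - 1` pixels where `d` is the Euclidean
#' distance-transform value (distance to the nearest background pixel
#' centre; the mask boundary lies half a pixel closer, hence the `- 1`).
#'
#' @param mask A logical/0-1 matrix, an `astro_cells` tibble (with
#'   `cell_id` choosing the row) or pixel indices plus `dim_img`.
#' @param cell_id Row of an `astro_cells` input to skeletonize.
#' @param dim_img Image dimensions when `mask` is given as pixel indices.
#' @return An object of class `astro_skeleton`: list with `idx` (linear
#'   indices of skeleton pixels), `width` (per-pixel full width, px),
#'   `dim`, `mask_idx` and the distance-transform matrix `dt`.
#' @export
skeletonize_mask <- function(mask, cell_id = 1L, dim_img = NULL) {
  m <- as_mask_matrix(mask, cell_id, dim_img)
  if (sum(m) < 9L) abort("mask too small")
  if (max(label_components(m, 8L)) != 1L) abort("mask must be connected")
  dt <- EBImage::imageData(EBImage::distmap(m * 1))
  sk <- thin_mask(m)
  idx <- which(sk)
  structure(list(idx = idx, width = pmax(2 * dt[idx] - 1, 1), dim = dim(m),
                 mask_idx = which(m), dt = dt),
            class = "astro_skeleton")
}

#' @export
print.astro_skeleton <- function(x, ...) {
  cat(sprintf("<astro_skeleton> %d skeleton px over a %d-px mask (%dx%d)\n",
              length(x$idx), length(x$mask_idx), x$dim[1], x$dim[2]))
  invisible(x)
}

# ordered trace of a simple-path pixel component; returns pixel indices
trace_path <- function(comp_idx, dim) {
  if (length(comp_idx) <= 1L) return(comp_idx)
  rc <- idx_to_rc(comp_idx, dim)
  key <- new.env(hash = TRUE, size = length(comp_idx))
  for (i in seq_along(comp_idx)) assign(as.character(comp_idx[i]), i, envir = key)
  nbrs <- function(i) {
    r <- rc[i, 1L]; c <- rc[i, 2L]
    out <- integer(0)
    for (k in seq_len(nrow(NB8))) {
      rr <- r + NB8[k, 1L]; cc <- c + NB8[k, 2L]
      if (rr < 1L || rr > dim[1L] || cc < 1L || cc > dim[2L]) next
      id <- (cc - 1L) * dim[1L] + rr
      j <- mget(as.character(id), envir = key, ifnotfound = list(NULL))[[1L]]
      if (!is.null(j)) out <- c(out, j)
    }
    out
  }
  deg <- vapply(seq_along(comp_idx), function(i) length(nbrs(i)), integer(1))
  ends <- which(deg <= 1L)
  start <- if (length(ends) > 0L) ends[which.min(comp_idx[ends])] else which.min(comp_idx)
  visited <- logical(length(comp_idx))
  path <- integer(length(comp_idx)); np <- 0L
  cur <- start
  repeat {
    visited[cur] <- TRUE; np <- np + 1L; path[np] <- cur
    nxt <- nbrs(cur); nxt <- nxt[!visited[nxt]]
    if (length(nxt) == 0L) break
    cur <- nxt[which.min(comp_idx[nxt])]
  }
  ordered <- comp_idx[path[seq_len(np)]]
  c(ordered, setdiff(comp_idx, ordered))   # stragglers (thinning clumps) appended
}

# core branch-graph construction (no pruning); `extra_jn` marks pixels
# forced to junction status (absorbed inter-junction stubs)
branch_graph_once <- function(skmat, skel, extra_jn = NULL) {
  dim <- skel$dim
  deg <- degree8(skmat)
  jn <- skmat & deg >= 3L
  if (!is.null(extra_jn)) jn <- jn | (skmat & extra_jn)
  jl <- label_components(jn, 8L)
  n_junction <- max(jl)
  interior <- skmat & !jn
  il <- label_components(interior, 8L)
  n_int <- max(il)
  widths <- matrix(0, dim[1L], dim[2L])
  widths[skel$idx] <- skel$width

  # junction cluster adjacent to a pixel (0 if none)
  adj_junction <- function(idx) {
    rc <- idx_to_rc(idx, dim)
    for (k in seq_len(nrow(NB8))) {
      rr <- rc[1L] + NB8[k, 1L]; cc <- rc[2L] + NB8[k, 2L]
      if (rr < 1L || rr > dim[1L] || cc < 1L || cc > dim[2L]) next
      if (jl[rr, cc] > 0L) return(jl[rr, cc])
    }
    0L
  }

  branches <- list()
  if (n_int > 0L) {
    comps <- split(which(il > 0L), il[il > 0L])
    for (b in seq_along(comps)) {
      px <- trace_path(comps[[b]], dim)
      ja <- adj_junction(px[1L])
      jb <- adj_junction(px[length(px)])
      branches[[b]] <- tibble(
        branch_id = b,
        node_a = if (ja > 0L) ja else NA_integer_,
        node_b = if (jb > 0L) jb else NA_integer_,
        length_px = length(px),
        mean_width_px = mean(widths[px]),
        is_leaf = is.na(if (ja > 0L) ja else NA_integer_) ||
                  is.na(if (jb > 0L) jb else NA_integer_),
        pixels = list(px))
    }
  }
  br <- if (length(branches)) bind_rows(branches) else
    tibble(branch_id = integer(0), node_a = integer(0), node_b = integer(0),
           length_px = integer(0), mean_width_px = numeric(0),
           is_leaf = logical(0), pixels = list())
  nodes <- if (n_junction > 0L) {
    purrr::map_dfr(seq_len(n_junction), function(j) {
      px <- which(jl == j)
      ce <- centroid_rc0(px, dim)
      tibble(node_id = j, kind = "junction", n_px = length(px),
             centroid_row = ce[1L], centroid_col = ce[2L], pixels = list(px))
    })
  } else tibble(node_id = integer(0), kind = character(0), n_px = integer(0),
                centroid_row = numeric(0), centroid_col = numeric(0), pixels = list())
  list(branches = br, nodes = nodes, jl = jl)
}

#' Decompose a skeleton into a branch graph
#'
#' Splits the skeleton at branchpoints (pixels with 8-connected degree at
#' least 3; adjacent junction pixels are merged into one node) into
#' simple branches, each carrying its ordered pixel path, length and mean
#' local width.  Leaf branches end at an endpoint (degree-1 pixel).
#' Spurious leaf branches shorter than `prune_spurs` pixels, a by-product
#' of thinning, are pruned and the graph rebuilt once.
#'
#' @param skel An `astro_skeleton` (see [skeletonize_mask()]).
#' @param prune_spurs Prune leaf branches shorter than this many pixels
#'   (default 3; 0 disables).  With `width_adaptive = TRUE` (default)
#'   the pruning length at each junction is raised to the local skeleton
#'   width there, since thinning a ribbon of width `w` leaves spurious
#'   side spurs up to about `w` pixels long at junctions and rounded
#'   caps; genuine branches are much longer than their parent's width.
#' @param width_adaptive Raise the spur threshold to the junction width.
#' @param max_prune_iter Pruning/rebuild iterations (default 5).
#' @param trim_intensity Optional intensity matrix (the channel the mask
#'   was detected in).  Leaf-branch ends are trimmed of consecutive
#'   pixels whose intensity falls below `trim_threshold`: under noise
#'   the detected mask sprouts short low-intensity extensions past the
#'   true process tip, and the skeleton follows them.  With clean input
#'   every skeleton pixel clears the threshold and nothing is trimmed.
#' @param trim_threshold Intensity floor for tip support; default
#'   half-way between the mask and background medians of
#'   `trim_intensity`.
#' @return An object of class `astro_branchgraph`: list with a `branches`
#'   tibble (`branch_id`, `node_a`, `node_b`, `length_px`,
#'   `mean_width_px`, `is_leaf`, `pixels`), a junction `nodes` tibble,
#'   `n_endpoints`, and the `skeleton`.
#' @export
build_branch_graph <- function(skel, prune_spurs = 3L, width_adaptive = TRUE,
                               max_prune_iter = 5L, trim_intensity = NULL,
                               trim_threshold = NULL) {
  stopifnot(inherits(skel, "astro_skeleton"))
  if (length(skel$idx) == 0L) abort("skeleton is empty")
  skmat <- matrix(FALSE, skel$dim[1L], skel$dim[2L])
  skmat[skel$idx] <- TRUE
  if (!is.null(trim_intensity) && is.null(trim_threshold)) {
    inside <- trim_intensity[skel$mask_idx]
    outside <- trim_intensity[-skel$mask_idx]
    trim_threshold <- if (length(outside) > 0L)
      (median(inside) + median(outside)) / 2 else -Inf
  }
  widths <- matrix(0, skel$dim[1L], skel$dim[2L])
  widths[skel$idx] <- skel$width
  iter <- 0L
  extra_jn <- matrix(FALSE, skel$dim[1L], skel$dim[2L])
  repeat {
    bg <- branch_graph_once(skmat, skel, extra_jn)
    iter <- iter + 1L
    if (prune_spurs <= 0L || nrow(bg$branches) <= 1L || iter > max_prune_iter) break
    br <- bg$branches
    thr <- rep(as.numeric(prune_spurs), nrow(br))
    if (width_adaptive && nrow(bg$nodes) > 0L) {
      node_w <- vapply(bg$nodes$pixels, function(px) mean(widths[px]), numeric(1))
      for (i in seq_len(nrow(br))) {
        ns <- c(br$node_a[i], br$node_b[i]); ns <- ns[!is.na(ns)]
        if (length(ns) > 0L) thr[i] <- max(thr[i], max(node_w[ns]))
      }
    }
    # leaf spurs: thinning artifacts at junctions and rounded caps
    spur <- br$is_leaf & br$length_px < thr &
      !(is.na(br$node_a) & is.na(br$node_b))
    # short junction-to-junction stubs: one true branchpoint split in two
    # by thinning; absorb the stub into the junction node.  The width
    # guard keeps a thin branch segment pinched between two wide
    # junctions from being swallowed (only blob-like stubs of comparable
    # width belong to the branchpoint itself)
    node_w_max <- if (nrow(bg$nodes) > 0L) {
      nw <- vapply(bg$nodes$pixels, function(px) mean(widths[px]), numeric(1))
      vapply(seq_len(nrow(br)), function(i) {
        ns <- c(br$node_a[i], br$node_b[i]); ns <- ns[!is.na(ns)]
        if (length(ns) == 0L) 0 else max(nw[ns])
      }, numeric(1))
    } else rep(0, nrow(br))
    stub <- !br$is_leaf & !is.na(br$node_a) & !is.na(br$node_b) &
      br$length_px < pmin(thr, 5) & br$mean_width_px >= 0.5 * node_w_max
    # unsupported leaf-tip pixels: consecutive sub-threshold pixels at a
    # free branch end are noise growth beyond the true tip
    trimmed <- FALSE
    if (!is.null(trim_intensity)) {
      for (i in which(br$is_leaf)) {
        px <- br$pixels[[i]]
        ordered <- if (is.na(br$node_b[i])) rev(px) else px   # free end first
        bad <- cumprod(trim_intensity[ordered] < trim_threshold) > 0
        if (any(bad) && sum(bad) < length(px)) {
          skmat[ordered[bad]] <- FALSE
          trimmed <- TRUE
        }
      }
    }
    if (!any(spur) && !any(stub) && !trimmed) break
    if (any(spur)) skmat[unlist(br$pixels[spur])] <- FALSE
    if (any(stub)) extra_jn[unlist(br$pixels[stub])] <- TRUE
  }
  n_end <- sum(is.na(bg$branches$node_a)) + sum(is.na(bg$branches$node_b))
  structure(list(branches = bg$branches, nodes = bg$nodes,
                 n_endpoints = n_end, skeleton = skel),
            class = "astro_branchgraph")
}

#' @export
print.astro_branchgraph <- function(x, ...) {
  cat(sprintf("<astro_branchgraph> %d branches, %d junctions, %d endpoints\n",
              nrow(x$branches), nrow(x$nodes), x$n_endpoints))
  invisible(x)
}
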