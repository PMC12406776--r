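# multi-source geodesic label propagation over a mask (8-connected BFS;
# equidistant ties resolved toward the lower label)
geodesic_territory <- function(maskm, seed_lab) {
  lab <- seed_lab
  lab[!maskm] <- 0L
  repeat {
    cand <- maskm & lab == 0L
    if (!any(cand)) break
    best <- matrix(Inf, nrow(lab), ncol(lab))
    for (k in seq_len(nrow(NB8))) {
      sh <- shift_mat(lab, NB8[k, 1L], NB8[k, 2L])
      pos <- sh > 0L
      best[pos] <- pmin(best[pos], sh[pos])
    }
    newly <- cand & is.finite(best)
    if (!any(newly)) break              # unreachable pocket; leave 0
    lab[newly] <- as.integer(best[newly])
  }
  lab
}

# split skeleton branches at the soma region: each maximal run of pixels
# outside the soma becomes its own branch (ends cut at the soma are
# flagged and are never treated as free tips); in-soma pixels are handed
# to `absorb`
split_at_soma <- function(br, in_soma, absorb) {
  if (nrow(br) == 0L) {
    br$cut_a <- logical(0); br$cut_b <- logical(0)
    return(br)
  }
  out <- list()
  for (b in seq_len(nrow(br))) {
    px <- br$pixels[[b]]
    inside <- in_soma[px]
    if (!any(inside)) {
      row <- br[b, ]; row$cut_a <- FALSE; row$cut_b <- FALSE
      out[[length(out) + 1L]] <- row
      next
    }
    if (all(inside)) { absorb(px); next }
    absorb(px[inside])
    r <- rle(!inside)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    for (k in runs) {
      rpx <- px[starts[k]:ends[k]]
      row <- br[b, ]
      row$pixels <- list(rpx)
      row$length_px <- length(rpx)
      row$cut_a <- starts[k] != 1L
      row$cut_b <- ends[k] != length(px)
      if (row$cut_a) row$node_a <- NA_integer_
      if (row$cut_b) row$node_b <- NA_integer_
      row$is_leaf <- (is.na(row$node_a) & !row$cut_a) | (is.na(row$node_b) & !row$cut_b)
      out[[length(out) + 1L]] <- row
    }
  }
  res <- bind_rows(out)
  if (nrow(res) > 0L) res$branch_id <- seq_len(nrow(res))
  res
}

#' Classify branches into the four hierarchy types
#'
#' Applies a deterministic rule table to a branch graph:
#' the soma is the connected set of mask pixels whose distance-transform
#' value is at least `theta_soma` times the maximum (containing the
#' global maximum); branches incident to the soma (directly or through a
#' junction node touching it) whose mean width (measured outside the
#' soma) is at least `theta_primary` times the soma width are
#' `SOMA_PRIMARY`; the distal `L_tip` pixels of every other leaf branch
#' form a `TERMINAL` tip segment; remaining segments are `FINE` when
#' their mean width is strictly below `theta_fine` px, otherwise
#' `SECONDARY`.  Branches lying entirely inside the soma are absorbed
#' into it.  Every mask pixel is then assigned to its geodesically
#' nearest typed segment (ties toward the lower segment id), giving the
#' territory map used to bin mitochondria.
#'
#' @param bg An `astro_branchgraph` (see [build_branch_graph()]).
#' @param theta_soma Soma threshold as a fraction of the maximum
#'   distance-transform value (default 0.6).
#' @param theta_primary Primary-branch width threshold as a fraction of
#'   the soma width (default 0.35).
#' @param theta_fine Maximum mean width of a fine branch, px (default 3).
#' @param L_tip Length of the terminal tip segment of leaf branches, px
#'   (default 5).
#' @return An object of class `astro_arbor`: list with a `segments`
#'   tibble (`segment_id`, `branch_id`, `type`, `length_px`,
#'   `mean_width_px`, `pixels`; segment 1 is the soma body), the integer
#'   `territory` matrix (0 outside the cell), `soma_idx`, `soma_width_px`
#'   and the parameters used.
#' @export
classify_branches <- function(bg, theta_soma = 0.6, theta_primary = 0.35,
                              theta_fine = 3, L_tip = 5L) {
  stopifnot(inherits(bg, "astro_branchgraph"))
  skel <- bg$skeleton
  d <- skel$dim
  dt <- skel$dt
  maskm <- matrix(FALSE, d[1L], d[2L])
  maskm[skel$mask_idx] <- TRUE

  maxdt <- max(dt)
  soma_cand <- dt >= theta_soma * maxdt
  sl <- label_components(soma_cand, 8L)
  soma_idx <- which(sl == sl[which.max(dt)])
  in_soma <- matrix(FALSE, d[1L], d[2L]); in_soma[soma_idx] <- TRUE
  near_soma <- matrix(FALSE, d[1L], d[2L])
  near_soma[dilate_idx(soma_idx, d, 2L)] <- TRUE

  sk_in_soma <- skel$idx[in_soma[skel$idx]]
  soma_width <- if (length(sk_in_soma) > 0L) {
    mean(2 * dt[sk_in_soma] - 1)
  } else 2 * maxdt - 1

  widths <- matrix(0, d[1L], d[2L]); widths[skel$idx] <- skel$width
  br <- bg$branches
  soma_extra <- integer(0)                 # absorbed-branch pixels
  segs <- list(tibble(segment_id = 1L, branch_id = NA_integer_,
                      type = "SOMA_PRIMARY", length_px = NA_integer_,
                      mean_width_px = soma_width, pixels = list(soma_idx),
                      role = "soma", node_a = NA_integer_, node_b = NA_integer_))
  soma_centroid <- centroid_rc0(soma_idx, d) + 1  # 1-based for distances
  sid <- 1L
  # split branches running through the soma into their outside runs, so
  # a skeleton arc joining two primaries across the soma counts as two
  br <- split_at_soma(br, in_soma, function(px) { soma_extra <<- c(soma_extra, px) })
  if (nrow(br) > 0L)
    br$mean_width_px <- vapply(br$pixels, function(px) mean(widths[px]), numeric(1))

  # junction nodes touching the soma extend primary-branch incidence
  node_touches_soma <- if (nrow(bg$nodes) > 0L)
    vapply(bg$nodes$pixels, function(px) any(near_soma[px]), logical(1)) else logical(0)
  if (nrow(br) > 0L) for (b in seq_len(nrow(br))) {
    px <- br$pixels[[b]]
    inside <- in_soma[px]
    if (all(inside)) { soma_extra <- c(soma_extra, px); next }
    ns <- c(br$node_a[b], br$node_b[b]); ns <- ns[!is.na(ns)]
    incident <- any(near_soma[px]) ||
      (length(ns) > 0L && any(node_touches_soma[ns]))
    mw_out <- mean(widths[px[!inside]])
    if (incident && mw_out >= theta_primary * soma_width) {
      sid <- sid + 1L
      segs[[length(segs) + 1L]] <- tibble(
        segment_id = sid, branch_id = br$branch_id[b], type = "SOMA_PRIMARY",
        length_px = br$length_px[b], mean_width_px = br$mean_width_px[b],
        pixels = list(px), role = "primary",
        node_a = br$node_a[b], node_b = br$node_b[b])
      next
    }
    if (br$is_leaf[b]) {
      # distal (free) end: the NA-node side; if both free, farther from soma
      free_start <- is.na(br$node_a[b]) && !br$cut_a[b]
      free_end <- is.na(br$node_b[b]) && !br$cut_b[b]
      if (!free_start && !free_end) free_end <- TRUE
      tip_at_end <- if (free_start && free_end) {
        rc1 <- idx_to_rc(px[1L], d); rc2 <- idx_to_rc(px[length(px)], d)
        sum((rc2 - soma_centroid)^2) >= sum((rc1 - soma_centroid)^2)
      } else free_end
      nt <- min(L_tip, length(px))
      tip_px <- if (tip_at_end) tail(px, nt) else head(px, nt)
      rest_px <- if (tip_at_end) head(px, length(px) - nt) else tail(px, length(px) - nt)
      if (length(rest_px) > 0L) {
        mw_rest <- mean(widths[rest_px])
        sid <- sid + 1L
        segs[[length(segs) + 1L]] <- tibble(
          segment_id = sid, branch_id = br$branch_id[b],
          type = if (mw_rest < theta_fine) "FINE" else "SECONDARY",
          length_px = length(rest_px), mean_width_px = mw_rest,
          pixels = list(rest_px), role = "branch",
          node_a = br$node_a[b], node_b = br$node_b[b])
      }
      sid <- sid + 1L
      segs[[length(segs) + 1L]] <- tibble(
        segment_id = sid, branch_id = br$branch_id[b], type = "TERMINAL",
        length_px = length(tip_px), mean_width_px = mean(widths[tip_px]),
        pixels = list(tip_px), role = "tip",
        node_a = NA_integer_, node_b = NA_integer_)
    } else {
      sid <- sid + 1L
      segs[[length(segs) + 1L]] <- tibble(
        segment_id = sid, branch_id = br$branch_id[b],
        type = if (br$mean_width_px[b] < theta_fine) "FINE" else "SECONDARY",
        length_px = br$length_px[b], mean_width_px = br$mean_width_px[b],
        pixels = list(px), role = "branch",
        node_a = br$node_a[b], node_b = br$node_b[b])
    }
  }
  segments <- bind_rows(segs)

  # propagate primary status outward: a wide segment sharing a junction
  # node with a primary is part of the same thick process (it is typed
  # SOMA_PRIMARY but not counted as an extra primary branch)
  if (nrow(bg$nodes) > 0L) {
    seg_nodes <- lapply(seq_len(nrow(segments)), function(i) {
      ns <- c(segments$node_a[i], segments$node_b[i]); ns[!is.na(ns)]
    })
    repeat {
      prim_nodes <- unique(unlist(seg_nodes[segments$type == "SOMA_PRIMARY"]))
      cand <- which(segments$type == "SECONDARY" &
                    segments$mean_width_px >= theta_primary * soma_width &
                    vapply(seg_nodes, function(ns) any(ns %in% prim_nodes), logical(1)))
      if (length(cand) == 0L) break
      segments$type[cand] <- "SOMA_PRIMARY"
      segments$role[cand] <- "primary_ext"
    }
  }

  # territory: branch skeleton seeds; junction-cluster pixels take the
  # widest adjacent segment (a branchpoint belongs to its thickest
  # process); the soma overwrites inside its region
  seed <- matrix(0L, d[1L], d[2L])
  for (s in seq_len(nrow(segments)))
    seed[segments$pixels[[s]]] <- segments$segment_id[s]
  if (nrow(bg$nodes) > 0L) {
    for (j in seq_len(nrow(bg$nodes))) {
      npx <- bg$nodes$pixels[[j]]
      nb <- dilate_idx(npx, d, 1L)
      labs <- unique(seed[nb]); labs <- labs[labs > 0L]
      if (length(labs) == 0L) next
      wsel <- segments$mean_width_px[match(labs, segments$segment_id)]
      seed[npx] <- labs[order(-wsel, labs)][1L]
    }
  }
  seed[soma_idx] <- 1L
  if (length(soma_extra) > 0L) seed[soma_extra] <- 1L
  territory <- geodesic_territory(maskm, seed)

  structure(list(segments = segments, territory = territory,
                 soma_nodes = which(node_touches_soma),
                 soma_idx = soma_idx, soma_width_px = soma_width,
                 dim = d, mask_idx = skel$mask_idx,
                 params = list(theta_soma = theta_soma,
                               theta_primary = theta_primary,
                               theta_fine = theta_fine, L_tip = L_tip)),
            class = "astro_arbor")
}

#' @export
print.astro_arbor <- function(x, ...) {
  cs <- branch_counts(x)
  cat("<astro_arbor>\n")
  print(as_tibble(cs))
  invisible(x)
}

#' Branch counts per hierarchy type
#'
#' Counts branches per type: `SOMA_PRIMARY` is the soma itself plus the
#' primary branches, `TERMINAL` counts tip segments, `SECONDARY` and
#' `FINE` count branch segments of those types.
#'
#' @param arbor An `astro_arbor` (see [classify_branches()]).
#' @return A tibble with columns `type` and `branch_count`, one row per
#'   branch type in hierarchy order.
#' @export
branch_counts <- function(arbor) {
  stopifnot(inherits(arbor, "astro_arbor"))
  s <- arbor$segments
  # a primary process may be split into several segments by junctions
  # along its course; segments of type SOMA_PRIMARY connected through a
  # shared junction node are one primary branch
  prim <- which(s$role %in% c("primary", "primary_ext"))
  n_primary <- 0L
  if (length(prim) > 0L) {
    parent <- seq_along(prim)
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    for (i in seq_along(prim)) for (j in seq_len(i - 1L)) {
      ni <- c(s$node_a[prim[i]], s$node_b[prim[i]])
      nj <- c(s$node_a[prim[j]], s$node_b[prim[j]])
      ni <- setdiff(ni[!is.na(ni)], arbor$soma_nodes)
      nj <- setdiff(nj[!is.na(nj)], arbor$soma_nodes)
      if (length(intersect(ni, nj)) > 0L) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
    n_primary <- length(unique(vapply(seq_along(prim), find, integer(1))))
  }
  n <- c(
    SOMA_PRIMARY = 1L + n_primary,
    SECONDARY = sum(s$type == "SECONDARY"),
    FINE = sum(s$type == "FINE"),
    TERMINAL = sum(s$type == "TERMINAL")
  )
  tibble(type = factor(BRANCH_TYPES, levels = BRANCH_TYPES),
         branch_count = as.integer(n[BRANCH_TYPES]))
}
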