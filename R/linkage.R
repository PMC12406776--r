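#' Brightest (maximum-bottleneck) path between two fragments
#'
#' Finds an 8-connected pixel path from one fragment to another that
#' maximises the minimum intensity along the path (endpoints included).
#' Among bottleneck-optimal routes, a deterministic tie-break prefers the
#' path with the least total darkness (sum of `max intensity - I(p)`),
#' which favours bright and short, then shorter length, then lower pixel
#' index.  The edge weight reported for fragment linkage is the mean
#' intensity over all path pixels, including the two terminal pixels.
#'
#' @param img Numeric intensity matrix.
#' @param pixels_a,pixels_b Linear pixel indices of the two (disjoint)
#'   fragments.
#' @param envelope Search envelope: the joint bounding box of the two
#'   fragments inflated by this many pixels (default 50); use `Inf` to
#'   search the whole image.
#' @return A list with `path` (linear pixel indices from a to b; empty if
#'   unreachable), `weight` (mean intensity over path pixels; 0 if
#'   unreachable) and `bottleneck` (minimum intensity along the path).
#' @export
brightest_path <- function(img, pixels_a, pixels_b, envelope = 50L) {
  img <- check_image(img)
  if (length(pixels_a) == 0L || length(pixels_b) == 0L)
    abort("fragments must be non-empty")
  if (length(intersect(pixels_a, pixels_b)) > 0L)
    abort("fragments must be disjoint")
  d <- dim(img)
  allowed <- rep(TRUE, length(img))
  if (is.finite(envelope)) {
    rc <- idx_to_rc(c(pixels_a, pixels_b), d)
    r0 <- max(1L, min(rc[, 1L]) - envelope); r1 <- min(d[1L], max(rc[, 1L]) + envelope)
    c0 <- max(1L, min(rc[, 2L]) - envelope); c1 <- min(d[2L], max(rc[, 2L]) + envelope)
    allowed <- matrix(FALSE, d[1L], d[2L])
    allowed[r0:r1, c0:c1] <- TRUE
    allowed <- as.vector(allowed)
  }
  res <- cpp_brightest_path(img, as.integer(pixels_a) - 1L,
                            as.integer(pixels_b) - 1L, allowed)
  if (length(res$path) == 0L)
    return(list(path = integer(0), weight = 0, bottleneck = NA_real_))
  path <- res$path + 1L
  list(path = path, weight = mean(img[path]), bottleneck = res$bottleneck)
}

#' Fragment graph weighted by brightest-path intensity
#'
#' Builds the complete graph over detected fragments in which each edge
#' carries the brightest connecting path and its mean intensity.
#'
#' @param img Numeric intensity matrix the fragments were detected in.
#' @param fragments An `astro_fragments` tibble (see [detect_regions()]).
#' @param envelope Per-pair search envelope passed to [brightest_path()].
#' @return A tibble of class `astro_fragment_graph` with columns
#'   `frag_a`, `frag_b`, `weight`, `bottleneck` and a `path` list-column;
#'   attribute `node_ids` lists the fragment ids.
#' @export
build_fragment_graph <- function(img, fragments, envelope = 50L) {
  img <- check_image(img)
  n <- nrow(fragments)
  edges <- tibble(frag_a = integer(0), frag_b = integer(0),
                  weight = numeric(0), bottleneck = numeric(0), path = list())
  if (n >= 2L) {
    pr <- utils::combn(n, 2L)
    rows <- purrr::map(seq_len(ncol(pr)), function(j) {
      i <- pr[1L, j]; k <- pr[2L, j]
      bp <- brightest_path(img, fragments$pixels[[i]], fragments$pixels[[k]],
                           envelope = envelope)
      tibble(frag_a = fragments$id[i], frag_b = fragments$id[k],
             weight = bp$weight, bottleneck = bp$bottleneck, path = list(bp$path))
    })
    edges <- bind_rows(rows)
  }
  attr(edges, "node_ids") <- fragments$id
  class(edges) <- c("astro_fragment_graph", class(edges))
  edges
}

#' Optimal (maximum-weight) spanning-tree linkage of fragments
#'
#' Selects the spanning tree (spanning forest if the graph is
#' disconnected) that maximises total edge weight, i.e. the brightest
#' global linkage; equivalently the minimum spanning tree of the
#' brightness-inverted cost.  Kruskal's algorithm with edges ordered by
#' decreasing weight and ties broken toward lexicographically smaller
#' `(frag_a, frag_b)` pairs makes the result deterministic.
#'
#' @param graph An `astro_fragment_graph` tibble ([build_fragment_graph()]),
#'   or any tibble with `frag_a`, `frag_b`, `weight` columns.
#' @return The edge tibble with a logical `in_tree` column, of class
#'   `astro_linkage`; attributes `total_weight` (sum over tree edges) and
#'   `n_components`.
#' @export
link_fragments <- function(graph) {
  node_ids <- attr(graph, "node_ids") %||% unique(c(graph$frag_a, graph$frag_b))
  n <- length(node_ids)
  in_tree <- rep(FALSE, nrow(graph))
  if (nrow(graph) > 0L && n > 1L) {
    a <- pmin(graph$frag_a, graph$frag_b)
    b <- pmax(graph$frag_a, graph$frag_b)
    ord <- order(-graph$weight, a, b)
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    for (e in ord) {
      ia <- find(match(graph$frag_a[e], node_ids))
      ib <- find(match(graph$frag_b[e], node_ids))
      if (ia != ib) { parent[max(ia, ib)] <- min(ia, ib); in_tree[e] <- TRUE }
    }
  }
  out <- mutate(as_tibble(graph), in_tree = in_tree)
  attr(out, "node_ids") <- node_ids
  attr(out, "total_weight") <- sum(out$weight[out$in_tree])
  attr(out, "n_components") <- n - sum(in_tree)
  class(out) <- c("astro_linkage", class(out))
  out
}

#' Assemble cell masks from linked fragments
#'
#' Cuts linkage-tree edges weaker than `min_link_weight`; each remaining
#' connected component of fragments becomes one cell mask consisting of
#' the member fragments' pixels plus the 1-px linking-path corridors.
#'
#' @param img Numeric intensity matrix.
#' @param fragments An `astro_fragments` tibble.
#' @param tree An `astro_linkage` tibble ([link_fragments()]).
#' @param min_link_weight Minimum mean path intensity for a link to be
#'   kept; default half the mean fragment interior intensity.
#' @return A tibble of class `astro_cells`, one row per cell sorted by
#'   decreasing area: `cell_id`, `area_px`, `n_fragments`, `member_ids`
#'   and `pixels` list-columns; attribute `dim_img`.
#' @export
assemble_cells <- function(img, fragments, tree, min_link_weight = NULL) {
  img <- check_image(img)
  empty <- tibble(cell_id = integer(0), area_px = integer(0),
                  n_fragments = integer(0), member_ids = list(), pixels = list())
  attr(empty, "dim_img") <- dim(img)
  class(empty) <- c("astro_cells", class(empty))
  if (nrow(fragments) == 0L) return(empty)
  if (is.null(min_link_weight))
    min_link_weight <- 0.5 * mean(img[unlist(fragments$pixels)])
  kept <- tree[tree$in_tree & tree$weight >= min_link_weight, , drop = FALSE]

  ids <- fragments$id
  parent <- seq_along(ids)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (nrow(kept) > 0L) for (e in seq_len(nrow(kept))) {
    ia <- find(match(kept$frag_a[e], ids)); ib <- find(match(kept$frag_b[e], ids))
    if (ia != ib) parent[max(ia, ib)] <- min(ia, ib)
  }
  comp <- vapply(seq_along(ids), find, integer(1))
  groups <- split(seq_along(ids), comp)

  rows <- purrr::map(groups, function(members) {
    px <- unlist(fragments$pixels[members], use.names = FALSE)
    if (nrow(kept) > 0L) {
      sel <- match(kept$frag_a, ids) %in% members & match(kept$frag_b, ids) %in% members
      px <- c(px, unlist(kept$path[sel], use.names = FALSE))
    }
    px <- unique(px)
    tibble(area_px = length(px), n_fragments = length(members),
           member_ids = list(ids[members]), pixels = list(sort(px)))
  })
  out <- bind_rows(rows)
  out <- out[order(-out$area_px), , drop = FALSE]
  out <- mutate(out, cell_id = dplyr::row_number(), .before = 1L)
  attr(out, "dim_img") <- dim(img)
  class(out) <- c("astro_cells", class(out))
  out
}
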