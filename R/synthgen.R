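#' Specification of a synthetic astrocyte arbor
#'
#' Collects the geometric parameters of the synthetic arbor generator:
#' a wide soma disk with branches radiating outward over `n_levels`
#' hierarchy levels, branch width strictly decreasing with depth, and a
#' bounded random bend per step (tortuosity).  The defaults emulate a
#' cultured astrocyte at the scale the detection and hierarchy defaults
#' are tuned for: a 9-px-radius soma (18 px wide), primary branches 8 px
#' wide, secondary 4 px, fine 2 px, on a 512 x 512 16-bit canvas.
#'
#' @param canvas Image height and width in pixels.
#' @param soma_radius Soma disk radius, px.
#' @param n_levels Number of branch levels (1 = primaries only).
#' @param n_primary Range (min, max) of primary branches.
#' @param n_children Range of children per branch at each split.
#' @param lengths List of per-level length ranges, px.
#' @param widths Per-level branch widths, px; must strictly decrease.
#' @param tortuosity Maximum bend per step, degrees.
#' @param step Polyline step length, px.
#' @return A list of class `astro_arborspec`.
#' @export
arbor_spec <- function(canvas = c(512L, 512L), soma_radius = 9, n_levels = 3L,
                       n_primary = c(4L, 6L), n_children = c(2L, 3L),
                       lengths = list(c(45, 65), c(28, 40), c(16, 26)),
                       widths = c(8, 4, 2), tortuosity = 15, step = 3) {
  stopifnot(n_levels >= 1L, length(widths) >= n_levels,
            length(lengths) >= n_levels, soma_radius > 0,
            all(diff(widths) < 0), tortuosity >= 0, step > 0)
  structure(list(canvas = as.integer(canvas), soma_radius = soma_radius,
                 n_levels = as.integer(n_levels), n_primary = n_primary,
                 n_children = n_children, lengths = lengths, widths = widths,
                 tortuosity = tortuosity, step = step),
            class = "astro_arborspec")
}

# grow a polyline step by step, stopping just before it would collide
# with previously accepted centre-line points (half-widths respected) or
# leave the canvas; the start neighbourhood shared with the parent and
# siblings is exempt from the clearance test
grow_clear <- function(start, heading, len, tortuosity, step, hw,
                       avoid, avoid_hw, excl_radius, canvas, margin, gap = 2,
                       avoid_owner = NULL, exclude_owner = NA_integer_) {
  if (!is.null(avoid_owner) && !is.na(exclude_owner)) {
    keep <- avoid_owner != exclude_owner
    avoid <- avoid[keep, , drop = FALSE]
    avoid_hw <- avoid_hw[keep]
  }
  n <- max(2L, ceiling(len / step) + 1L)
  pts <- matrix(0, n, 2L)
  pts[1L, ] <- start
  h <- heading; np <- 1L
  for (i in 2L:n) {
    h <- h + runif(1, -tortuosity, tortuosity) * pi / 180
    p <- pts[np, ] + step * c(sin(h), cos(h))
    if (any(p < margin) || p[1L] > canvas[1L] - margin || p[2L] > canvas[2L] - margin)
      break
    if (nrow(avoid) > 0L &&
        sqrt(sum((p - start)^2)) > excl_radius) {
      dd <- sqrt((avoid[, 1L] - p[1L])^2 + (avoid[, 2L] - p[2L])^2)
      if (any(dd < avoid_hw + hw + gap)) break
    }
    np <- np + 1L
    pts[np, ] <- p
  }
  list(pts = pts[seq_len(np), , drop = FALSE], heading = h,
       achieved = (np - 1L) * step)
}

#' Generate a random astrocyte arbor with ground truth
#'
#' Builds a seeded, reproducible random branch tree rooted at a soma
#' disk.  Level-1 branches radiate from the soma at roughly even angles;
#' each branch of level `l < n_levels` spawns children at its distal end.
#' Intended branch types are recorded for validation: level 1 is
#' `SOMA_PRIMARY`, level 2 `SECONDARY`, deeper levels (or branches no
#' wider than 3 px) `FINE`; every leaf carries a `TERMINAL` tip
#' annotation when rendered.
#'
#' @param spec An [arbor_spec()].
#' @param seed Integer seed; identical seeds give identical arbors.
#' @return A list of class `astro_groundtruth` with the `spec`, the
#'   `soma` (centre, radius), a `branches` tibble (`branch_id`, `level`,
#'   `parent_id`, `width`, `intended_type`, `is_leaf`, `poly`
#'   list-column of (row, col) polylines) and an empty `mitos` slot.
#' @export
generate_arbor <- function(spec = arbor_spec(), seed = 1L) {
  stopifnot(inherits(spec, "astro_arborspec"))
  with_local_seed(seed, {
    center <- (spec$canvas + 1) / 2
    margin <- max(spec$widths) / 2 + 2
    rows <- list(); headings <- numeric(0)
    avoid <- matrix(0, 0, 2L); avoid_hw <- numeric(0); avoid_owner <- integer(0)
    accept <- function(pts, hw, owner) {
      avoid <<- rbind(avoid, pts)
      avoid_hw <<- c(avoid_hw, rep(hw, nrow(pts)))
      avoid_owner <<- c(avoid_owner, rep(owner, nrow(pts)))
    }
    n1 <- if (spec$n_primary[1L] == spec$n_primary[2L]) spec$n_primary[1L] else
      sample(spec$n_primary[1L]:spec$n_primary[2L], 1L)
    base <- runif(1, 0, 2 * pi)
    bid <- 0L
    for (j in seq_len(n1)) {
      hw <- spec$widths[1L] / 2
      ok <- FALSE; best <- NULL
      for (try in 1:40) {
        ang <- base + 2 * pi * (j - 1L) / n1 + runif(1, -0.4, 0.4) * pi / n1
        start <- center + (spec$soma_radius - 1) * c(sin(ang), cos(ang))
        len <- runif(1, spec$lengths[[1L]][1L], spec$lengths[[1L]][2L])
        gp <- grow_clear(start, ang, len, spec$tortuosity, spec$step, hw,
                         avoid, avoid_hw, spec$soma_radius + hw + 2,
                         spec$canvas, margin)
        if (is.null(best) || gp$achieved > best$achieved) best <- gp
        if (gp$achieved >= len - spec$step) { ok <- TRUE; break }
      }
      gp <- best
      if (!ok && gp$achieved < 0.5 * spec$lengths[[1L]][1L])
        abort("arbor exceeds canvas")
      bid <- bid + 1L
      rows[[bid]] <- tibble(branch_id = bid, level = 1L, parent_id = NA_integer_,
                            width = spec$widths[1L], poly = list(gp$pts))
      headings[bid] <- gp$heading
      accept(gp$pts, hw, bid)
    }
    if (spec$n_levels > 1L) for (lv in 2L:spec$n_levels) {
      parents <- which(vapply(rows, function(r) r$level, integer(1)) == lv - 1L)
      for (p in parents) {
        hw <- spec$widths[lv] / 2
        parent_hw <- rows[[p]]$width / 2
        start <- rows[[p]]$poly[[1L]][nrow(rows[[p]]$poly[[1L]]), ]
        # grow the whole sibling set together: siblings constrain one
        # another, so a failed child triggers a fresh draw of the set;
        # if the geometry stays infeasible the children are dropped (all,
        # or all but >= 2), leaving the parent a genuine leaf
        best_set <- list()
        for (attempt in 1:8) {
          nc <- if (spec$n_children[1L] == spec$n_children[2L]) spec$n_children[1L] else
            sample(spec$n_children[1L]:spec$n_children[2L], 1L)
          offs <- seq(-50, 50, length.out = nc) * pi / 180
          set <- list()
          trial_avoid <- avoid; trial_hw <- avoid_hw; trial_owner <- avoid_owner
          for (q in seq_len(nc)) {
            got <- NULL
            for (try in 1:15) {
              h0 <- headings[p] + offs[q] + runif(1, -8 - 2 * try, 8 + 2 * try) * pi / 180
              len <- runif(1, spec$lengths[[lv]][1L], spec$lengths[[lv]][2L])
              gp <- grow_clear(start, h0, len, spec$tortuosity, spec$step, hw,
                               trial_avoid, trial_hw, parent_hw + hw + 4,
                               spec$canvas, margin,
                               avoid_owner = trial_owner,
                               exclude_owner = rows[[p]]$branch_id)
              if (gp$achieved >= max(0.75 * spec$lengths[[lv]][1L], len - spec$step)) {
                got <- gp; break
              }
            }
            if (is.null(got)) next
            set[[length(set) + 1L]] <- got
            trial_avoid <- rbind(trial_avoid, got$pts)
            trial_hw <- c(trial_hw, rep(hw, nrow(got$pts)))
            trial_owner <- c(trial_owner, rep(-1L, nrow(got$pts)))
          }
          if (length(set) > length(best_set)) best_set <- set
          if (length(set) == nc) break
        }
        if (length(best_set) == 1L) best_set <- list()   # avoid degree-2 joins
        for (gp in best_set) {
          bid <- bid + 1L
          rows[[bid]] <- tibble(branch_id = bid, level = lv, parent_id = rows[[p]]$branch_id,
                                width = spec$widths[lv], poly = list(gp$pts))
          headings[bid] <- gp$heading
          accept(gp$pts, hw, bid)
        }
      }
    }
    br <- bind_rows(rows)
    br$is_leaf <- !(br$branch_id %in% br$parent_id)
    br$intended_type <- ifelse(br$level == 1L, "SOMA_PRIMARY",
                        ifelse(br$level == 2L & br$width > 3, "SECONDARY", "FINE"))
    structure(list(spec = spec, seed = as.integer(seed),
                   soma = list(center = center, radius = spec$soma_radius),
                   branches = br, mitos = NULL),
              class = "astro_groundtruth")
  })
}

# arclength-parameterised point and direction on a polyline
poly_locate <- function(poly, t) {
  seg <- sqrt(rowSums(diff(poly)^2))
  cum <- c(0, cumsum(seg))
  t <- max(0, min(t, cum[length(cum)]))
  i <- max(1L, findInterval(t, cum, rightmost.closed = TRUE))
  i <- min(i, nrow(poly) - 1L)
  f <- if (seg[i] > 0) (t - cum[i]) / seg[i] else 0
  p <- poly[i, ] + f * (poly[i + 1L, ] - poly[i, ])
  d <- poly[i + 1L, ] - poly[i, ]
  list(p = p, angle = atan2(d[1L], d[2L]), length = cum[length(cum)])
}

poly_length <- function(poly) sum(sqrt(rowSums(diff(poly)^2)))

#' Place ground-truth mitochondria on the arbor
#'
#' Places non-overlapping elliptical mitochondria with centres on host
#' branches of the requested types.  `SECONDARY` and `FINE` placements
#' keep a safety margin from branchpoints and from the terminal tip
#' region so that the intended type is unambiguous; `TERMINAL`
#' mitochondria sit in the distal tip of leaf branches.  Sizes (areas,
#' px) are drawn uniformly from per-type ranges; ellipses are elongated
#' along the branch with the minor axis capped by the branch width.
#'
#' @param gt An `astro_groundtruth` (see [generate_arbor()]).
#' @param counts Named vector of requested mitochondria per type, e.g.
#'   `c(SECONDARY = 6, FINE = 12, TERMINAL = 4)`.
#' @param size_ranges Named list of (min, max) areas in px per type.
#' @param seed Integer seed.
#' @param L_tip Tip length used for the terminal margin, px.
#' @param min_render Minimum rasterised in-mask area, px: candidate
#'   placements whose ellipse covers fewer host-ribbon pixels are
#'   rejected, so every ground-truth mitochondrion stays detectable at
#'   the default detector area floor.
#' @return `gt` with a populated `mitos` tibble (`mito_id`,
#'   `host_branch`, `intended_type`, `row`, `col`, `semi_major`,
#'   `semi_minor`, `angle`, `nominal_size`).
#' @export
place_mitochondria <- function(gt, counts = c(SECONDARY = 6, FINE = 12, TERMINAL = 4),
                               size_ranges = list(SECONDARY = c(8, 18),
                                                  FINE = c(5, 10),
                                                  TERMINAL = c(5, 8)),
                               seed = 1L, L_tip = 5, min_render = 5L) {
  stopifnot(inherits(gt, "astro_groundtruth"))
  counts <- counts[counts > 0]
  if (length(counts) == 0L) { gt$mitos <- gt$mitos %||% NULL; return(gt) }
  br <- gt$branches
  d <- gt$spec$canvas
  tube_cache <- vector("list", nrow(br))
  host_tube <- function(b) {
    if (is.null(tube_cache[[b]]))
      tube_cache[[b]] <<- raster_tube(d, br$poly[[b]], br$width[b])
    tube_cache[[b]]
  }
  with_local_seed(seed, {
    placed <- list(); k <- 0L
    centers <- matrix(0, 0, 2L); radii <- numeric(0)
    for (ty in names(counts)) {
      hosts <- if (ty == "TERMINAL") which(br$is_leaf) else which(br$intended_type == ty)
      if (length(hosts) == 0L) abort(sprintf("no host branches for type %s", ty))
      for (m in seq_len(counts[[ty]])) {
        ok <- FALSE
        for (try in 1:400) {
          b <- hosts[sample.int(length(hosts), 1L)]
          poly <- br$poly[[b]]
          L <- poly_length(poly)
          # margins keep centres away from junction territory: the
          # proximal junction is dominated by the (wider) parent, the
          # distal one by the children
          pw <- br$width[match(br$parent_id[b], br$branch_id)]
          prox_margin <- max(4, if (is.na(br$parent_id[b])) 4 else 1.5 * pw)
          tip_margin <- if (br$is_leaf[b]) L_tip + 3 else max(8, br$width[b] + 2)
          if (ty == "TERMINAL") {
            if (L < L_tip + 6) next
            t <- runif(1, L - L_tip + 1, L - 1)
          } else {
            if (L < prox_margin + tip_margin + 3) next
            t <- runif(1, prox_margin, L - tip_margin)
          }
          loc <- poly_locate(poly, t)
          s <- runif(1, size_ranges[[ty]][1L], size_ranges[[ty]][2L])
          bmin <- min(br$width[b] / 2, sqrt(s / pi))
          amaj <- max(s / (pi * bmin), bmin)
          epx <- raster_ellipse(d, loc$p, amaj, bmin, loc$angle)
          if (length(intersect(epx, host_tube(b))) < min_render) next
          if (nrow(centers) > 0L) {
            dd <- sqrt((centers[, 1L] - loc$p[1L])^2 + (centers[, 2L] - loc$p[2L])^2)
            if (any(dd < radii + amaj + 2)) next
          }
          k <- k + 1L
          placed[[k]] <- tibble(mito_id = k, host_branch = br$branch_id[b],
                                intended_type = ty, row = loc$p[1L], col = loc$p[2L],
                                semi_major = amaj, semi_minor = bmin,
                                angle = loc$angle, nominal_size = s)
          centers <- rbind(centers, loc$p); radii <- c(radii, amaj)
          ok <- TRUE
          break
        }
        if (!ok) abort("cannot place mitochondria without overlap; relax counts or sizes")
      }
    }
    gt$mitos <- bind_rows(placed)
    gt
  })
}

# pixel indices within `width/2` of a polyline (a rasterised ribbon)
raster_tube <- function(dim, poly, width) {
  hw <- width / 2
  r0 <- max(1L, floor(min(poly[, 1L]) - hw - 1)); r1 <- min(dim[1L], ceiling(max(poly[, 1L]) + hw + 1))
  c0 <- max(1L, floor(min(poly[, 2L]) - hw - 1)); c1 <- min(dim[2L], ceiling(max(poly[, 2L]) + hw + 1))
  rr <- rep(r0:r1, times = c1 - c0 + 1L)
  cc <- rep(c0:c1, each = r1 - r0 + 1L)
  dmin <- rep(Inf, length(rr))
  for (i in seq_len(nrow(poly) - 1L)) {
    p1 <- poly[i, ]; p2 <- poly[i + 1L, ]
    v <- p2 - p1; vv <- sum(v^2)
    if (vv == 0) { d <- sqrt((rr - p1[1L])^2 + (cc - p1[2L])^2) } else {
      tt <- pmin(1, pmax(0, ((rr - p1[1L]) * v[1L] + (cc - p1[2L]) * v[2L]) / vv))
      d <- sqrt((rr - (p1[1L] + tt * v[1L]))^2 + (cc - (p1[2L] + tt * v[2L]))^2)
    }
    dmin <- pmin(dmin, d)
  }
  sel <- dmin <= hw
  rc_to_idx(rr[sel], cc[sel], dim)
}

# pixel indices of a filled rotated ellipse
raster_ellipse <- function(dim, center, a, b, angle) {
  ext <- max(a, b) + 1
  r0 <- max(1L, floor(center[1L] - ext)); r1 <- min(dim[1L], ceiling(center[1L] + ext))
  c0 <- max(1L, floor(center[2L] - ext)); c1 <- min(dim[2L], ceiling(center[2L] + ext))
  rr <- rep(r0:r1, times = c1 - c0 + 1L)
  cc <- rep(c0:c1, each = r1 - r0 + 1L)
  dr <- rr - center[1L]; dc <- cc - center[2L]
  u <- dr * sin(angle) + dc * cos(angle)     # along-branch coordinate
  v <- dr * cos(angle) - dc * sin(angle)
  sel <- (u / a)^2 + (v / b)^2 <= 1
  rc_to_idx(rr[sel], cc[sel], dim)
}

#' Render the two-channel image pair with label rasters
#'
#' Rasterises the arbor as constant-intensity ribbons (soma disk plus
#' branch tubes of their specified widths) in the cell channel and the
#' placed mitochondria as ellipses (clipped to the cell mask) in the
#' organelle channel, adds a constant background level and seeded
#' pseudo-normal noise, and emits complete ground-truth label rasters.
#' Rendered mitochondrial sizes (pixel counts after rasterisation and
#' clipping) are written back into the ground truth, since those are the
#' areas a perfect detector would measure.
#'
#' @param gt An `astro_groundtruth`, typically after
#'   [place_mitochondria()].
#' @param intensities List with `cell`, `mito` and `background` levels
#'   (16-bit scale; defaults 180 / 200 / 120).
#' @param noise_sd Standard deviation of additive pseudo-normal noise
#'   (default 0); images are rounded to integers and clipped to
#'   `[0, 65535]`.
#' @param seed Integer seed for the noise.
#' @param L_tip Tip length for the `TERMINAL` label overlay, px.
#' @return A list of class `astro_rendering`: `cell` and `mito`
#'   intensity matrices, `type_map` (0 background, 1-4 the branch types
#'   in hierarchy order), `branch_map` (ground-truth branch ids, soma =
#'   0 with type 1), `mito_map` (instance labels) and the updated `gt`.
#' @export
render_image <- function(gt, intensities = list(cell = 180, mito = 200, background = 120),
                         noise_sd = 0, seed = 1L, L_tip = 5) {
  stopifnot(inherits(gt, "astro_groundtruth"))
  d <- gt$spec$canvas
  type_code <- setNames(seq_along(BRANCH_TYPES), BRANCH_TYPES)
  branch_map <- matrix(0L, d[1L], d[2L])
  type_map <- matrix(0L, d[1L], d[2L])

  ctr <- gt$soma$center
  rr <- rep(seq_len(d[1L]), times = d[2L]); cc <- rep(seq_len(d[2L]), each = d[1L])
  soma_idx <- which((rr - ctr[1L])^2 + (cc - ctr[2L])^2 <= gt$soma$radius^2)
  type_map[soma_idx] <- 1L

  br <- gt$branches[order(gt$branches$level, gt$branches$branch_id), ]
  for (i in seq_len(nrow(br))) {
    px <- raster_tube(d, br$poly[[i]], br$width[i])
    branch_map[px] <- br$branch_id[i]
    type_map[px] <- type_code[[br$intended_type[i]]]
  }
  # terminal tips of leaves overwrite the distal end of their ribbon
  for (i in which(br$is_leaf)) {
    poly <- br$poly[[i]]
    L <- poly_length(poly)
    if (L <= L_tip) next
    # clip the polyline to its last L_tip of arclength
    seg <- sqrt(rowSums(diff(poly)^2)); cum <- c(0, cumsum(seg))
    keep <- which(cum >= L - L_tip)
    start <- poly_locate(poly, L - L_tip)$p
    tip_poly <- rbind(start, poly[keep, , drop = FALSE])
    px <- raster_tube(d, tip_poly, br$width[i])
    type_map[px] <- type_code[["TERMINAL"]]
  }
  type_map[soma_idx] <- 1L
  branch_map[soma_idx] <- 0L
  cell_mask <- type_map > 0L

  mito_map <- matrix(0L, d[1L], d[2L])
  if (!is.null(gt$mitos) && nrow(gt$mitos) > 0L) {
    sizes <- integer(nrow(gt$mitos))
    for (i in seq_len(nrow(gt$mitos))) {
      m <- gt$mitos[i, ]
      px <- raster_ellipse(d, c(m$row, m$col), m$semi_major, m$semi_minor, m$angle)
      px <- px[cell_mask[px]]
      mito_map[px] <- i
      sizes[i] <- length(px)
    }
    gt$mitos$size_px <- sizes
  }

  cell <- matrix(intensities$background, d[1L], d[2L])
  cell[cell_mask] <- intensities$background + intensities$cell
  mito <- matrix(intensities$background, d[1L], d[2L])
  mito[mito_map > 0L] <- intensities$background + intensities$mito
  if (noise_sd > 0) {
    with_local_seed(seed, {
      cell <- cell + matrix(rnorm(length(cell), 0, noise_sd), d[1L], d[2L])
      mito <- mito + matrix(rnorm(length(mito), 0, noise_sd), d[1L], d[2L])
    })
  }
  cell <- pmin(pmax(round(cell), 0), 65535)
  mito <- pmin(pmax(round(mito), 0), 65535)
  structure(list(cell = cell, mito = mito, type_map = type_map,
                 branch_map = branch_map, mito_map = mito_map, gt = gt),
            class = "astro_rendering")
}

#' One-call synthetic astrocyte benchmark image
#'
#' Convenience wrapper chaining [generate_arbor()],
#' [place_mitochondria()] and [render_image()], deriving the three
#' stage seeds from one master seed.
#'
#' @param seed Master seed.
#' @param spec An [arbor_spec()].
#' @param mito_counts,size_ranges Passed to [place_mitochondria()].
#' @param noise_sd,intensities Passed to [render_image()].
#' @return See [render_image()].
#' @export
simulate_astrocyte <- function(seed = 1L, spec = arbor_spec(),
                               mito_counts = c(SECONDARY = 6, FINE = 12, TERMINAL = 4),
                               size_ranges = list(SECONDARY = c(8, 18),
                                                  FINE = c(5, 10), TERMINAL = c(5, 8)),
                               noise_sd = 0,
                               intensities = list(cell = 180, mito = 200, background = 120)) {
  gt <- generate_arbor(spec, seed = seed)
  gt <- place_mitochondria(gt, counts = mito_counts, size_ranges = size_ranges,
                           seed = seed + 1000L)
  render_image(gt, intensities = intensities, noise_sd = noise_sd, seed = seed + 2000L)
}
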