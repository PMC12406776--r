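#' Detect mitochondria inside a cell mask
#'
#' Runs the order-statistics region detector on the organelle channel
#' with pixels outside the cell mask suppressed to the background median,
#' and clips detections to the mask.
#'
#' @param mito_img Organelle-channel intensity matrix (same shape as the
#'   cell channel).
#' @param mask Cell mask: an `astro_cells` tibble (row `cell_id`), a
#'   logical matrix, or pixel indices with `dim_img`.
#' @param alpha,min_area,max_area,ring_width,sigma Detector settings, see
#'   [detect_regions()]; defaults suit punctate organelles
#'   (`min_area = 5`, `max_area = 2000`: an organelle never spans the
#'   whole arbor).
#' @param cell_id,dim_img Mask interpretation helpers.
#' @return A tibble of class `astro_mitos`: `mito_id`, `size_px`,
#'   `mean_intensity`, `zscore`, `centroid_row`, `centroid_col` (0-based)
#'   and a `pixels` list-column.
#' @export
detect_mitochondria <- function(mito_img, mask, alpha = 0.001, min_area = 5L,
                                max_area = 2000L, ring_width = 2L, sigma = NULL,
                                cell_id = 1L, dim_img = NULL) {
  mito_img <- check_image(mito_img)
  m <- as_mask_matrix(mask, cell_id, dim_img)
  if (!all(dim(m) == dim(mito_img)))
    abort("organelle channel and cell mask have different shapes")
  bg <- if (any(!m)) median(mito_img[!m]) else 0
  if (is.null(sigma)) sigma <- estimate_noise(mito_img)
  supp <- mito_img
  supp[!m] <- bg
  fr <- detect_regions(supp, alpha = alpha, min_area = min_area,
                       max_area = max_area, ring_width = ring_width,
                       sigma = sigma)
  rows <- purrr::map(seq_len(nrow(fr)), function(i) {
    px <- fr$pixels[[i]][m[fr$pixels[[i]]]]
    if (length(px) < min_area) return(NULL)
    # full-width-at-half-contrast refinement: noise pixels riding just
    # above the detection level are excluded from the measured organelle
    ring <- region_ring(px, dim(m), ring_width)
    if (length(ring) > 0L) {
      half <- mean(mito_img[ring]) + (mean(mito_img[px]) - mean(mito_img[ring])) / 2
      keep <- mito_img[px] >= half
      if (sum(keep) >= min_area) px <- px[keep]
    }
    ce <- centroid_rc0(px, dim(m))
    tibble(size_px = length(px), mean_intensity = mean(mito_img[px]),
           zscore = fr$zscore[i], centroid_row = ce[1L], centroid_col = ce[2L],
           pixels = list(px))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L)
    out <- tibble(size_px = integer(0), mean_intensity = numeric(0),
                  zscore = numeric(0), centroid_row = numeric(0),
                  centroid_col = numeric(0), pixels = list())
  out <- out[order(-out$size_px), , drop = FALSE]
  out <- mutate(out, mito_id = dplyr::row_number(), .before = 1L)
  attr(out, "dim_img") <- dim(m)
  class(out) <- c("astro_mitos", class(out))
  out
}

#' Assign mitochondria to branch types
#'
#' Bins each mitochondrion into the branch type holding the plurality of
#' its pixels in the arbor territory map; ties are broken toward the
#' finer type (`TERMINAL` over `FINE` over `SECONDARY` over
#' `SOMA_PRIMARY`).  Mitochondria landing in the soma or a primary
#' branch are flagged `excluded`, since mitochondria form a dense network
#' there that cannot be resolved into discrete organelles.
#'
#' @param mitos An `astro_mitos` tibble (see [detect_mitochondria()]).
#' @param arbor An `astro_arbor` (see [classify_branches()]).
#' @return `mitos` with `assigned_type` and logical `excluded` columns.
#' @export
assign_mitochondria <- function(mitos, arbor) {
  stopifnot(inherits(arbor, "astro_arbor"))
  type_of_segment <- arbor$segments$type[order(arbor$segments$segment_id)]
  fineness <- setNames(seq_along(BRANCH_TYPES), BRANCH_TYPES)  # higher = finer
  assigned <- character(nrow(mitos))
  for (i in seq_len(nrow(mitos))) {
    labs <- arbor$territory[mitos$pixels[[i]]]
    if (any(labs == 0L)) abort("mitochondrion outside cell")
    types <- type_of_segment[labs]
    tab <- table(types)
    best <- names(tab)[tab == max(tab)]
    assigned[i] <- best[which.max(fineness[best])]
  }
  mutate(mitos,
         assigned_type = factor(assigned, levels = BRANCH_TYPES),
         excluded = assigned == "SOMA_PRIMARY")
}

#' Per-branch-type mitochondrial statistics of one cell
#'
#' Summarises assigned mitochondria into the per-cell profile: branch
#' counts, mitochondrial counts and mean mitochondrial sizes per branch
#' type.  Counts and sizes are reported only for `SECONDARY`, `FINE` and
#' `TERMINAL` branches; soma/primary mitochondria appear solely in the
#' excluded count.  An empty type reports a count of 0 and `NA` mean
#' size.
#'
#' @param assigned An assigned `astro_mitos` tibble
#'   (see [assign_mitochondria()]).
#' @param arbor Optional `astro_arbor` supplying branch counts.
#' @param cell_id Cell identifier stored in the profile.
#' @param pixel_size Physical pixel size (micrometres per pixel) used to
#'   derive sizes in square micrometres.
#' @return A tibble of class `astro_profile` with one row per branch
#'   type: `cell_id`, `type`, `branch_count`, `mito_count`,
#'   `mito_mean_size_px`, `mito_mean_size_um2`; attribute
#'   `excluded_mito_count`.
#' @export
mito_stats <- function(assigned, arbor = NULL, cell_id = 1L, pixel_size = 1) {
  if (nrow(assigned) > 0L && is.null(assigned$assigned_type))
    abort("mitochondria must be assigned first (see assign_mitochondria)")
  reported <- c("SECONDARY", "FINE", "TERMINAL")
  counts <- sizes <- setNames(rep(NA_real_, 4L), BRANCH_TYPES)
  counts[reported] <- 0
  for (ty in reported) {
    sel <- !assigned$excluded & assigned$assigned_type == ty
    counts[ty] <- sum(sel)
    sizes[ty] <- if (any(sel)) mean(assigned$size_px[sel]) else NA_real_
  }
  bc <- if (!is.null(arbor)) branch_counts(arbor)$branch_count else rep(NA_integer_, 4L)
  out <- tibble(
    cell_id = cell_id,
    type = factor(BRANCH_TYPES, levels = BRANCH_TYPES),
    branch_count = bc,
    mito_count = as.integer(unname(counts[BRANCH_TYPES])),
    mito_mean_size_px = unname(sizes[BRANCH_TYPES]),
    mito_mean_size_um2 = unname(sizes[BRANCH_TYPES]) * pixel_size^2
  )
  attr(out, "excluded_mito_count") <- sum(assigned$excluded %||% logical(0))
  class(out) <- c("astro_profile", class(out))
  out
}
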