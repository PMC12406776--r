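#' Tidy a per-cell profile into long form
#'
#' @param x An `astro_profile` (see [mito_stats()] / [run_pipeline()]).
#' @param ... Unused.
#' @return A long tibble with columns `cell_id`, `type`, `metric`,
#'   `value`.
#' @export
tidy.astro_profile <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x),
                      cols = c("branch_count", "mito_count",
                               "mito_mean_size_px", "mito_mean_size_um2"),
                      names_to = "metric", values_to = "value")
}

#' One-row summary of a per-cell profile
#'
#' @param x An `astro_profile`.
#' @param ... Unused.
#' @return A tibble with one row per cell: total branch count, total
#'   reported mitochondria and the excluded soma/primary count.
#' @export
glance.astro_profile <- function(x, ...) {
  out <- summarise(group_by(as_tibble(x), .data$cell_id),
                   n_branches = sum(.data$branch_count, na.rm = TRUE),
                   n_mito_reported = sum(.data$mito_count, na.rm = TRUE))
  out$n_mito_excluded <- attr(x, "excluded_mito_count") %||% NA_integer_
  ungroup(out)
}

#' Tidy the typed segments of an arbor
#'
#' @param x An `astro_arbor` (see [classify_branches()]).
#' @param ... Unused.
#' @return A tibble of typed segments without the pixel payload.
#' @export
tidy.astro_arbor <- function(x, ...) {
  select(x$segments, "segment_id", "branch_id", "type", "length_px",
         "mean_width_px", "role")
}

#' One-row summary of an arbor
#'
#' @param x An `astro_arbor`.
#' @param ... Unused.
#' @return A tibble with mask area, soma width, total skeleton length
#'   and per-type branch counts.
#' @export
glance.astro_arbor <- function(x, ...) {
  bc <- branch_counts(x)
  wide <- tidyr::pivot_wider(bc, names_from = "type", values_from = "branch_count")
  dplyr::bind_cols(
    tibble(mask_area_px = length(x$mask_idx),
           soma_width_px = x$soma_width_px,
           skeleton_px = sum(x$segments$length_px, na.rm = TRUE)),
    wide)
}

#' Tidy detected fragments or mitochondria
#'
#' @param x An `astro_fragments` or `astro_mitos` tibble.
#' @param ... Unused.
#' @return The table without the pixel list-column.
#' @export
tidy.astro_fragments <- function(x, ...) {
  select(as_tibble(x), -"pixels")
}

#' @rdname tidy.astro_fragments
#' @export
tidy.astro_mitos <- function(x, ...) {
  select(as_tibble(x), -"pixels")
}

#' Plot an arbor territory map
#'
#' Renders the branch-type territory of a classified arbor as a raster,
#' one colour per hierarchy type.
#'
#' @param object An `astro_arbor`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.astro_arbor <- function(object, ...) {
  terr <- object$territory
  idx <- which(terr > 0L)
  rc <- idx_to_rc(idx, dim(terr))
  type <- object$segments$type[match(terr[idx], object$segments$segment_id)]
  df <- tibble(row = rc[, 1L], col = rc[, 2L],
               type = factor(type, levels = BRANCH_TYPES))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$type)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column (px)", y = "row (px)", fill = "branch type") +
    ggplot2::theme_minimal()
}

#' Plot a per-cell profile
#'
#' Bar panels of branch counts, mitochondrial counts and mean
#' mitochondrial sizes per branch type.
#'
#' @param object An `astro_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.astro_profile <- function(object, ...) {
  df <- tidy.astro_profile(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$type, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot neighbor-distance distributions
#'
#' Empirical cumulative distributions of the nearest-neighbor distance
#' and the mean distance to k neighbors.
#'
#' @param object An `astro_neighbors` tibble (see [neighbor_stats()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.astro_neighbors <- function(object, ...) {
  k <- attr(object, "k") %||% NA_integer_
  df <- tidyr::pivot_longer(as_tibble(object), cols = c("nn_distance", "k_mean_distance"),
                            names_to = "metric", values_to = "distance")
  df$metric <- ifelse(df$metric == "nn_distance", "nearest neighbor",
                      sprintf("mean of %s neighbors", k))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, colour = .data$metric)) +
    ggplot2::stat_ecdf() +
    ggplot2::labs(x = "distance", y = "ECDF", colour = NULL) +
    ggplot2::theme_minimal()
}
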