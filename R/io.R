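#' Read channels from a grayscale/multi-channel TIFF
#'
#' Reads 8- or 16-bit unsigned TIFF images at native integer levels.
#' Multi-channel files are supported either as multiple pages
#' (`layout = "pages"`) or as samples along the trailing axis of a
#' single page (`layout = "samples"`).
#'
#' @param path Path to the TIFF file.
#' @param channel 0-based channel index, or `NULL` for all channels.
#' @param layout `"pages"` (default) or `"samples"`.
#' @return A numeric matrix (single channel) or a list of matrices.
#' @export
read_image <- function(path, channel = NULL, layout = c("pages", "samples")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) abort(sprintf("cannot read '%s': file does not exist", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) abort(sprintf("cannot read '%s': %s", path, conditionMessage(e))))
  chans <- list()
  if (layout == "pages") {
    for (p in pages) {
      if (length(dim(p)) == 3L) for (s in seq_len(dim(p)[3L])) chans[[length(chans) + 1L]] <- p[, , s]
      else chans[[length(chans) + 1L]] <- p
    }
  } else {
    p <- pages[[1L]]
    if (length(dim(p)) == 3L) for (s in seq_len(dim(p)[3L])) chans[[length(chans) + 1L]] <- p[, , s]
    else chans[[1L]] <- p
  }
  chans <- lapply(chans, function(m) { storage.mode(m) <- "double"; m })
  if (is.null(channel)) return(if (length(chans) == 1L) chans[[1L]] else chans)
  ch <- as.integer(channel)
  if (ch < 0L || ch >= length(chans))
    abort(sprintf("cannot read '%s': channel %d not present (%d channel(s))",
                  path, ch, length(chans)))
  chans[[ch + 1L]]
}

#' Write an integer intensity matrix as a TIFF
#'
#' @param img Numeric matrix of non-negative integers.
#' @param path Output path.
#' @param bits Bits per sample, 8 or 16 (default 16).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bits = 16L) {
  stopifnot(bits %in% c(8L, 16L))
  mx <- 2^bits - 1
  if (any(img < 0) || any(img > mx)) abort("intensities out of range for bit depth")
  tiff::writeTIFF(round(img) / mx, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

PIPELINE_DEFAULTS <- list(
  cell_channel = 0L, mito_channel = 1L,
  cell_alpha = 0.001, cell_min_area = 50, cell_max_area = NA,
  mito_alpha = 0.001, mito_min_area = 5, mito_max_area = 2000,
  ring_width = 2, envelope = 50, min_link_weight = NA,
  theta_soma = 0.6, theta_primary = 0.35, theta_fine = 3, L_tip = 5,
  prune_spurs = 3, pixel_size = 1, seed = 1L
)

#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()].  Unknown keys are
#' rejected.  `min_link_weight = NA` defers to the data-driven default
#' (half the mean fragment intensity).
#'
#' @param ... Named settings overriding the defaults (see
#'   `astroseg:::PIPELINE_DEFAULTS`).
#' @return A list of class `astro_config`.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  if (length(over) > 0L && (is.null(names(over)) || any(names(over) == "")))
    abort("all configuration values must be named")
  unknown <- setdiff(names(over), names(PIPELINE_DEFAULTS))
  if (length(unknown) > 0L)
    abort(sprintf("unknown configuration key(s): %s", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(PIPELINE_DEFAULTS, over)
  stopifnot(cfg$cell_alpha > 0, cfg$cell_alpha < 1, cfg$mito_alpha > 0,
            cfg$mito_alpha < 1, cfg$theta_soma > 0, cfg$theta_soma <= 1,
            cfg$theta_primary > 0, cfg$theta_fine > 0, cfg$L_tip >= 1,
            cfg$pixel_size > 0)
  structure(cfg, class = "astro_config")
}

#' Write / read a flat key=value configuration file
#'
#' @param cfg An `astro_config`.
#' @param path File path.
#' @return `read_config` returns an `astro_config`; `write_config`
#'   returns `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k) sprintf("%s=%s", k, format(cfg[[k]], digits = 12)),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) {
    v <- trimws(paste(p[-1L], collapse = "="))
    suppressWarnings(num <- as.numeric(v))
    if (!is.na(num)) num else if (v == "NA") NA else v
  })
  names(vals) <- vapply(kv, function(p) trimws(p[1L]), character(1))
  do.call(pipeline_config, vals)
}

empty_outputs <- function(out_dir) {
  readr::write_csv(tibble(branch_id = integer(0), type = character(0),
                          length_px = integer(0), mean_width_px = numeric(0)),
                   file.path(out_dir, "branches.csv"))
  readr::write_csv(tibble(mito_id = integer(0), cell_id = integer(0),
                          size_px = integer(0), size_um2 = numeric(0),
                          centroid_row = numeric(0), centroid_col = numeric(0),
                          assigned_type = character(0), excluded = logical(0)),
                   file.path(out_dir, "mitochondria.csv"))
  readr::write_csv(tibble(cell_id = integer(0), type = character(0),
                          branch_count = integer(0), mito_count = integer(0),
                          mito_mean_size_px = numeric(0), mito_mean_size_um2 = numeric(0)),
                   file.path(out_dir, "profiles.csv"))
}

#' Run the full segmentation pipeline on an image pair
#'
#' Detect astrocyte fragments, link them through the brightest-path
#' fragment graph and its optimal spanning tree, assemble the cell mask,
#' skeletonize and classify the branch hierarchy, detect and bin
#' mitochondria, and summarise per-branch-type statistics.  When
#' `out_dir` is given, writes `fragments.csv`, `edges.csv`,
#' `branches.csv`, `mitochondria.csv`, `profiles.csv`, label TIFFs
#' (`cell_labels.tif`, `type_labels.tif`, `mito_labels.tif`) and echoes
#' the configuration (`config.txt`).
#'
#' @param cell_img,mito_img Intensity matrices of the two channels.
#' @param config An `astro_config` (see [pipeline_config()]).
#' @param out_dir Optional output directory (created if needed).
#' @param verbose Log each stage with counts via [message()].
#' @return A list of class `astro_result`: `status` (`"ok"` or
#'   `"no significant cell region"`), `fragments`, `graph`, `cells`,
#'   `arbors` (list of `astro_arbor` per cell), `mitos`, `profiles`.
#' @export
run_pipeline <- function(cell_img, mito_img = NULL, config = pipeline_config(),
                         out_dir = NULL, verbose = TRUE) {
  cell_img <- check_image(cell_img, "cell_img")
  if (!is.null(mito_img)) {
    mito_img <- check_image(mito_img, "mito_img")
    if (!all(dim(mito_img) == dim(cell_img)))
      abort("cell and organelle channels have different shapes")
  }
  say <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(config, file.path(out_dir, "config.txt"))
  }
  t0 <- proc.time()[3L]

  sigma <- estimate_noise(cell_img)
  # a single cell cannot fill the field; an unbounded area gate would let
  # a near-percolation noise component outscore the cell
  cell_max <- if (is.na(config$cell_max_area)) 0.25 * length(cell_img) else config$cell_max_area
  frags <- detect_regions(cell_img, alpha = config$cell_alpha,
                          min_area = config$cell_min_area,
                          max_area = cell_max,
                          ring_width = config$ring_width, sigma = sigma)
  say("detect: sigma=%.3g, %d fragment(s)", sigma, nrow(frags))
  if (!is.null(out_dir))
    readr::write_csv(
      select(as_tibble(frags), "id", "area_px", "mean_intensity", "zscore",
             "centroid_row", "centroid_col"),
      file.path(out_dir, "fragments.csv"))

  if (nrow(frags) == 0L) {
    say("status: no significant cell region")
    if (!is.null(out_dir)) empty_outputs(out_dir)
    return(structure(list(status = "no significant cell region",
                          fragments = frags, graph = NULL, cells = NULL,
                          arbors = list(), mitos = NULL, profiles = NULL),
                     class = "astro_result"))
  }

  graph <- build_fragment_graph(cell_img, frags, envelope = config$envelope)
  tree <- link_fragments(graph)
  mlw <- if (is.na(config$min_link_weight)) NULL else config$min_link_weight
  cells <- assemble_cells(cell_img, frags, tree, min_link_weight = mlw)
  say("linkage: %d edge(s), %d cell(s)", nrow(tree), nrow(cells))
  if (!is.null(out_dir)) {
    et <- as_tibble(tree)
    et$kept_after_cut <- et$in_tree & et$weight >=
      (mlw %||% (0.5 * mean(cell_img[unlist(frags$pixels)])))
    readr::write_csv(select(et, "frag_a", "frag_b", "weight", "bottleneck",
                            "in_tree", "kept_after_cut"),
                     file.path(out_dir, "edges.csv"))
  }

  arbors <- list(); branch_tabs <- list(); mito_tabs <- list(); prof_tabs <- list()
  mitos_by_cell <- list()
  all_mitos <- NULL
  for (ci in seq_len(nrow(cells))) {
    skel <- skeletonize_mask(cells, cell_id = ci)
    bg <- build_branch_graph(skel, prune_spurs = config$prune_spurs,
                             trim_intensity = cell_img)
    arbor <- classify_branches(bg, theta_soma = config$theta_soma,
                               theta_primary = config$theta_primary,
                               theta_fine = config$theta_fine,
                               L_tip = config$L_tip)
    arbors[[ci]] <- arbor
    segs <- arbor$segments
    branch_tabs[[ci]] <- tibble(cell_id = ci, segment_id = segs$segment_id,
                                branch_id = segs$branch_id, type = segs$type,
                                length_px = segs$length_px,
                                mean_width_px = segs$mean_width_px,
                                is_soma = segs$role == "soma")
    say("hierarchy cell %d: %s", ci,
        paste(sprintf("%s=%d", branch_counts(arbor)$type,
                      branch_counts(arbor)$branch_count), collapse = " "))
    mt <- NULL
    if (!is.null(mito_img)) {
      mt <- detect_mitochondria(mito_img, cells, alpha = config$mito_alpha,
                                min_area = config$mito_min_area,
                                max_area = config$mito_max_area,
                                ring_width = config$ring_width, cell_id = ci)
      mt <- assign_mitochondria(mt, arbor)
      mitos_by_cell[[ci]] <- mt
      say("organelle cell %d: %d mitochondria (%d excluded)", ci, nrow(mt),
          sum(mt$excluded))
      mito_tabs[[ci]] <- mutate(
        select(as_tibble(mt), "mito_id", "size_px", "centroid_row",
               "centroid_col", "assigned_type", "excluded"),
        cell_id = ci, size_um2 = .data$size_px * config$pixel_size^2,
        .after = "mito_id")
      all_mitos <- bind_rows(all_mitos, mito_tabs[[ci]])
    }
    prof_tabs[[ci]] <- mito_stats(mt %||% tibble(size_px = integer(0),
                                                 assigned_type = factor(character(0), BRANCH_TYPES),
                                                 excluded = logical(0)),
                                  arbor = arbor, cell_id = ci,
                                  pixel_size = config$pixel_size)
  }
  profiles <- bind_rows(prof_tabs)
  class(profiles) <- c("astro_profile", class(tibble()))

  if (!is.null(out_dir)) {
    readr::write_csv(bind_rows(branch_tabs), file.path(out_dir, "branches.csv"))
    if (!is.null(all_mitos)) readr::write_csv(all_mitos, file.path(out_dir, "mitochondria.csv"))
    readr::write_csv(profiles, file.path(out_dir, "profiles.csv"))
    d <- dim(cell_img)
    lab <- matrix(0L, d[1L], d[2L])
    for (ci in seq_len(nrow(cells))) lab[cells$pixels[[ci]]] <- ci
    write_image(lab, file.path(out_dir, "cell_labels.tif"), bits = 16L)
    tm <- matrix(0L, d[1L], d[2L])
    type_code <- setNames(seq_along(BRANCH_TYPES), BRANCH_TYPES)
    for (ci in seq_len(nrow(cells))) {
      ar <- arbors[[ci]]
      terr <- ar$territory
      tys <- ar$segments$type[match(terr[terr > 0L], ar$segments$segment_id)]
      tm[which(terr > 0L)] <- type_code[tys]
    }
    write_image(tm, file.path(out_dir, "type_labels.tif"), bits = 16L)
    if (!is.null(mito_img)) {
      mm <- matrix(0L, d[1L], d[2L])
      k <- 0L
      for (ci in seq_along(mitos_by_cell)) {
        mt <- mitos_by_cell[[ci]]
        if (is.null(mt)) next
        for (i in seq_len(nrow(mt))) { k <- k + 1L; mm[mt$pixels[[i]]] <- k }
      }
      write_image(mm, file.path(out_dir, "mito_labels.tif"), bits = 16L)
    }
  }
  say("pipeline done in %.1fs", proc.time()[3L] - t0)
  structure(list(status = "ok", fragments = frags, graph = tree, cells = cells,
                 arbors = arbors, mitos = all_mitos, profiles = profiles),
            class = "astro_result")
}

#' @export
print.astro_result <- function(x, ...) {
  cat(sprintf("<astro_result> status: %s\n", x$status))
  if (!is.null(x$profiles)) print(as_tibble(x$profiles))
  invisible(x)
}
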