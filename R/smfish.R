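#' Per-cell transcript-count table
#'
#' smFISH output reduced to per-cell records: a 2-D position in a PSM-aligned
#' frame (x is the anteroposterior axis with the posterior end at 0,
#' anterior positive; y the dorsoventral/width axis) plus transcript counts
#' for two genes.
#'
#' @param x Data frame with columns `cell_id, x_um, y_um, count_gene1,
#'   count_gene2`.
#' @return A data frame of class `cell_table`.
#' @export
cell_table <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("cell_id", "x_um", "y_um", "count_gene1", "count_gene2")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("cell table is missing column(s): ", paste(miss, collapse = ", "))
  for (cn in c("count_gene1", "count_gene2")) {
    v <- x[[cn]]
    if (any(is.na(v)) || any(v < 0) || any(v != floor(v)))
      stop(cn, " must hold non-negative integer counts")
    x[[cn]] <- as.integer(v)
  }
  x <- x[, need]
  class(x) <- c("cell_table", "data.frame")
  x
}

#' Read / write a per-cell transcript-count table as CSV
#'
#' Columns `cell_id, x_um, y_um, count_gene1, count_gene2`.
#'
#' @param path File path.
#' @return `read_cell_table` returns a [cell_table()];
#'   `write_cell_table` returns `path` invisibly.
#' @export
read_cell_table <- function(path) {
  cell_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_cell_table
#' @param x A [cell_table()].
#' @export
write_cell_table <- function(x, path) {
  stopifnot(inherits(x, "cell_table"))
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Slicing configuration for spatial transcript correlation
#'
#' Controls how the PSM is cut into stripe-parallel slices. The stripe angle
#' is measured relative to the anteroposterior axis: 90 degrees means
#' stripes perpendicular to the axis, so slices advance purely along x. For
#' mutants whose stripe angle cannot be measured per position, a single
#' fixed angle (the mean at the anterior-most expression domain) is used.
#'
#' @param psm_length_um PSM length along the anteroposterior axis,
#'   micrometers.
#' @param angle_deg Fixed stripe angle in degrees, in (0, 180); default 90.
#' @param thickness_um Slice thickness in micrometers (default 10).
#' @param region Closed interval of slice-center positions kept, as
#'   fractions of PSM length from the posterior end (default `c(0.4, 0.8)`,
#'   the region of characteristic kinematic waves).
#' @param background Per-gene background count `b` subtracted (and clamped
#'   at zero) before averaging; length-2 vector, default `c(0, 0)`.
#' @param psm_width_um PSM width used to place slice centers for oblique
#'   angles; default NULL derives it from the data.
#' @return A `slice_config` list.
#' @export
slice_config <- function(psm_length_um, angle_deg = 90, thickness_um = 10,
                         region = c(0.4, 0.8), background = c(0, 0),
                         psm_width_um = NULL) {
  stopifnot(is.numeric(psm_length_um), psm_length_um > 0)
  if (thickness_um <= 0) stop("thickness_um must be positive")
  if (angle_deg <= 0 || angle_deg >= 180)
    stop("angle_deg must lie strictly inside (0, 180)")
  if (length(region) != 2L || region[1L] < 0 || region[2L] > 1 ||
      region[1L] >= region[2L])
    stop("region must satisfy 0 <= lower < upper <= 1")
  if (length(background) == 1L) background <- rep(background, 2L)
  if (any(background < 0)) stop("background must be non-negative")
  structure(list(psm_length_um = psm_length_um, angle_deg = angle_deg,
                 thickness_um = thickness_um, region = region,
                 background = background, psm_width_um = psm_width_um),
            class = "slice_config")
}

#' Assign each cell to a stripe-parallel slice
#'
#' Projects every cell onto the axis normal to the stripe direction
#' (`u = x sin(alpha) + y cos(alpha)`, alpha the stripe angle) and takes
#' `floor(u / thickness)` as the slice index, so each cell belongs to
#' exactly one slice. At alpha = 90 degrees this reduces to slicing by x
#' alone.
#'
#' @param cells A [cell_table()].
#' @param cfg A [slice_config()].
#' @return Integer slice index per cell.
#' @export
assign_slices <- function(cells, cfg) {
  stopifnot(inherits(cells, "cell_table"), inherits(cfg, "slice_config"))
  a <- cfg$angle_deg * pi / 180
  u <- cells$x_um * sin(a) + cells$y_um * cos(a)
  as.integer(floor(u / cfg$thickness_um))
}

#' Background-subtracted slice means of both genes
#'
#' Per slice and gene, the mean of `max(count - b, 0)` over member cells,
#' with the slice-center position expressed as a fraction of PSM length from
#' the posterior end (measured along the anteroposterior axis at the PSM
#' midline). Slices without cells are absent; retained slices have
#' `n_cells >= 1`.
#'
#' @param cells A [cell_table()].
#' @param cfg A [slice_config()].
#' @return A `slice_stats` data frame: `slice, center_fraction, mean_gene1,
#'   mean_gene2, n_cells`, ordered by slice index.
#' @export
slice_profiles <- function(cells, cfg) {
  stopifnot(inherits(cells, "cell_table"), inherits(cfg, "slice_config"))
  sl <- assign_slices(cells, cfg)
  a <- cfg$angle_deg * pi / 180
  y_mid <- if (!is.null(cfg$psm_width_um)) cfg$psm_width_um / 2 else
    mean(range(cells$y_um))
  g1 <- pmax(cells$count_gene1 - cfg$background[1L], 0)
  g2 <- pmax(cells$count_gene2 - cfg$background[2L], 0)
  idx <- sort(unique(sl))
  out <- do.call(rbind, lapply(idx, function(k) {
    sel <- sl == k
    u_center <- (k + 0.5) * cfg$thickness_um
    x_center <- (u_center - y_mid * cos(a)) / sin(a)
    data.frame(slice = k, center_fraction = x_center / cfg$psm_length_um,
               mean_gene1 = mean(g1[sel]), mean_gene2 = mean(g2[sel]),
               n_cells = sum(sel))
  }))
  class(out) <- c("slice_stats", "data.frame")
  out
}

#' Restrict slice statistics to a PSM region
#'
#' Keeps slices whose center fraction lies in the closed interval `bounds`
#' (default the 40--80% posterior region where kinematic waves are
#' characteristic); boundary-exact centers are kept.
#'
#' @param stats A `slice_stats` data frame from [slice_profiles()].
#' @param bounds Closed interval of center fractions, default `c(0.4, 0.8)`.
#' @return The retained subset; an error if fewer than 3 slices remain
#'   (the correlation would be unreliable).
#' @export
filter_region <- function(stats, bounds = c(0.4, 0.8)) {
  stopifnot(is.data.frame(stats), "center_fraction" %in% names(stats),
            length(bounds) == 2L, bounds[1L] < bounds[2L])
  keep <- stats$center_fraction >= bounds[1L] &
    stats$center_fraction <= bounds[2L]
  out <- stats[keep, , drop = FALSE]
  if (nrow(out) < 3L)
    stop("fewer than 3 slices inside the region; correlation unreliable")
  out
}

#' Spatial Pearson correlation of two genes across slices
#'
#' Pearson r between the background-subtracted slice-mean vectors of the
#' two genes, ordered by slice index. Undefined (NA, with a `reason`
#' attribute) when either profile is constant.
#'
#' @param stats A `slice_stats` data frame (usually after
#'   [filter_region()]), at least 3 slices.
#' @return Pearson r, or NA when undefined.
#' @export
spatial_correlation <- function(stats) {
  stopifnot(is.data.frame(stats),
            all(c("slice", "mean_gene1", "mean_gene2") %in% names(stats)))
  if (nrow(stats) < 3L) stop("need at least 3 slices")
  stats <- stats[order(stats$slice), ]
  if (stats::sd(stats$mean_gene1) == 0 || stats::sd(stats$mean_gene2) == 0)
    return(structure(NA_real_, reason = "constant slice profile"))
  stats::cor(stats$mean_gene1, stats$mean_gene2)
}

#' Slice, restrict and correlate in one call
#'
#' Convenience wrapper: [slice_profiles()], [filter_region()] with the
#' configured region, then [spatial_correlation()].
#'
#' @inheritParams slice_profiles
#' @return Pearson r (NA when undefined).
#' @export
smfish_spatial_correlation <- function(cells, cfg) {
  spatial_correlation(filter_region(slice_profiles(cells, cfg), cfg$region))
}
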