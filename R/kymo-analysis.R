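#' Analysis configuration for the amplitude pipeline
#'
#' Collects the tunables of the determination-front amplitude extraction.
#' The detection window should match the clock period at the imaging
#' temperature: 12 frames at 21.5 degC and 7 frames at 26 degC (5-min
#' frames); `temperature` picks these defaults, or set `window_frames`
#' directly.
#'
#' @param front_fraction Determination-front position as a fraction of PSM
#'   length from the posterior end (default 0.5: segmental commitment occurs
#'   in the middle of the PSM).
#' @param window_frames Detection window per wave, in pre-resampling frames.
#' @param temperature One of `"21.5C"` or `"26C"`; sets `window_frames` to 12
#'   or 7 when that is NULL.
#' @param sg_window Savitzky-Golay window length in frames (odd, >
#'   `sg_order`).
#' @param sg_order Savitzky-Golay polynomial order.
#' @param resample_factor Uniform re-gridding factor after smoothing
#'   (default 10).
#' @param n_waves Number of consecutive waves to extract (default 15,
#'   boundaries 11--25).
#' @param profile_width_px Width of the line profile averaged around the
#'   front position (default 4).
#' @param loi_width_px Line-of-interest band width used when building
#'   kymographs from stacks (default 15).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(front_fraction = 0.5, window_frames = NULL,
                            temperature = NULL, sg_window = 9L, sg_order = 2L,
                            resample_factor = 10L, n_waves = 15L,
                            profile_width_px = 4L, loi_width_px = 15L) {
  if (is.null(window_frames)) {
    window_frames <- if (is.null(temperature)) 12L else
      switch(temperature, "21.5C" = 12L, "26C" = 7L,
             stop("unknown temperature label: ", temperature))
  }
  window_frames <- as.integer(window_frames)
  sg_window <- as.integer(sg_window); sg_order <- as.integer(sg_order)
  resample_factor <- as.integer(resample_factor)
  if (window_frames < 3L) stop("window_frames must be >= 3")
  if (sg_window %% 2L == 0L || sg_window <= sg_order)
    stop("sg_window must be odd and greater than sg_order")
  if (resample_factor < 1L) stop("resample_factor must be >= 1")
  if (front_fraction <= 0 || front_fraction >= 1)
    stop("front_fraction must lie strictly inside (0, 1)")
  structure(list(front_fraction = front_fraction,
                 window_frames = window_frames, sg_window = sg_window,
                 sg_order = sg_order, resample_factor = resample_factor,
                 n_waves = as.integer(n_waves),
                 profile_width_px = as.integer(profile_width_px),
                 loi_width_px = as.integer(loi_width_px)),
            class = "analysis_config")
}

#' Determination-front trajectory on a kymograph
#'
#' The front sits at a fixed fraction `f` of the PSM length from the
#' posterior edge: `position = f * psm_extent` pixels from that edge, per
#' frame (fractional positions allowed). Column `k` of the kymograph covers
#' the interval `(k - 1, k]` pixels, so a position `p` falls in column
#' `ceiling(p)` and the profile band is centered on the round-half-up pixel
#' `floor(p + 0.5)`.
#'
#' @param kymo A [kymograph()].
#' @param psm_extent PSM length in pixels: a scalar or one value per frame.
#'   Defaults to the full kymograph width.
#' @param front_fraction Fraction `f` in (0, 1).
#' @return Numeric vector of fractional column positions (1-based), one per
#'   frame, of class `front_trajectory`.
#' @export
locate_front <- function(kymo, psm_extent = ncol(kymo$intensity),
                         front_fraction = 0.5) {
  stopifnot(inherits(kymo, "kymograph"))
  if (front_fraction <= 0 || front_fraction >= 1)
    stop("front_fraction must lie strictly inside (0, 1)")
  nf <- nrow(kymo$intensity)
  if (length(psm_extent) == 1L) psm_extent <- rep(psm_extent, nf)
  if (length(psm_extent) != nf)
    stop("psm_extent must be scalar or one value per frame")
  if (any(psm_extent <= 0)) stop("psm_extent must be positive")
  if (any(psm_extent > ncol(kymo$intensity)))
    stop("psm_extent exceeds the kymograph width")
  structure(front_fraction * psm_extent, class = "front_trajectory")
}

#' Raw intensity profile along the front trajectory
#'
#' For each frame, averages the `width_px` columns centered at the front
#' position (rounded half-up to a pixel; for even widths the band extends one
#' column further to the anterior side of center). Bands that would cross the
#' edge of
#' the kymograph are clamped inside it with a warning.
#'
#' @param kymo A [kymograph()].
#' @param traj A [locate_front()] trajectory (or numeric positions).
#' @param width_px Band width in columns (default 4).
#' @return Numeric vector, one mean intensity per frame.
#' @export
extract_front_profile <- function(kymo, traj, width_px = 4L) {
  stopifnot(inherits(kymo, "kymograph"), width_px >= 1L)
  mat <- kymo$intensity
  pos <- as.numeric(traj)
  if (length(pos) != nrow(mat))
    stop("trajectory length must equal the number of frames")
  center <- floor(pos + 0.5)                 # round half-up to pixel
  left <- center - floor(width_px / 2) + (1 - width_px %% 2L)
  lo <- left; hi <- left + width_px - 1L
  clamp <- lo < 1L | hi > ncol(mat)
  if (any(clamp)) {
    warning(sum(clamp), " frame(s) had the profile band clamped at the edge")
    shift <- pmax(1L - lo, 0L) - pmax(hi - ncol(mat), 0L)
    lo <- lo + shift; hi <- hi + shift
  }
  vapply(seq_len(nrow(mat)), function(f) mean(mat[f, lo[f]:hi[f]]),
         numeric(1L))
}

#' Smooth and resample a front profile
#'
#' Savitzky-Golay least-squares smoothing (stated window and order, in
#' frames) followed by linear interpolation onto a uniform grid of
#' `factor * length(series)` samples spanning the same time range. The
#' returned object keeps the frame-to-sample mapping used by
#' [detect_waves()].
#'
#' @param series Raw per-frame intensity series.
#' @param sg_window Odd smoothing window length, frames.
#' @param sg_order Polynomial order (< `sg_window`).
#' @param factor Resampling factor (1 = no resampling).
#' @return A `front_profile` list: `raw`, `smoothed` (per frame),
#'   `resampled`, `factor`, `frame_times` (frame index of each resampled
#'   sample).
#' @export
smooth_resample <- function(series, sg_window = 9L, sg_order = 2L,
                            factor = 10L) {
  series <- as.numeric(series)
  n <- length(series)
  if (sg_window %% 2L == 0L || sg_window <= sg_order)
    stop("sg_window must be odd and greater than sg_order")
  if (n <= sg_window) stop("series shorter than the smoothing window")
  if (factor < 1L) stop("factor must be >= 1")
  sm <- as.numeric(signal::sgolayfilt(series, p = sg_order, n = sg_window))
  if (factor == 1L) {
    rs <- sm
    tt <- seq_len(n)
  } else {
    tt <- seq(1, n, length.out = n * factor)
    rs <- stats::approx(seq_len(n), sm, xout = tt)$y
  }
  structure(list(raw = series, smoothed = sm, resampled = rs,
                 factor = as.integer(factor), frame_times = tt),
            class = "front_profile")
}

#' @export
print.front_profile <- function(x, ...) {
  cat(sprintf("Front profile: %d frames -> %d resampled samples (factor %d)\n",
              length(x$raw), length(x$resampled), x$factor))
  invisible(x)
}

# index of the resampled sample closest to a given frame
.sample_of_frame <- function(profile, frame) {
  n <- length(profile$raw)
  m <- length(profile$resampled)
  round(1 + (frame - 1) * (m - 1) / (n - 1))
}

#' Windowed trough-to-peak wave detection
#'
#' Partitions the resampled front profile, starting at the 7-somite frame,
#' into `n_waves` consecutive windows of one approximate clock period each
#' (`window_frames`, counted in pre-resampling frames). Within a window the
#' peak is the largest interior strict local maximum and the trough the
#' smallest interior strict local minimum; the amplitude is their intensity
#' difference. If either extremum is absent from a window (e.g. the profile
#' is monotone there), that wave's amplitude is set to zero. Amplitudes are
#' never negative.
#'
#' @param profile A [smooth_resample()] front profile.
#' @param window_frames Window length per wave, pre-resampling frames.
#' @param n_waves Number of consecutive waves wanted.
#' @param start_frame Frame at which wave 1 begins (the 7-somite stage).
#' @return A `wave_table` data frame: `wave_index, trough_frame, peak_frame,
#'   amplitude`. Trough/peak times are in fractional frame units (NA for
#'   zero-amplitude waves). Truncated with a warning when the profile holds
#'   fewer than `n_waves` full windows.
#' @export
detect_waves <- function(profile, window_frames, n_waves = 15L, start_frame) {
  stopifnot(inherits(profile, "front_profile"), window_frames >= 3L,
            n_waves >= 1L)
  y <- profile$resampled
  w_s <- as.integer(window_frames) * profile$factor
  s0 <- .sample_of_frame(profile, start_frame)
  if (s0 < 1L || s0 > length(y)) stop("start_frame outside the profile")
  n_fit <- (length(y) - s0 + 1L) %/% w_s
  if (n_fit < n_waves) {
    warning("profile holds only ", n_fit, " of ", n_waves,
            " requested windows; output truncated")
    n_waves <- n_fit
  }
  if (n_waves < 1L) stop("profile too short for a single detection window")
  out <- data.frame(wave_index = seq_len(n_waves), trough_frame = NA_real_,
                    peak_frame = NA_real_, amplitude = 0)
  for (k in seq_len(n_waves)) {
    idx <- (s0 + (k - 1L) * w_s):(s0 + k * w_s - 1L)
    w <- y[idx]
    i <- 2:(length(w) - 1L)  # window-edge samples are not extrema
    is_max <- w[i] > w[i - 1L] & w[i] > w[i + 1L]
    is_min <- w[i] < w[i - 1L] & w[i] < w[i + 1L]
    if (any(is_max) && any(is_min)) {
      pk <- i[is_max][which.max(w[i][is_max])]
      tr <- i[is_min][which.min(w[i][is_min])]
      out$amplitude[k] <- max(w[pk] - w[tr], 0)
      out$peak_frame[k] <- profile$frame_times[idx[pk]]
      out$trough_frame[k] <- profile$frame_times[idx[tr]]
    }
  }
  class(out) <- c("wave_table", "data.frame")
  out
}

#' Map wave indices to somite-boundary indices
#'
#' The first clock wave passing the determination front at the 7-somite
#' stage specifies the 11th somite boundary, so `boundary_index =
#' wave_index + 10`.
#'
#' @param waves A `wave_table` from [detect_waves()].
#' @return The table with a `boundary_index` column added.
#' @export
assign_boundaries <- function(waves) {
  stopifnot(is.data.frame(waves), "wave_index" %in% names(waves))
  waves$boundary_index <- waves$wave_index + 10L
  waves
}

#' Attach boundary phenotypes to detected waves
#'
#' Joins a wave table (with `boundary_index`) against a [boundary_table()]
#' on the boundary index, optionally restricted to one embryo and side,
#' labeling each wave's fated boundary intact, defected or unknown.
#'
#' @param waves Wave table with `boundary_index`.
#' @param table A [boundary_table()].
#' @param embryo_id,side Optional filters applied to `table` before the
#'   join.
#' @return The wave table with a `phenotype` column
#'   (`"intact"`/`"defected"`/`"unknown"`).
#' @export
pair_boundary_phenotypes <- function(waves, table, embryo_id = NULL,
                                     side = NULL) {
  stopifnot(is.data.frame(waves), "boundary_index" %in% names(waves),
            inherits(table, "boundary_table"))
  if (!is.null(embryo_id)) table <- table[table$embryo_id %in% embryo_id, ]
  if (!is.null(side)) table <- table[table$side %in% side, ]
  m <- match(waves$boundary_index, table$boundary_index)
  code <- table$phenotype[m]
  waves$phenotype <- ifelse(is.na(code), "unknown",
                            ifelse(code == 1L, "defected", "intact"))
  waves
}

#' Normalize wave amplitudes to the intact-boundary mean per experiment
#'
#' Each amplitude is divided by the mean amplitude of the waves preceding
#' intact boundaries within the same independent experiment, so the
#' intact-group mean of normalized amplitudes is exactly 1 per experiment.
#' Experiments without any intact boundary cannot be normalized; their
#' records get NA and a warning.
#'
#' @param waves Data frame with columns `experiment_id`, `amplitude`,
#'   `phenotype` (values `"intact"`/`"defected"`/`"unknown"`).
#' @return The input with a `normalized_amplitude` column.
#' @export
normalize_amplitudes <- function(waves) {
  stopifnot(is.data.frame(waves),
            all(c("experiment_id", "amplitude", "phenotype") %in% names(waves)))
  waves$normalized_amplitude <- NA_real_
  for (ex in unique(waves$experiment_id)) {
    sel <- waves$experiment_id == ex
    intact <- sel & waves$phenotype == "intact"
    if (!any(intact)) {
      warning("experiment ", ex,
              " has no intact-boundary amplitude; records left unnormalized")
      next
    }
    waves$normalized_amplitude[sel] <-
      waves$amplitude[sel] / mean(waves$amplitude[intact])
  }
  waves
}

#' Compare normalized amplitudes preceding intact vs defected boundaries
#'
#' Reports the group medians of normalized amplitude, the percent by which
#' the defected-group median falls below the intact one
#' (`100 * (1 - median_defected / median_intact)`), and the two-sided
#' Mann-Whitney rank-sum p-value.
#'
#' @param waves Data frame with `normalized_amplitude` and `phenotype`
#'   columns (waves with phenotype `"unknown"` or NA amplitude are dropped).
#' @return An `amplitude_comparison` list: `median_intact`,
#'   `median_defected`, `percent_less`, `p.value`, `n_intact`, `n_defected`.
#' @export
compare_amplitude_groups <- function(waves) {
  stopifnot(is.data.frame(waves),
            all(c("normalized_amplitude", "phenotype") %in% names(waves)))
  w <- waves[waves$phenotype %in% c("intact", "defected") &
               !is.na(waves$normalized_amplitude), ]
  a_int <- w$normalized_amplitude[w$phenotype == "intact"]
  a_def <- w$normalized_amplitude[w$phenotype == "defected"]
  if (!length(a_int)) stop("intact group is empty")
  if (!length(a_def)) stop("defected group is empty")
  med_i <- stats::median(a_int); med_d <- stats::median(a_def)
  p <- stats::wilcox.test(a_int, a_def, alternative = "two.sided",
                          exact = FALSE, correct = TRUE)$p.value
  structure(list(median_intact = med_i, median_defected = med_d,
                 percent_less = 100 * (1 - med_d / med_i), p.value = p,
                 n_intact = length(a_int), n_defected = length(a_def)),
            class = "amplitude_comparison")
}

#' @export
print.amplitude_comparison <- function(x, ...) {
  cat(sprintf(paste0("Normalized amplitude, intact (n = %d) vs defected",
                     " (n = %d) boundaries:\n"), x$n_intact, x$n_defected))
  cat(sprintf("  medians %.3f vs %.3f -> defected median %.1f%% less (p = %.3g)\n",
              x$median_intact, x$median_defected, x$percent_less, x$p.value))
  invisible(x)
}

#' Run the full amplitude pipeline on one kymograph
#'
#' Front location, 4-px profile extraction, Savitzky-Golay smoothing with
#' 10x resampling, windowed trough-to-peak detection from the 7-somite
#' frame, and boundary assignment, in one call.
#'
#' @param kymo A [kymograph()].
#' @param config An [analysis_config()].
#' @param psm_extent PSM length in pixels (scalar or per frame); defaults to
#'   the kymograph width.
#' @param experiment_id Identifier copied into the output rows.
#' @return A wave table with `experiment_id`, `wave_index`,
#'   `boundary_index`, trough/peak frames and `amplitude`.
#' @export
extract_wave_amplitudes <- function(kymo, config = analysis_config(),
                                    psm_extent = ncol(kymo$intensity),
                                    experiment_id = "exp1") {
  stopifnot(inherits(kymo, "kymograph"), inherits(config, "analysis_config"))
  traj <- locate_front(kymo, psm_extent, config$front_fraction)
  raw <- extract_front_profile(kymo, traj, config$profile_width_px)
  prof <- smooth_resample(raw, config$sg_window, config$sg_order,
                          config$resample_factor)
  waves <- detect_waves(prof, config$window_frames, config$n_waves,
                        kymo$seven_somite_frame)
  waves <- assign_boundaries(waves)
  waves$experiment_id <- experiment_id
  waves[, c("experiment_id", "wave_index", "boundary_index", "trough_frame",
            "peak_frame", "amplitude")]
}
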