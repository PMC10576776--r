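#' Parameters for the synthetic kymograph generator
#'
#' Describes a posterior-to-anterior raised-cosine traveling clock wave whose
#' per-cycle amplitude at the determination front is planted, plus additive
#' Gaussian noise. The generator contract: at any fixed position, the
#' noiseless trough-to-peak intensity range of cycle `c` equals
#' `amplitudes[c]`, which makes amplitude recovery directly testable.
#'
#' @param amplitudes Numeric vector of per-cycle amplitudes `A_c` (arb.
#'   units); its length sets the number of planted waves.
#' @param period_frames Clock period at the front, in frames; one wave
#'   occupies exactly this many frames.
#' @param n_px Spatial width in pixels (posterior at column 1).
#' @param n_frames Total frames; default fits all planted cycles after the
#'   7-somite frame plus half a period of padding.
#' @param frame_interval_min,px_size_um Acquisition metadata.
#' @param baseline Baseline intensity `B` (arb. units).
#' @param wavelength_px Spatial wavelength of the traveling wave, pixels.
#'   Wave speed is `wavelength_px / period_frames` px/frame (posterior to
#'   anterior).
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param front_fraction Determination-front position as a fraction of the
#'   PSM length from the posterior end, in (0, 1).
#' @param seven_somite_frame Frame index at which the first planted cycle
#'   starts.
#' @param temperature_label Metadata label.
#' @param seed RNG seed for the noise.
#' @return A `kymo_synth_params` list.
#' @export
kymo_synth_params <- function(amplitudes, period_frames = 12L, n_px = 120L,
                              n_frames = NULL, frame_interval_min = 5,
                              px_size_um = 2.6, baseline = 1,
                              wavelength_px = 80, noise_sd = 0.02,
                              front_fraction = 0.5, seven_somite_frame = 10L,
                              temperature_label = "21.5C", seed = 1L) {
  stopifnot(is.numeric(amplitudes), length(amplitudes) >= 1L,
            all(amplitudes >= 0), period_frames >= 4L, n_px >= 8L,
            baseline >= 0, wavelength_px > 0, noise_sd >= 0)
  if (front_fraction <= 0 || front_fraction >= 1)
    stop("front_fraction must lie strictly inside (0, 1)")
  n_cycles <- length(amplitudes)
  if (is.null(n_frames))
    n_frames <- seven_somite_frame + n_cycles * period_frames +
      ceiling(period_frames / 2)
  if (n_frames < seven_somite_frame + period_frames)
    stop("n_frames too small to contain one full cycle after the 7-somite frame")
  structure(list(amplitudes = amplitudes, period_frames = as.integer(period_frames),
                 n_px = as.integer(n_px), n_frames = as.integer(n_frames),
                 frame_interval_min = frame_interval_min, px_size_um = px_size_um,
                 baseline = baseline, wavelength_px = wavelength_px,
                 noise_sd = noise_sd, front_fraction = front_fraction,
                 seven_somite_frame = as.integer(seven_somite_frame),
                 temperature_label = temperature_label, seed = as.integer(seed)),
            class = "kymo_synth_params")
}

#' Synthesize a kymograph with planted per-cycle amplitudes
#'
#' Renders `I(x, t) = B + A_c(t) (1 + cos phi(x, t))/2 + e` with
#' `phi(x, t) = 2 pi ((t - t0)/T - (x - x_f)/lambda) - pi/2` and
#' `e ~ N(0, noise_sd^2)`: a kinematic wave traveling from the posterior
#' (column 1) toward the anterior, whose amplitude switches between planted
#' values `A_c` on period boundaries counted from the 7-somite frame `t0`.
#' The phase offset puts each cycle's peak a quarter period, and its trough
#' three quarter periods, into the cycle's window at the front position
#' `x_f`, so both extrema are interior to the detection window.
#'
#' @param kp A [kymo_synth_params()] object.
#' @return List with `kymograph` (a [kymograph()]) and `truth`
#'   (data frame `wave_index, amplitude` of the planted values).
#' @export
synthesize_kymograph <- function(kp) {
  stopifnot(inherits(kp, "kymo_synth_params"))
  n_cycles <- length(kp$amplitudes)
  t_rel <- seq_len(kp$n_frames) - kp$seven_somite_frame  # frames since t0
  cyc <- pmin(pmax(floor(t_rel / kp$period_frames) + 1L, 1L), n_cycles)
  x <- seq_len(kp$n_px) - 1
  x_f <- kp$front_fraction * (kp$n_px - 1)
  phase <- outer(2 * pi * t_rel / kp$period_frames,
                 2 * pi * (x - x_f) / kp$wavelength_px, `-`) - pi / 2
  mat <- kp$baseline + kp$amplitudes[cyc] * (1 + cos(phase)) / 2
  if (kp$noise_sd > 0) {
    set.seed(kp$seed)
    mat <- mat + matrix(stats::rnorm(length(mat), 0, kp$noise_sd),
                        nrow = nrow(mat))
  }
  list(kymograph = kymograph(mat, kp$frame_interval_min, kp$px_size_um,
                             kp$seven_somite_frame, kp$temperature_label),
       truth = data.frame(wave_index = seq_len(n_cycles),
                          amplitude = kp$amplitudes))
}
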