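test_that("front trajectory follows the stated fraction of PSM length", {
  k <- kymograph(matrix(0, 5, 250), 5, 2.6, 1)
  expect_equal(as.numeric(locate_front(k, 200, 0.5)), rep(100, 5))
  # linearly shrinking PSM: closed-form line, verified pointwise
  ext <- seq(200, 100, length.out = 5)
  expect_equal(as.numeric(locate_front(k, ext, 0.6)),
               seq(120, 60, length.out = 5))
  # near the posterior limit the trajectory pins to the posterior edge
  expect_lt(max(locate_front(k, 200, 1e-6)), 0.001)
  expect_error(locate_front(k, 200, 0), "front_fraction")
  expect_error(locate_front(k, 200, 1), "front_fraction")
  expect_error(locate_front(k, 300, 0.5), "exceeds")
  expect_error(locate_front(k, -1, 0.5), "positive")
})

test_that("front profile averages the enumerated band columns", {
  ramp <- matrix(rep(1:200, each = 3), nrow = 3)   # I(x) = column index
  k <- kymograph(ramp, 5, 2.6, 1)
  # width 1: exact column read-off at the round-half-up pixel
  expect_equal(extract_front_profile(k, rep(100.0, 3), width_px = 1),
               rep(100, 3))
  # width 4 at front 100.0: band columns 99,100,101,102 by direct enumeration
  expect_equal(extract_front_profile(k, rep(100.0, 3), width_px = 4),
               rep(mean(c(99, 100, 101, 102)), 3))
  # constant kymograph stays constant for any width
  kc <- kymograph(matrix(5, 3, 50), 5, 2.6, 1)
  expect_equal(extract_front_profile(kc, rep(10.2, 3), width_px = 4),
               rep(5, 3))
  # band clamped (with warning) when the front sits at the edge
  expect_warning(p <- extract_front_profile(k, rep(1, 3), width_px = 4),
                 "clamped")
  expect_equal(p, rep(mean(1:4), 3))
})

test_that("smoothing reproduces polynomials and factor 1 is the identity", {
  ramp <- 3 + 0.7 * (1:60)
  fp <- smooth_resample(ramp, sg_window = 9, sg_order = 2, factor = 1)
  expect_equal(fp$resampled, ramp, tolerance = 1e-10)
  noisy <- sin((1:60) / 5)
  fp1 <- smooth_resample(noisy, sg_window = 9, sg_order = 2, factor = 1)
  expect_identical(fp1$resampled, fp1$smoothed)
  expect_error(smooth_resample(ramp, sg_window = 8), "odd")
  expect_error(smooth_resample(ramp, sg_window = 3, sg_order = 4), "odd")
  expect_error(smooth_resample(1:5, sg_window = 9), "shorter")
})

test_that("smoothed values match explicit least-squares coefficients", {
  set.seed(6)
  t <- 1:80
  clean <- sin(2 * pi * t / 25)
  y <- clean + rnorm(80, 0, 0.1)
  fp <- smooth_resample(y, sg_window = 9, sg_order = 2, factor = 1)
  # independent oracle: projection row of the local quadratic LS fit
  A <- outer(-4:4, 0:2, `^`)
  w <- (solve(t(A) %*% A) %*% t(A))[1, ]   # evaluation at the window center
  for (i in c(5, 20, 41, 76))
    expect_equal(fp$smoothed[i], sum(w * y[(i - 4):(i + 4)]),
                 tolerance = 1e-10)
  # smoothing reduces the RMS deviation from the clean signal (interior)
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(rms((fp$smoothed - clean)[5:76]), rms((y - clean)[5:76]))
})

test_that("resampling re-grids uniformly at the stated factor", {
  y <- cumsum(rnorm(40))
  fp <- smooth_resample(y, factor = 10)
  expect_length(fp$resampled, 400)
  expect_equal(fp$frame_times[1], 1)
  expect_equal(fp$frame_times[400], 40)
  expect_lt(max(abs(diff(diff(fp$frame_times)))), 1e-12)
})

test_that("pure sinusoids yield exact trough-to-peak amplitudes", {
  W <- 12
  t <- 1:(1 + 16 * W)
  y <- 100 + 50 * sin(2 * pi * (t - 1) / W)
  # window-3 quadratic smoothing is exact interpolation; no resampling
  fp <- smooth_resample(y, sg_window = 3, sg_order = 2, factor = 1)
  waves <- detect_waves(fp, W, n_waves = 15, start_frame = 1)
  expect_equal(waves$amplitude, rep(100, 15), tolerance = 1e-10)
  # with 10x linear resampling the amplitude carries only the chordal
  # interpolation error of the 12-frame sampling (< 1%)
  fp10 <- smooth_resample(y, sg_window = 3, sg_order = 2, factor = 10)
  waves10 <- detect_waves(fp10, W, n_waves = 15, start_frame = 1)
  expect_equal(waves10$amplitude, rep(100, 15), tolerance = 1e-2)
})

test_that("monotone windows obey the zero-amplitude rule", {
  fp <- smooth_resample(1:40, sg_window = 3, sg_order = 2, factor = 10)
  waves <- detect_waves(fp, 12, n_waves = 3, start_frame = 1)
  expect_equal(waves$amplitude, rep(0, 3))
  expect_true(all(is.na(waves$peak_frame)))
  flat <- smooth_resample(rep(2, 40), sg_window = 3, sg_order = 2, factor = 10)
  expect_equal(detect_waves(flat, 12, 3, 1)$amplitude, rep(0, 3))
})

test_that("too-short profiles truncate with a warning", {
  y <- 100 + 50 * sin(2 * pi * (1:61) / 12)
  fp <- smooth_resample(y, sg_window = 3, sg_order = 2, factor = 10)
  expect_warning(w <- detect_waves(fp, 12, n_waves = 15, start_frame = 1),
                 "truncated")
  expect_lt(nrow(w), 15)
})

test_that("planted alternating amplitudes are recovered within 10%", {
  amps <- rep(c(1.0, 0.4), length.out = 15)
  kg <- synthesize_kymograph(kymo_synth_params(
    amplitudes = amps, period_frames = 20, noise_sd = 0.02, seed = 14))
  waves <- extract_wave_amplitudes(kg$kymograph,
                                   analysis_config(window_frames = 20))
  expect_equal(nrow(waves), 15)
  rel <- waves$amplitude / amps[waves$wave_index]
  expect_true(all(abs(rel - 1) < 0.10))
  # the high/low alternation pattern is recovered exactly
  expect_identical(waves$amplitude > 0.7, amps[waves$wave_index] == 1.0)
})

test_that("noiseless round trip matches planted amplitudes within 2%", {
  set.seed(15)
  amps <- runif(10, 0.4, 1.2)
  kg <- synthesize_kymograph(kymo_synth_params(
    amplitudes = amps, period_frames = 40, noise_sd = 0, n_px = 160,
    wavelength_px = 100))
  waves <- extract_wave_amplitudes(kg$kymograph,
                                   analysis_config(window_frames = 40,
                                                   n_waves = 10))
  expect_true(all(abs(waves$amplitude / amps - 1) <= 0.02))
})

test_that("amplitudes are scale-equivariant and shift-invariant", {
  amps <- rep(c(1.0, 0.4), length.out = 8)
  kp <- kymo_synth_params(amplitudes = amps, period_frames = 20,
                          noise_sd = 0.02, seed = 23)
  kg <- synthesize_kymograph(kp)
  cfg <- analysis_config(window_frames = 20, n_waves = 8)
  base <- extract_wave_amplitudes(kg$kymograph, cfg)
  scaled <- kg$kymograph; scaled$intensity <- scaled$intensity * 3.7
  shifted <- kg$kymograph; shifted$intensity <- shifted$intensity + 11
  w_scaled <- extract_wave_amplitudes(scaled, cfg)
  w_shifted <- extract_wave_amplitudes(shifted, cfg)
  expect_equal(w_scaled$amplitude, base$amplitude * 3.7, tolerance = 1e-9)
  expect_equal(w_shifted$amplitude, base$amplitude, tolerance = 1e-9)
  # normalized amplitudes are unchanged by positive scaling
  fate <- rep(c("intact", "defected"), 4)
  base$phenotype <- w_scaled$phenotype <- fate
  n_base <- normalize_amplitudes(base)
  n_scaled <- normalize_amplitudes(w_scaled)
  expect_equal(n_scaled$normalized_amplitude, n_base$normalized_amplitude,
               tolerance = 1e-9)
})

test_that("waves map to boundaries by index + 10", {
  waves <- data.frame(wave_index = c(1L, 7L, 15L))
  out <- assign_boundaries(waves)
  expect_identical(out$boundary_index, c(11L, 17L, 25L))
  all_w <- assign_boundaries(data.frame(wave_index = 1:15))
  expect_identical(all_w$boundary_index, 11:25)
  expect_false(any(duplicated(all_w$boundary_index)))
})

test_that("phenotype pairing joins on boundary index", {
  left <- matrix(0L, 1, 20); left[1, c(1, 5)] <- 1L   # boundaries 11, 15
  tab <- make_boundary_table(left, matrix(0L, 1, 20))
  waves <- assign_boundaries(data.frame(wave_index = 1:15))
  paired <- pair_boundary_phenotypes(waves, tab, embryo_id = "E01", side = "L")
  expect_equal(paired$phenotype[paired$boundary_index == 11], "defected")
  expect_equal(paired$phenotype[paired$boundary_index == 12], "intact")
  beyond <- assign_boundaries(data.frame(wave_index = 25L))  # boundary 35
  expect_equal(pair_boundary_phenotypes(beyond, tab)$phenotype, "unknown")
})

test_that("normalization fixes the intact-group mean to 1 per experiment", {
  w <- data.frame(experiment_id = "a",
                  amplitude = c(2, 2, 1),
                  phenotype = c("intact", "intact", "defected"))
  out <- normalize_amplitudes(w)
  expect_equal(out$normalized_amplitude, c(1, 1, 0.5))
  # all equal amplitudes normalize to 1
  w2 <- data.frame(experiment_id = "b", amplitude = rep(4, 6),
                   phenotype = rep(c("intact", "defected"), 3))
  expect_equal(normalize_amplitudes(w2)$normalized_amplitude, rep(1, 6))
  # two experiments with different intact means: both renormalize to 1 exactly
  set.seed(7)
  w3 <- data.frame(experiment_id = rep(c("x", "y"), each = 10),
                   amplitude = c(runif(10, 1, 2), runif(10, 4, 9)),
                   phenotype = rep(c("intact", "defected"), 10))
  out3 <- normalize_amplitudes(w3)
  for (ex in c("x", "y")) {
    sel <- out3$experiment_id == ex & out3$phenotype == "intact"
    expect_equal(mean(out3$normalized_amplitude[sel]), 1, tolerance = 1e-12)
  }
  # no intact boundary: unnormalizable, flagged
  w4 <- data.frame(experiment_id = "z", amplitude = 1:3,
                   phenotype = rep("defected", 3))
  expect_warning(out4 <- normalize_amplitudes(w4), "no intact")
  expect_true(all(is.na(out4$normalized_amplitude)))
})

test_that("amplitude group comparison reports the percent-less statistic", {
  w <- data.frame(normalized_amplitude = c(1, 1, 1, 0.6, 0.6),
                  phenotype = c(rep("intact", 3), rep("defected", 2)))
  cmp <- compare_amplitude_groups(w)
  expect_equal(cmp$percent_less, 40)
  same <- data.frame(normalized_amplitude = rep(c(1, 2, 3), 2),
                     phenotype = rep(c("intact", "defected"), each = 3))
  expect_equal(compare_amplitude_groups(same)$percent_less, 0)
  only_int <- data.frame(normalized_amplitude = 1, phenotype = "intact")
  expect_error(compare_amplitude_groups(only_int), "defected group")
})
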