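# shared fixtures, built in code at test time

# boundary table over boundaries 11..(10 + ncol) from per-side phenotype
# matrices (rows = embryos)
make_boundary_table <- function(left, right = left, condition = "fix") {
  stopifnot(all(dim(left) == dim(right)))
  n_b <- ncol(left)
  rows <- lapply(seq_len(nrow(left)), function(e) {
    data.frame(embryo_id = sprintf("E%02d", e),
               side = rep(c("L", "R"), each = n_b),
               boundary_index = rep(seq_len(n_b) + 10L, 2L),
               phenotype = c(left[e, ], right[e, ]))
  })
  boundary_table(do.call(rbind, rows), condition = condition)
}

# simulator tuned so each boundary defects i.i.d. with probability p
bernoulli_sim <- function(n_embryos, p, seed, n_cycles = 20L) {
  simulate_boundary_outcomes(clock_sim_params(
    n_cycles = n_cycles, mu = 0, sigma = 0.5,
    theta = threshold_for_defect_probability(p), env_scale = 1,
    n_embryos = n_embryos, seed = seed))
}

# Pearson r by the explicit product-moment sum formula (independent oracle)
pearson_by_formula <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# synthesize kymographs with planted per-wave fates at a given
# defected:intact amplitude-median ratio and run the full amplitude pipeline
planted_ratio_waves <- function(n_experiments, ratio = 0.6, seed = 1,
                                period_frames = 12L, noise_sd = 0.02,
                                n_waves = 15L, amp_sd = 0.1) {
  set.seed(seed)
  out <- vector("list", n_experiments)
  for (ex in seq_len(n_experiments)) {
    fate <- ifelse(stats::rbinom(n_waves, 1L, 0.45) == 1L,
                   "defected", "intact")
    amps <- exp(stats::rnorm(n_waves, 0, amp_sd)) *
      ifelse(fate == "defected", ratio, 1)
    kymo_seed <- sample.int(.Machine$integer.max - 1L, 1L)
    kg <- synthesize_kymograph(kymo_synth_params(
      amplitudes = amps, period_frames = period_frames,
      noise_sd = noise_sd, seed = kymo_seed))
    w <- extract_wave_amplitudes(
      kg$kymograph,
      analysis_config(window_frames = period_frames, n_waves = n_waves),
      experiment_id = sprintf("exp%02d", ex))
    w$phenotype <- fate[w$wave_index]
    w$planted <- amps[w$wave_index]
    out[[ex]] <- w
  }
  normalize_amplitudes(do.call(rbind, out))
}
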