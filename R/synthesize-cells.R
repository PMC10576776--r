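#' Parameters for the striped two-gene transcript-field generator
#'
#' Emulates the snapshot appearance of segmentation-clock transcription in a
#' fixed PSM: two to three stripes of RNA along the anteroposterior axis,
#' sampled as per-cell Poisson counts. Cell `i` at position `x_i` expresses
#' gene 1 with rate `b + lambda0 (1 + m cos(2 pi x_i / lambda + eta_i))` and
#' gene 2 with an additional fixed phase offset `Delta` plus its own
#' independent jitter, `eta` terms drawn N(0, kappa^2) per cell and gene.
#' `kappa = 0, Delta = 0` reproduces in-phase wild-type-like stripes; large
#' `kappa` decorrelates the genes as in clock mutants.
#'
#' @param n_cells Number of cells, placed uniformly in the PSM rectangle.
#' @param psm_length_um,psm_width_um PSM rectangle dimensions (x in
#'   `[0, length]`, posterior at 0; y in `[0, width]`).
#' @param stripe_wavelength_um Spatial stripe wavelength `lambda`.
#' @param modulation Stripe modulation depth `m` in \[0, 1\].
#' @param mean_count Mean expression rate `lambda0` (counts per cell).
#' @param phase_offset Inter-gene phase offset `Delta`, radians.
#' @param phase_jitter Per-cell phase jitter SD `kappa >= 0`, radians.
#' @param background Background count rate `b >= 0` added to both genes.
#' @param seed RNG seed.
#' @return A `cell_field_params` list.
#' @export
cell_field_params <- function(n_cells = 3000L, psm_length_um = 500,
                              psm_width_um = 100, stripe_wavelength_um = 150,
                              modulation = 0.9, mean_count = 50,
                              phase_offset = 0, phase_jitter = 0,
                              background = 0, seed = 1L) {
  stopifnot(n_cells >= 1L, psm_length_um > 0, psm_width_um > 0,
            stripe_wavelength_um > 0, mean_count >= 0)
  if (modulation < 0 || modulation > 1)
    stop("modulation depth must lie in [0, 1]")
  if (phase_jitter < 0) stop("phase_jitter must be >= 0")
  if (background < 0) stop("background must be >= 0")
  structure(list(n_cells = as.integer(n_cells), psm_length_um = psm_length_um,
                 psm_width_um = psm_width_um,
                 stripe_wavelength_um = stripe_wavelength_um,
                 modulation = modulation, mean_count = mean_count,
                 phase_offset = phase_offset, phase_jitter = phase_jitter,
                 background = background, seed = as.integer(seed)),
            class = "cell_field_params")
}

#' Synthesize a striped two-gene per-cell transcript field
#'
#' Draws cell positions uniformly in the PSM rectangle and Poisson counts
#' for both genes under the striped rate model of [cell_field_params()].
#'
#' @param cp A [cell_field_params()] object.
#' @return A [cell_table()].
#' @export
synthesize_cell_field <- function(cp) {
  stopifnot(inherits(cp, "cell_field_params"))
  set.seed(cp$seed)
  n <- cp$n_cells
  x <- stats::runif(n, 0, cp$psm_length_um)
  y <- stats::runif(n, 0, cp$psm_width_um)
  base_phase <- 2 * pi * x / cp$stripe_wavelength_um
  eta1 <- if (cp$phase_jitter > 0) stats::rnorm(n, 0, cp$phase_jitter) else 0
  eta2 <- if (cp$phase_jitter > 0) stats::rnorm(n, 0, cp$phase_jitter) else 0
  rate1 <- cp$background +
    cp$mean_count * (1 + cp$modulation * cos(base_phase + eta1))
  rate2 <- cp$background +
    cp$mean_count * (1 + cp$modulation * cos(base_phase + cp$phase_offset + eta2))
  cell_table(data.frame(
    cell_id = sprintf("C%05d", seq_len(n)),
    x_um = x, y_um = y,
    count_gene1 = stats::rpois(n, rate1),
    count_gene2 = stats::rpois(n, rate2),
    stringsAsFactors = FALSE
  ))
}
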