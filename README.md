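# segclock

Quantitative analysis of variable somite-segmentation phenotypes in
zebrafish segmentation-clock mutants.

## The problem and who this is for

Embryos mutant for the segmentation-clock genes *her1* or *her7* show
incomplete penetrance and variable expressivity: genetically identical
siblings raised in the same environment form different numbers of defective
somite boundaries, with intact and broken boundaries intermingled along the
axis. A parsimonious explanation is an **amplitude-threshold model**: each
clock cycle *c* at the determination front draws an oscillation amplitude

&nbsp;&nbsp;&nbsp;&nbsp;*A<sub>c</sub> = s · exp(μ + σZ<sub>c</sub>)*,&nbsp;&nbsp;&nbsp;*Z<sub>c</sub> ~ N(0, 1)* i.i.d.,

and the somite boundary fed by that cycle (boundary *c* + 10, since the
wave passing at the 7-somite stage specifies the 11th boundary) forms
intact iff *A<sub>c</sub> ≥ θ*. The per-cycle defect probability is then
Φ((ln θ − ln s − μ)/σ), and an unfavorable environment (low temperature,
hypoxia) acts through the multiplicative scale *s*, proportionally lowering
the count of supra-threshold cycles.

The package is for developmental biologists and quantitative-biology
analysts who score metameric binary phenotypes, extract oscillation
amplitudes from reporter kymographs, or measure spatial transcript
correlations, and want the whole chain — simulation, extraction,
statistics — reproducible and testable without any raw imaging data.

It provides four analysis layers plus generators:

* **Boundary statistics** — penetrance (an embryo with a single defected
  boundary on either side counts as defected), expressivity
  (defective-boundary counts per side), the Pearson correlation between
  consecutive-boundary phenotypes (11th–29th vs 12th–30th of each side) and
  between left and right sides (11th–30th), summarized with 0.1-binned
  normalized-frequency histograms, percent-change comparisons, and the
  standard tests (Mann–Whitney, Fisher exact, Kruskal–Wallis with Dunn's
  pairwise correction).
* **Kymograph amplitudes** — line-of-interest kymograph construction,
  determination-front trajectory at a fixed PSM fraction, 4-px line
  profile, Savitzky–Golay smoothing with 10× resampling, windowed
  trough-to-peak detection (12-frame windows at 21.5 °C, 7 at 26 °C; a
  window without an interior peak or trough scores amplitude zero),
  normalization to the per-experiment intact-boundary mean, and
  intact-vs-defected group comparison.
* **smFISH spatial correlation** — stripe-parallel slicing of per-cell
  two-gene transcript counts at a fixed stripe angle, background-subtracted
  slice means over the posterior 40–80 % of the PSM, and the spatial
  Pearson correlation of the two genes.
* **Synthetic data** — generators for all three data types under the
  amplitude-threshold model, with planted ground truth, so every stage is
  testable end to end.

## Worked example

```r
library(segclock)

# printed expressivity medians: 8 defects/side at 28 °C vs 13 at 21.5 °C
expressivity_change(8, 13)$percent
#> [1] 63

# simulate 111 embryos whose boundaries defect i.i.d. with probability 0.45
params <- clock_sim_params(n_embryos = 111,
                           theta = threshold_for_defect_probability(0.45),
                           seed = 42)
sim <- simulate_boundary_outcomes(params)
print(sim)
#> Stochastic amplitude-threshold clock simulation
#>   111 embryos x 2 sides x 20 cycles (boundaries 11-30)
#>   amplitude ~ 1 * lognormal(mu = 0, sigma = 0.5), theta = 0.939
#>   analytic defect probability: 0.4500; empirical: 0.4401

defect_counts(sim$boundary_table)
#> Defective boundaries per side (boundaries 11-30)
#>   condition n_sides median q1 q3     mean
#> 1       sim     222      9  7 10 8.801802

summarize_correlations(consecutive_correlations(sim$boundary_table))
#> Correlation summary: mean r = -0.0389 over 222 units (0 undefined excluded)
summarize_correlations(left_right_correlations(sim$boundary_table))
#> Correlation summary: mean r = -0.0160 over 111 units (0 undefined excluded)
```

Both mean correlations sit near zero: under the threshold model consecutive
somites — and the two sides of one embryo — fail independently, like coin
flips, which is the signature observed in scored mutant clutches.

```r
# plant alternating high/low wave amplitudes, recover them from the image
kg <- synthesize_kymograph(kymo_synth_params(
  amplitudes = rep(c(1, 0.4), length.out = 15),
  period_frames = 12, noise_sd = 0.02, seed = 9))
waves <- extract_wave_amplitudes(kg$kymograph,
                                 analysis_config(temperature = "21.5C"))
waves$phenotype <- rep(c("intact", "defected"), length.out = 15)
compare_amplitude_groups(normalize_amplitudes(waves))
#> Normalized amplitude, intact (n = 8) vs defected (n = 7) boundaries:
#>   medians 0.995 vs 0.414 -> defected median 58.4% less (p = 0.00146)
```

The detector recovers the planted 1.0 : 0.4 amplitude alternation from the
noisy synthetic kymograph; the defected-group median is the planted ~60 %
below the intact one.

```r
# in-phase striped two-gene field: spatial correlation near 1
cells <- synthesize_cell_field(cell_field_params(seed = 3))
smfish_spatial_correlation(cells, slice_config(psm_length_um = 500,
                                               psm_width_um = 100))
#> [1] 0.9996524
```

A command-line wrapper for whole runs (simulate / analyze / validate from a
YAML or JSON config) is installed at `inst/cli/segclock.R`.

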