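---
title: "Methods: the amplitude-threshold model and its extraction pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the amplitude-threshold model and its extraction pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segclock)
```

## The generative model

Variable segmentation phenotypes in clock mutants are modeled as
independent per-cycle threshold failures. For each embryo side, clock cycle
$c$ draws an oscillation amplitude

$$A_c = s \, e^{\mu + \sigma Z_c}, \qquad Z_c \sim \mathcal N(0,1)
\text{ i.i.d.},$$

and the boundary specified by that cycle (boundary $c + 10$) is intact iff
$A_c \ge \theta$. The per-cycle defect probability has the closed form
$\Phi\!\left((\ln\theta - \ln s - \mu)/\sigma\right)$, which
`analytic_defect_probability()` implements and the test suite uses as a
Monte-Carlo oracle for the simulator.

Model assumptions, and why they were chosen:

* **Log-normal amplitudes.** No amplitude distribution is established
  empirically; we need positive support and a multiplicative noise
  structure, which is the standard picture for gene-expression
  variability. $\mu$ and $\sigma$ stay free parameters. Only defect
  *fractions* are constrained by observation, so $(\mu, \sigma, \theta)$
  are identifiable only through $\Phi((\ln\theta-\ln s-\mu)/\sigma)$; the
  defaults $\mu = 0$, $\sigma = 0.5$, $\theta = 1$ are a convenient
  parameterization, not an estimate.
* **Multiplicative environment.** The environment factor $s > 0$ scales
  amplitude. This makes "worse environment $\Rightarrow$ fewer
  supra-threshold cycles" hold monotonically for every $\theta$, which an
  additive shift would not guarantee sign-safely. A property test verifies
  the monotonicity on a grid with common random numbers.
* **Full independence.** Cycle-to-cycle and left–right draws are
  independent — that is the empirical finding the statistics layer is
  designed to detect, and the null the correlation envelopes are tested
  against. The generator exposes no correlation parameter because every
  analysis here targets the independent case.
* **Seeding.** One root seed deterministically spawns per-embryo child
  seeds, so an embryo's draws do not depend on how many embryos precede
  it.

The simulator is deliberately phenomenological: it draws amplitudes rather
than integrating the her1/her7 delayed-negative-feedback oscillator, and it
does not model PSM growth, cell movement, or 3-D tissue structure. Passing
tests therefore demonstrate correctness of the *analysis chain*, not of any
mechanistic claim about how amplitudes arise.

## Synthetic kymographs

`synthesize_kymograph()` renders

$$I(x,t) = B + A_{c(t)}\,\frac{1 + \cos\varphi(x,t)}{2} + \varepsilon,
\qquad \varphi(x,t) = 2\pi\!\left(\frac{t - t_0}{T} -
\frac{x - x_f}{\lambda}\right) - \frac{\pi}{2},$$

a raised-cosine wave traveling posterior $\to$ anterior, with
$\varepsilon \sim \mathcal N(0, \text{noise\_sd}^2)$ and the cycle index
$c(t)$ advancing every $T$ frames from the 7-somite frame $t_0$. The
raised-cosine waveform was chosen because its noiseless trough-to-peak
range at any fixed position equals the planted $A_c$ exactly, making
recovery testable against ground truth. The $-\pi/2$ phase offset places
each cycle's peak a quarter period, and its trough three quarters, into the
cycle's own window at the front position, so both extrema are interior to
the detection window that tiles the same grid.

Default conditions mirror the 21.5 °C imaging setup the analysis targets:
5-minute frames, a 12-frame (60-minute) clock period, 15 waves covering
boundaries 11–25, pixel size 2.6 µm, and noise_sd 0.02 on amplitudes of
order 1.

## Amplitude extraction

The pipeline follows the kymograph procedure step by step:

1. **Front trajectory** (`locate_front`): position $= f \times$ PSM extent,
   in pixels from the posterior edge; $f$ defaults to 0.5 because segmental
   commitment occurs around the middle of the PSM. The stage-dependent
   front ratio used with real embryos is not reproduced; per-frame PSM
   extents can be supplied instead.
2. **Line profile** (`extract_front_profile`): mean over a 4-px band
   centered on the round-half-up pixel of the (fractional) front position;
   for even widths the band extends one extra column anteriorly. Bands are
   clamped at the image edge with a warning.
3. **Smoothing and resampling** (`smooth_resample`): Savitzky–Golay
   least-squares smoothing, then linear interpolation onto a uniform grid
   of 10× the frame count. The filter's window and order are not dictated
   by the procedure being reproduced; the defaults (window 9 frames,
   order 2) suppress noise of the magnitude the generator plants while
   attenuating a 12-frame sinusoid by under 10 %. Attenuation is linear,
   so it cancels in normalized (ratio) statistics; tests that assert
   absolute planted-amplitude recovery use slower synthetic periods
   (20 or 40 frames), where the stated tolerances reflect interpolation
   error rather than filter attenuation.
4. **Wave detection** (`detect_waves`): the resampled profile is
   partitioned, starting at the 7-somite frame, into `n_waves` contiguous
   windows of one approximate clock period (12 frames at 21.5 °C, 7 at
   26 °C — `window_frames` is counted pre-resampling and multiplied by the
   resampling factor internally). Within a window, peak = largest interior
   strict local maximum, trough = smallest interior strict local minimum,
   amplitude = peak − trough; if either is missing the amplitude is zero.
   Contiguous tiling (rather than per-wave sliding) is an assumption made
   explicit here: the generator and the detector share the same grid, and
   with real data the window should match the local period. Two
   consequences of the strict-extremum rule are deliberate: monotone or
   flat windows score zero, and exact plateau ties — which arise only in
   noiseless synthetic profiles whose peak falls exactly between frames —
   are not extrema.
5. **Boundary mapping and normalization**: wave $k$ specifies boundary
   $k + 10$; each amplitude is divided by the mean amplitude of
   intact-fated waves of the same experiment, making the intact-group mean
   exactly 1 per experiment and removing between-experiment intensity
   scale. Experiments with no intact boundary are flagged unnormalizable
   rather than silently dropped.

Amplitudes are scale-equivariant and shift-invariant in the raw intensity,
and normalized amplitudes are scale-invariant; both are property-tested.

## Boundary statistics

* **Penetrance**: an embryo with a single defected boundary on either side
  is scored defected. **Expressivity**: defected-boundary count per side
  over the scoring range (default boundaries 11–30).
* **Correlations**: Pearson r between the lagged phenotype copies
  (11th–29th vs 12th–30th) per side, and between matched left/right
  vectors per embryo. Constant vectors make r undefined; such units are
  excluded from means and histograms and counted, since silently treating
  them as zero would bias the envelope. NA phenotypes use pairwise-complete
  deletion (at most 2 per side). Histograms use 0.1-wide half-open bins
  with a closed rightmost bin so r = 1 is representable.
* **A finite-sample caveat** worth stating analytically: the Pearson
  correlation between overlapping lagged copies of an i.i.d. sequence of
  length 20 (19 pairs) has expectation near $-1/19 \approx -0.05$, so even
  perfectly independent boundary outcomes yield a mean per-side r of
  magnitude about 0.05 — the same magnitude reported for scored mutant
  clutches. The per-side signed mean is kept as the headline statistic
  because it matches the established scoring procedure;
  `consecutive_correlations(..., pooled = TRUE)` exposes the pooled-pairs
  alternative, whose bias is smaller by two orders of magnitude, for users
  who want the nearly unbiased version of the same question.
* **Percent changes** are rounded half-up to integer percent (62.5 → 63).
* **Tests**: two groups — two-sided Mann–Whitney; penetrance contrasts —
  two-sided Fisher exact on the 2×2 table; three or more groups —
  Kruskal–Wallis with Dunn's rank-based pairwise z comparisons
  (tie-corrected, Holm-adjusted). Dunn's procedure is implemented in the
  package; the omnibus and two-group tests delegate to `stats`.
  Heteroscedastic ANOVA variants (Welch/Brown–Forsythe with Games–Howell)
  are intentionally not computed.

## smFISH spatial correlation

Cells are projected onto the normal of the stripe direction
($u = x\sin\alpha + y\cos\alpha$, $\alpha$ the stripe angle to the
anteroposterior axis; 90° means stripes perpendicular to the axis) and
assigned to slices of fixed thickness by `floor(u / thickness)` — a
partition, property-tested as such. Per slice and gene the mean of
background-subtracted counts, clamped at zero (negative expression being
meaningless), is taken; slices whose center fraction lies in the closed
interval [0.4, 0.8] of PSM length from the posterior end are retained, and
the spatial Pearson correlation of the two genes' slice-mean vectors is
reported. Fewer than 3 retained slices is an error rather than a number.
The slice thickness is not pinned down by the source procedure; the default
is 10 µm (about one cell diameter), and the fixed-angle mode corresponds to
the mutant analysis — a per-position angle function for wild-type tissue is
out of scope. The cell-field generator plants cosine-modulated Poisson
counts with per-cell, per-gene phase jitter $\kappa$; $\kappa = 0$,
$\Delta = 0$ emulates coherent in-phase stripes and large $\kappa$ the
mutant decorrelation, with median correlation degrading monotonically in
$\kappa$ (tested with common random numbers). What the generator does not
emulate: cell-size variation, segmentation errors, optical crowding, or the
anterior–posterior period gradient — so passing tests validate the metric,
not any claim about real mutant tissue values.

## Pipeline and problem sizes

`run_simulation_study()` writes a fixed file manifest (boundary TSV,
amplitude truth TSV, 16-bit TIFF kymograph + JSON sidecar + planted wave
truth, cell CSV, provenance JSON) and is byte-deterministic given config
and seed; `run_full_analysis()` consumes only those documented formats and
is idempotent. The test suite and the acceptance script run at desk scale
chosen to keep Monte-Carlo standard errors well inside the asserted
envelopes: 111 embryos (222 sides) for the correlation nulls, 500 embryos
(20 000 draws) for the simulator-vs-closed-form check, 14 synthetic
experiments × 15 waves (210 waves) for the end-to-end amplitude-deficit
recovery, and 20-seed ensembles for the smFISH field checks.

## Known limitations

* Amplitude distribution shape and threshold value are unconstrained by
  data; only defect probabilities are meaningful.
* The detector assumes the window tiles the profile from the 7-somite
  frame; strong period drift within an experiment would misalign windows.
* Savitzky–Golay attenuation biases *absolute* amplitudes low by a few
  percent at clock-period-scale windows; ratio statistics are unaffected.
* The smFISH layer consumes per-cell counts; spot detection and 3-D
  segmentation quality are upstream of this package.
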