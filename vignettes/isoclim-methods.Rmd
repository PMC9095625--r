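---
title: "Methods: isotope chronologies, transfer functions, and multi-proxy composites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotope chronologies, transfer functions, and multi-proxy composites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoclim)
```

# The reconstruction model

`isoclim` implements a classical proxy-based climate reconstruction
workflow. Its underlying statistical model is deliberately simple: a site
chronology $x_y$ (the mean per-mil isotope value of all trees covering
year $y$) is assumed linearly related to a seasonal climate variable $c_y$,

$$ c_y = \beta_0 + \beta_1 x_y + \varepsilon_y, $$

with the climate variable always the *response* and the proxy the
predictor. The regression is fitted by OLS on the instrumental overlap and
applied over the full proxy span. This direction — climate on proxy —
yields unbiased reconstructions when the calibration noise sits in the
observed climate series (station measurement error, local heterogeneity),
and attenuated amplitudes when the noise sits in the proxy; we accept this
asymmetry rather than applying variance-scaling corrections, and the
synthetic end-to-end tests are constructed accordingly. No
autocorrelation-adjusted effective sample size is used for p values: the
degrees of freedom reported are the raw pair `(1, n-2)`.

Before any calibration, the per-tree carbon series pass through three
corrections, in this order:

1. **Pyrolysis rescaling**, $\delta^{13}C = 1.1142\,\delta^{13}C_{raw} +
   1.45$: a fixed affine map correcting the reactor-carbon contribution of
   high-temperature pyrolysis. Being affine, it commutes with pooling —
   `correct_pyrolysis()` of a chronology equals the chronology of corrected
   trees, which the test suite asserts. It is off by default in the
   pipeline because synthetic (and most archived) values are already on
   the corrected scale.
2. **Suess correction**: the industrial-era decline of atmospheric
   $\delta^{13}C$-of-CO$_2$ is removed by subtracting the atmospheric
   anomaly relative to a baseline year, default 1800 CE, the conventional
   onset of the fossil-fuel signal. Years before the baseline are
   untouched. The correction *adds* up to the total decline (about 2 per
   mil by 2016) to recent values.
3. **Juvenile exclusion**: the first 30 rings of every tree are dropped.
   Age-related trends concentrate in the earliest rings; 30 is the
   conventional exclusion span and is configurable.

## Pooling and replication

Physical pooling of five trees' rings into one measured sample is emulated
as an equal-weight arithmetic mean: mass weights are unknowable in silico,
and downstream analysis treats the pooled value as *the* chronology value
either way. Per-year replication statistics (n, SD, SE = SD/√n) are kept
alongside the mean; the whole-period summary SD/SE are computed on the
annual mean series, not the tree-level pool, matching how whole-period
uncertainties are conventionally quoted.

Replication quality uses the mean pairwise inter-series correlation
$\bar r$ and the Express Population Signal in the Wigley form

$$ \mathrm{EPS} = \frac{N\bar r}{N\bar r + (1-\bar r)}, $$

which is monotone in both $N$ and $\bar r$ and exceeds the conventional
0.85–0.9 robustness bar for, e.g., $\bar r = 0.8,\ N = 8$
(EPS ≈ 0.97). Pairs must overlap by at least 10 years to contribute to
$\bar r$.

## Anomalies and extremes

Extremes are classified on z-scores against the full-period mean and SD —
a fixed baseline, not a moving window — because published σ-anomalies are
quoted relative to the whole analysed period. Thresholds are configurable
(± 2.5σ for precipitation extremes, ± 3σ for isotope records are the
conventional choices). `implied_baseline()` inverts two printed
(value, σ) pairs back to the baseline mean and SD, which is useful for
consistency-checking published anomaly tables; published pairs are rounded,
so only jointly consistent pairs reproduce the printed SD.

# Verification statistics

Split-period verification fits on a calibration window (default
1970–2009) and predicts a disjoint verification window (default
1930–1969). Beyond the two correlations, the report carries:

* **RE and CE**: one minus the error sum of squares over the verification
  window, normalized by the squared deviations of the observations from
  the calibration mean (RE) or the verification mean (CE). Since the
  verification mean minimizes its own sum of squares, RE ≥ CE
  algebraically on *every* input — the suite property-tests this on random
  series. Positive values indicate skill beyond climatology; RE = 1 for a
  perfect prediction and RE = 0 for the calibration-mean predictor, by
  construction.
* **Durbin–Watson** of the calibration residuals,
  $\sum(e_t-e_{t-1})^2/\sum e_t^2$: near 2 for white residuals, with the
  closed form $4(n-1)/n$ on alternating ±1 residuals serving as an exact
  test oracle.
* **Gleichläufigkeit** $K_s$: the fraction of year-to-year first
  differences with agreeing sign. Ties are not discussed in most published
  uses; we adopt the standard dendro convention that a zero difference on
  either side contributes ½. $K_s$ is symmetric and invariant under
  positive affine transforms of either series (not under general monotone
  transforms, which can create or destroy ties).
* **First-difference test**: Pearson r between $\Delta$obs and
  $\Delta$rec with its F and p. Differencing removes constants and shared
  trends, so this isolates high-frequency agreement.

Missing years inside windows are handled by pairwise-complete deletion
with a hard floor of 10 paired years.

# Reconstruction choices

* **Uncertainty band**: the flat regression standard error of estimate,
  not prediction intervals that widen away from the calibration mean. This
  matches the conventional flat SE band of published reconstruction plots
  and understates uncertainty for proxy values far outside the calibration
  range — a known limitation, stated rather than hidden.
* **Smoothing**: a centered Hamming window
  ($w_k = 0.54 - 0.46\cos(2\pi k/(M-1))$, normalized), width 101 for
  centennial-scale trends. At the edges the window is truncated and the
  remaining weights renormalized — no padding, no shortened output — so
  smoothed series span the full period. The smoother is linear, leaves
  constants fixed, and never increases variance. For decadal-scale
  comparisons the same operation with width 11 approximates a "10-year"
  average with the nearest odd centered window; a trailing-block variant
  can be had by block-averaging through `harmonize_proxies()`.
* **Epochs**: the shipped definitions are LALIA 516–800, MWP 800–1300,
  LIA 1400–1900, RP 1900–2016 CE. The 1300–1400 gap belongs to no epoch
  and stays unassigned; epoch tables are explicit user inputs because
  published epoch-contrast baselines (e.g. "the preceding 1490 years") are
  often not fully specified.
* **Trends** are OLS slopes on year; only p < 0.05 slopes are flagged,
  and the type-I rate of that flag is itself calibrated in the test suite.

# Multi-proxy composites

Annual tree-ring records and decadal lake-sediment records are combined
by harmonizing onto a common grid. The default upsamples decadal records
to annual by linear interpolation between record years; the alternative
block-averages annual records into complete decades. Published regional
reconstructions report annual-resolution skill against station data, which
implies upsampling, but no alignment rule is ever stated — the choice is
therefore explicit and configurable here, and interpolation was chosen as
the rule that preserves the decadal record's low-frequency content without
inventing high-frequency variance.

The composite model is OLS on predictors z-scored with
calibration-window means and SDs only (no leakage from the reconstruction
period); applying the model over the full span uses the stored scaling. A
condition-number guard (10⁶) rejects collinear predictor sets and names
the most correlated pair.

Per-predictor explained-variance shares use the LMG decomposition: the
incremental R² of each predictor averaged over all orderings in which
predictors can enter, computed by subset enumeration (guarded at 8
predictors) and normalized to 100% of explained variance. LMG was chosen
because published share tables that sum to exactly 100 are consistent with
a normalized decomposition, while the method behind such tables is
typically unstated; since shares that do *not* sum to 100 also occur in
the literature, the raw marginal R² (predictor alone) and last-entry
incremental R² (predictor after all others) are reported side by side.
For mutually orthogonal predictors LMG reduces to marginal R² ratios
(0.30/0.10 → 75%/25%), which the suite verifies against a closed form, and
the implementation is checked to 1e−9 against explicit enumeration of all
orderings at three predictors.

# The synthetic generator

The generator exists so that every stage is testable end to end without
external data, and its defaults *are* the study conditions the package
targets:

* **Climate**: monthly temperature = seasonal cosine cycle (annual mean
  −2.3 °C, half-amplitude 15.8 °C → July ≈ 13.5 °C) + AR(1) anomalies
  (coefficient 0.3 — weak interannual memory typical of summer
  temperature — marginal SD 1.5 °C) + optional linear trend (default 0).
  Monthly precipitation is gamma (shape 2: right-skewed totals without
  zero inflation) around an April–October wet-season profile with the
  July mean pinned (30 mm) and the annual total closed at 142.6 mm.
  VPD and sunshine are derived from temperature with additive noise so
  monthly screening has a full four-variable menu.
* **Trees**: per tree and year,
  $\delta^{13}C = \alpha + \beta_P P_{Jul} + \beta_S T_{Sep,y-1} +
  a(y) + o_t + \eta_y + \epsilon_{ty}$ and analogously
  $\delta^{18}O = \alpha' + b_T T_{Jul} + b'_S T_{Sep,y-1} + o'_t +
  \eta'_y + \epsilon'_{ty}$, where $a(y)$ is the atmospheric Suess anomaly
  (embedded so the correction stage has something real to remove), $o_t$
  are constant tree offsets, $\eta$ shared year noise and $\epsilon$
  tree-level noise. Coupling and noise defaults
  ($\beta_P = -0.02$ ‰/mm, $b_T = 0.45$ ‰/°C,
  $\beta_S = -0.19$, $b'_S = +0.26$ ‰/°C; year noise 0.55/0.75 ‰, tree
  noise 0.40/0.50 ‰, offsets 0.30 ‰) were derived once from the variance
  budget so that the site-level couplings match the published
  calibration correlations (δ¹³C–July precipitation ≈ −0.58,
  δ¹⁸O–July temperature ≈ 0.64, previous-September ≈ −0.38/+0.36) and the
  chronology means/SDs sit near the published whole-period statistics
  (−22.04 ± 0.75 ‰, ≈ 27.1 ± 1.15 ‰). Proxy noise magnitudes are not
  published; these are calibrated to the printed correlations, not derived
  from fractionation theory.
* **Stand structure**: lifespans are uniform around 350 years (± 100);
  a sequential backbone forces ≥ 30-year post-juvenile pairwise overlaps
  so chronology coverage has no gaps, and remaining trees are scattered
  uniformly. An exponentially decaying juvenile depletion (1.5 ‰ over the
  first 30 rings) gives the exclusion stage something to remove. Note that
  trees only live within the configured years, so a chronology meant to
  span 516–2016 should be simulated from 486 (as the acceptance script
  does).
* **Lake and ring proxies**: Co/Inc and Rb/Sr are affine in decadal-mean
  JJA precipitation, Ca/Ti/Br/Sr in decadal-mean JJA temperature, TRW and
  MXD in annual JJA temperature, each with additive noise sized for
  single-proxy correlations near 0.6–0.75 against their drivers.

**What passing tests do and do not show.** The generator is linear with
Gaussian noise and stationary couplings. Real isotope series carry
nonlinear and time-varying climate responses (e.g. permafrost-thaw and
VPD modulation of the oxygen signal), age structure beyond a single
juvenile trend, laboratory error, and dating uncertainty in sediment
cores — none of which are emulated. Passing parameter-recovery tests
demonstrates that the *pipeline arithmetic* is correct and unbiased under
its own assumptions, not that those assumptions hold for any particular
site. Headline regional magnitudes (a ~49% precipitation decline, ~2 °C
recent warming) require the real archived proxy and station data; on
synthetic data the package verifies the arithmetic that produces such
numbers (percent-change and epoch contrasts are exact on constructed
series), not the numbers themselves.

# Numerical and degenerate-input conventions

* Determinism: each simulator draws from its own stream derived from the
  configured seed, and restores the caller's RNG state afterwards.
* Zero-variance inputs error loudly (`fit_transfer`, `classify_anomalies`,
  `durbin_watson`) rather than returning NaN.
* Window floors: 10 paired years everywhere a correlation or regression
  is fitted; first differences need 3; Gleichläufigkeit needs 2.
* The drought index is a pluggable monthly function defaulting to
  De Martonne $12P/(T+10)$ averaged over May–July; published drought
  indices differ, and any reported index correlation depends on this
  choice.
* Test problem sizes: Monte-Carlo checks run at 20–500 seeds with stands
  of 5–12 trees over 80–150 years, and single runs at full study scale
  (42 trees, 1501 years). These sizes were chosen to put Monte-Carlo
  error well inside the asserted bands.

# Known limitations

Flat SE bands understate far-from-calibration uncertainty; no ensemble or
bootstrap transfer uncertainty; no ring-width detrending (TRW/MXD enter as
finished chronologies); no age-model uncertainty for decadal records; raw
(unadjusted) degrees of freedom in significance tests; physical pooling
emulated as an unweighted mean.
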