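---
title: "Counting membrane-receptor subunits: photobleaching steps and PIE-FCCS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting membrane-receptor subunits: photobleaching steps and PIE-FCCS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligocount)
```

oligocount implements the two complementary single-molecule readouts used to
decide whether a membrane receptor is a monomer, a dimer, or something
larger: (i) counting photobleaching steps of single fluorescent spots in
TIRF movies, inverted through a binomial dark-fluorophore model, and (ii)
pulsed-interleaved-excitation fluorescence cross-correlation spectroscopy
(PIE-FCCS), which measures the fraction of green- and red-labelled
molecules that diffuse together. Every stage of both pipelines can be run
against synthetic data with known ground truth; this vignette explains the
models, the defaults, and the choices made where the design was open.

## 1. Photobleaching step counting

### The measurement

A receptor fused to a fluorescent protein appears in TIRF as a
diffraction-limited spot. Under constant illumination each fluorophore
bleaches irreversibly at a constant per-frame hazard, so the spot intensity
decreases in discrete steps; the number of steps lower-bounds the number of
tagged subunits in the spot. Typical conditions — which the synthetic
generator reproduces as defaults — are 500–800 frames at 20 Hz over a
13 × 13 µm field, spot densities of 1–5 molecules/µm², and EMCCD-like noise
modelled as Poisson shot noise plus Gaussian read noise (no explicit
gain-register model; step detection only needs the second-order statistics).

### Why observed steps undercount subunits

Two corrections stand between the step histogram and the stoichiometry:

*Dark fluorophores.* A fraction `p_dark` of fluorescent-protein tags never
matures; for EGFP-class tags this is 25–35%, and 0.30 is the package
default. An n-mer therefore shows k visible steps with probability
`C(n,k) (1-p)^k p^(n-k) / (1 - p^n)` (conditioned on the spot being visible
at all) — `step_count_pmf()`. A tetramer at `p_dark = 0.3` most often shows
three or fewer steps.

*Random colocalization.* Two non-interacting monomers closer than the
diffraction limit look like one two-step spot. For molecules placed by a
Poisson process at density λ and an unresolvable-pair radius r, the
fraction of spots that are both-visible pairs is, to leading order in the
crowding parameter λπr²,

    (λ π r² / 2) (1 - p_dark)²            — expected_pair_fraction()

valid while λπr² ≪ 1 (the function refuses beyond 0.5). Note the
normalization: this counts both-visible pairs per spot *including spots
whose fluorophores are all dark*. Conditioning the denominator on visible
spots — what an experiment literally tallies — multiplies the value by
roughly 1/(1-p_dark); `coloc_two_step_mc()` reports both normalizations.
At 4 µm⁻², r = 0.1 µm and `p_dark = 0.3` the per-spot value is ≈3.1%,
matching the ~3% two-step fraction measured for monomer-control proteins,
which is the baseline subtracted from receptor histograms
(`subtract_baseline()`, default 0.03). The subtraction moves two-step mass
to one-step, because those spots really are two monomers; removing the
spots entirely is available via the bootstrap/manual path but not the
default, since the fraction-shift reading keeps the analyzed-spot count
fixed.

### Automated step counting

The paper-era practice of manual counting is replaced by penalized
least-squares changepoint segmentation (optimal partitioning with PELT
pruning, compiled): the per-changepoint penalty is
`penalty × σ̂² log n` with `penalty = 3` and σ̂ the robust noise SD from
the median absolute first difference. Only *downward* changes of at least
`min_step_sd = 3` noise SDs are retained — photobleaching is irreversible,
so upward transitions are blinking or noise. Spots are treated as immobile
(the experimental protocols anchor receptors to the glass); there is no
tracking. Traces whose final level stays more than two noise SDs above
baseline have not fully bleached; by default they are classified by the
steps observed and flagged `censored` (rejection is available via
`censored = "reject"`). At a step-to-noise ratio of 5 the detector assigns
the correct in-window step count to ≈98% of spots; residual errors are
near-coincident bleach events merging into one step.

### Censoring-aware inversion

With a bleach hazard of 0.005/frame and 500 frames, a fluorophore bleaches
inside the movie with probability q = 1 − 0.995⁵⁰⁰ ≈ 0.918. The ~8% of
fluorophores that outlive the movie contribute intensity but no step, which
deflates multistep fractions by several points — far more than the
detector's own error. `predict_categories()` therefore folds q into the
forward model: observed steps follow a binomial with per-fluorophore
success probability (1−p_dark)·q, zero-step spots drop out, and colocalized
pairs contribute `Binom(2, q)` steps. `fit_mixture()` inverts this model by
maximum likelihood on the weight simplex (deterministic multi-start
Nelder–Mead in softmax coordinates; a golden-section search when only two
sizes compete). The printed histograms of any finite recording carry the
same censoring, so the censoring-aware inversion is the faithful one;
`detect_prob = 1` recovers the ideal-counting model.

Identifiability is honest rather than optimistic: three observed categories
(one, two, ≥3 steps) cannot pin four mixture weights. The default support
{1, 2, 4, 6} reflects the dimer/"multimer of dimers" hypothesis space, and
fits over it report a `flat_likelihood` flag computed by scanning a simplex
grid for weight vectors within 2 log-likelihood units of the optimum. Every
fit carries a sensitivity sweep over `p_dark` ∈ {0.25, 0.35} alongside the
0.30 point estimate, and `bootstrap_histogram()` provides seeded
nonparametric CIs over spots.

### What the round trips show

The package's acceptance analyses fit a mixture to a published-style
category histogram, forward-simulate ≥5000 noisy traces through the full
detector, and check that the histogram comes back: ~94% one-step for the
ligand-free receptor, ~25/25/50 with ligand (support {1,2,4,6}), ~9%
corrected two-step for the dimerization-arm deletion. These validate the
pipeline's internal consistency — fit, forward model, trace simulator and
detector agree — not the biology of any particular receptor.

## 2. PIE-FCCS

### The measurement

Two pulsed lasers (488 and 561 nm) are interleaved with a 50 ns delay, so
every detected photon's originating laser is identifiable from its
microtime. Red-detector photons arriving within the 50 ns gate after a
488 nm pulse are rejected (`gate_photons()`): this removes green-to-red
bleed-through, FRET, and direct red excitation — the classic spectroscopic
artifacts that fake cross-correlation. Gated photon streams are binned
(0.1 ms default) and correlated with a multi-tau scheme: 16 linear lags,
then 8 lags per octave after each 2× rebinning, up to 1 s
(`multi_tau_correlate()`), with symmetric per-lag mean normalization. The
estimator is validated against a direct O(n²) loop oracle to 1e-12 in the
test suite.

Acquisition follows the standard per-cell protocol: five successive 15 s
segments, each gated, linearly detrended (removing slow photobleaching
drift; segments with a relative intensity trend above 50% are dropped), and
correlated; the per-segment curves are averaged (`analyze_cell()`).

### Model and estimators

For free 2D diffusion through a Gaussian detection profile the
autocorrelation is

    G(τ) = G0 (1 + τ/τ_D)^(-1) + B,   τ_D = w²/(4D)

with w the 1/e² beam waist (0.25 µm default; instruments quote pinhole
sizes rather than waists, so recovery tests use the configured waist
self-consistently). `fit_2d_diffusion()` fits this with `nlsLM`, two-pass:
a first fit over all lags sets the scale, then the fit is repeated over
lags ≤ 8 τ_D. The free baseline B absorbs the small uniform negative
offset that finite-duration mean normalization imprints on correlation
estimates (≈ −(2/T)∫G, a few percent of G0 for 15 s segments but a large
fraction of the tail); without it the offset masquerades as a faster decay
and biases D upward by ~7% under the default conditions. The per-cell
curves are fitted unweighted: per-lag error bars estimated from only five
segments are noisy enough that 1/se² weighting measurably degrades the
fit (weights are still honored when an `se` column is supplied).

The fraction correlated is computed from *fitted* zero-lag amplitudes —
never the raw first bin, which carries shot noise and afterpulsing —

    f_c = G_x(0) / max(G_gg(0), G_rr(0)).

The autocorrelation amplitudes come from the nonlinear fits; the
cross-correlation amplitude comes from a linear projection with the decay
shape fixed to the autocorrelations' diffusion time (co-diffusing
complexes share their constituents' mobility) over the same lag window,
with the amplitude *unconstrained in sign*. The sign matters: a
positivity-bounded fit cannot average away noise for truly independent
species, and its clipped amplitudes would inflate the population median
of f_c by several hundredths — the difference between resolving a monomer
control (median ~0.005) and not. The max denominator keeps f_c in [0, 1]
for ideal data and makes it insensitive to which color is in excess;
`min`, `green` and `red` conventions are available (`denominator =`),
since the literature varies. The max of two noisy amplitudes is biased
slightly high, which costs f_c about 0.01–0.015 at the default per-cell
noise — a known, convention-driven trade-off.
Amplitude ratios are insensitive to uncorrelated background because it
attenuates auto- and cross-amplitudes by the same factor. A
Cauchy–Schwarz-style amplitude check (G_x0² ≤ G_gg0·G_rr0, with 20% slack
for noise) and out-of-range f_c values are flagged, and f_c is clipped to
[0, 1.5]. Population summaries report medians, quartiles, full-range
whiskers and 1.5×IQR outliers, with a two-sample Student's t-test between
two conditions (`summarize_population()`).

### What the simulator emulates — and what it does not

`simulate_dual_color_streams()` moves particles by Brownian steps in a
periodic box through a centred Gaussian beam; photon counts are Poisson
per 0.1 ms bin (exact for correlation analysis at lags at or above the bin
width) with positions advanced every 1 ms (diffusive motion per millisecond
is ≪ the waist at membrane-protein diffusivities). A `co_diffusing_fraction`
φ of each color's particles carries both labels; the ideal estimator then
satisfies f_c = φ under equal labeling, which is what makes φ the ground
truth for recovery tests. Crosstalk photons are tagged to the 488 pulse so
gating can remove them exactly; background photons have uniform microtimes.

Two simulation-design points matter for accuracy. First, the box is 5 µm:
with a conserved particle number, the discrete diffusion modes of a small
periodic box suppress long-wavelength fluctuations and measurably shorten
the apparent decay (mode-sum theory: ≈ +9% bias on D at a 2.5 µm box,
≈ +2% at 5 µm). Second, molecular brightness defaults to 8 kHz at beam
centre — a realistic fluorescent-protein value that gives ~1.5 million
photons per channel per 75 s cell and per-cell f_c scatter of ≈0.03.

The simulator does *not* model: photobleaching during FCCS acquisition,
blinking/triplet kinetics, axial (z) structure of the detection volume,
anomalous or compartmentalized diffusion, detector afterpulsing or dead
time, or vendor TCSPC file formats (the documented CSV photon schema is the
interface). Passing recovery tests therefore demonstrates correctness of
the estimator chain under ideal membrane diffusion, not robustness to every
instrumental pathology of real recordings.

## 3. Reproducibility and problem sizes

All randomness flows from explicit `seed` arguments; outputs carry their
seed. `run_pipeline()` executes a declarative YAML configuration
(simulate → analyze → fit → report), writes every artifact with MD5 hashes
into a manifest, and `write_report()` renders the human-readable summary
including the `p_dark` sensitivity sweep; identical config + seed gives
identical files. The test suite runs the statistics at reduced but
informative sizes (hundreds of traces, 15 s single segments) and reserves
the full protocol — ≥5000-trace round trips, 75 s × 20-replicate FCCS
recoveries, ≥1 mm² colocalization fields — for the acceptance analyses,
whose per-analysis runtimes are minutes on one core.

## 4. Known limitations

- Step counting assumes immobile spots and clean irreversible bleaching;
  an optional blinking flag exists in the trace simulator for robustness
  testing, but the detector's upward-step rejection is the only mitigation.
- The mixture fit takes `p_dark` as an input (with sensitivity reporting)
  rather than estimating it; estimating it from the same three-category
  histogram would be degenerate.
- Mixture weights refer to the composition of visible spots, matching what
  a histogram over analyzed spots estimates; population fractions differ by
  the per-size visibility factor (1 − p_dark^n), a ≤4% relative effect on
  the dominant components at default settings.
- The single-component diffusion fit reports one effective D per curve; a
  mixture of fast monomers and slow multimers yields an intermediate value,
  which is exactly how the corresponding experiments summarize mobility.
- f_c is proportional to, not equal to, the true bound fraction when
  labeling is unequal or stoichiometries exceed 1:1; the package reports
  the amplitude-ratio definition and records the denominator convention in
  its outputs.
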