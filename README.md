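# oligocount

Single-molecule stoichiometry of membrane receptors, by two complementary
readouts:

1. **TIRF photobleaching step counting.** A receptor fused to a fluorescent
   protein shows up as a diffraction-limited spot whose intensity bleaches
   in discrete steps — one per fluorophore. oligocount detects spots,
   filters out overlapping and abnormally bright/wide ones, extracts
   background-subtracted traces, counts downward steps by penalized
   least-squares changepoint segmentation, and tallies one-step / two-step /
   multistep histograms with Wilson confidence intervals.
2. **Stoichiometry inference.** Observed steps undercount subunits: a
   fraction *p*<sub>dark</sub> ≈ 0.25–0.35 of fluorescent-protein tags
   never matures, and non-interacting molecules randomly colocalize within
   one spot. The binomial dark-fraction model gives, for an *n*-mer,

   *P(k | n) = C(n,k) (1−p)ᵏ pⁿ⁻ᵏ / (1 − pⁿ)*, k = 1…n,

   optionally with a per-fluorophore in-movie bleach probability *q*
   (finite recordings censor slow fluorophores). `fit_mixture()` inverts
   this by maximum likelihood over a mixture of assembly sizes, with the
   random-colocalization two-step baseline — analytically
   *(λπr²/2)(1−p)²* for density λ and merge radius r — inside the forward
   model, and returns a classed fit with `print`, `summary`, `coef`,
   `predict` and `simulate` methods (the latter forward-simulates noisy
   traces through the full detector).
3. **PIE-FCCS.** Two-color photon streams from pulsed interleaved
   excitation are time-gated by microtime and originating pulse (removing
   bleed-through, FRET and direct excitation), binned, correlated with a
   multi-tau correlator, and fitted with the 2D membrane-diffusion model
   *G(τ) = G₀(1 + τ/τ_D)⁻¹ + B*, *D = w²/(4τ_D)*. The fraction correlated
   *f_c = G_x(0)/max(G_gg(0), G_rr(0))* quantifies co-diffusion: ~0 for
   independent monomers, larger for dimers and multimers.

A synthetic-data module generates every input with known ground truth —
Poisson spot fields with unresolvable-pair merging, photobleaching traces
and TIFF movies with EMCCD-like noise, and pulse-tagged dual-color photon
streams from Brownian particles in a periodic box — so each stage of both
pipelines is testable without any external recording.

## Worked example

```r
library(oligocount)

# A mostly-monomeric receptor at low surface density
mix <- oligomer_mixture(c(`1` = 0.94, `2` = 0.06), p_dark = 0.30)
fld <- sample_spot_field(mix, coloc_model(density = 2), field_size = 13,
                         seed = 1)

# Simulate traces, count steps, histogram
acq <- acq_params(read_sd = 20, shot = FALSE)      # unit step = 5 x noise SD
calls <- lapply(simulate_trace_set(fld, acq, seed = 2), count_steps)
h <- build_histogram(calls)
print(h)
#> Step histogram: 215 spots analyzed, 12 rejected
#>          one_step two_step multistep
#> count    205.0000   9.0000    1.0000
#> fraction   0.9535   0.0419    0.0047
#> lower      0.9165   0.0222    0.0008
#> upper      0.9745   0.0776    0.0259

# Invert to a mixture (finite-movie censoring in the forward model)
fit <- fit_mixture(h, p_dark = 0.30, support = c(1, 2),
                   coloc_two_step = 0.03,
                   detect_prob = detect_prob_from_acq(acq))
print(coef(fit))
#>          1          2 
#> 0.96779354 0.03220646
```

The raw two-step fraction (4.2%) overstates the dimer weight because random
colocalization contributes two-step spots; with that baseline and the
finite-movie censoring in the forward model, the fit attributes ~3% to
dimers — consistent with the 6% truth at this small spot count, whose
bootstrap CI (`bootstrap_histogram(calls, seed = 3)`) spans it.

For PIE-FCCS:

```r
cfg <- membrane_sim_config(diffusion_coeff = 0.4, co_diffusing_fraction = 0.5,
                           duration = 75)
st <- simulate_dual_color_streams(cfg, pie_config(), seed = 4)
cell <- analyze_cell(st, waist = 0.25)
print(cell)
#> Cell summary: f_c = 0.443, D_green = 0.410, D_red = 0.420 um^2/s (5 segments)
```

`run_pipeline()` drives either analysis (or both) from a single YAML
configuration with a fixed seed and writes a hashed manifest;
`write_report()` renders the human-readable summary, including a
sensitivity sweep of the mixture fit over *p*<sub>dark</sub> 0.25–0.35. A
thin command-line front-end lives at `exec/oligocount`.

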