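Package: oligocount
Title: Single-Molecule Stoichiometry by Photobleaching Step Counting and PIE-FCCS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring membrane-receptor oligomerization from
    single-molecule fluorescence data. Implements TIRF photobleaching analysis
    (spot detection, trace extraction, automated change-point step counting,
    step-category histograms) with a binomial dark-fluorophore mixture model and
    random-colocalization correction for converting step histograms into
    oligomer-size estimates, and pulsed-interleaved-excitation fluorescence
    cross-correlation spectroscopy (PIE-FCCS) analysis (photon time-gating,
    multi-tau auto- and cross-correlation, 2D membrane-diffusion fitting,
    fraction correlated). A synthetic-data module generates ground-truthed TIRF
    movies, per-spot intensity traces and two-color pulse-tagged photon streams
    so every stage of both pipelines can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
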