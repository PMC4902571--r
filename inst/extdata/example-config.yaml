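# Example end-to-end configuration for `oligocount run` / run_pipeline().
# Simulates a mostly-monomeric receptor's photobleaching experiment and a
# dual-color FCCS experiment, then analyzes both.
mode: both
seed: 1
out_dir: oligocount-run
tirf:
  mixture:
    "1": 0.94
    "2": 0.06
  p_dark: 0.30
  n_spots: 500
  read_sd: 20          # unit step = 5 x noise SD at brightness 100
  bleach_rate: 0.005
  support: [1, 2]
  baseline: 0.03       # monomer-control two-step fraction
fccs:
  n_cells: 5
  duration: 75         # five 15 s segments
  diffusion_coeff: 0.4
  co_diffusing_fraction: 0.13
  n_in_focus: 5
  waist: 0.25
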