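# Example study configuration for runPipeline().
#
# Phantom mode simulates a two-group study (control vs myocarditis-like
# presets) end to end; files mode processes existing single-cell stacks.

mode: phantom          # "phantom" or "files"
seed: 101
n_samples: 5           # pseudo-samples per group
cells_per_sample: 8
rl_iterations: 0       # Richardson-Lucy iterations in the per-cell pipeline
tubule_spacing: 2.8    # base lattice spacing (um), jittered per sample
cell:                  # overrides for the phantom cell geometry (um)
  lengthUm: 12
  semiAxisY: 4.0
  semiAxisZ: 3.5
imaging:               # overrides for the confocal forward model
  poissonScale: 1.0
  readNoiseSD: 3.0
  background: 5.0

# --- files mode ---------------------------------------------------------
# mode: files
# rl_iterations: 150
# min_cell_volume: 500        # um^3
# inputs:
#   - path: stacks/avsd_s1_cell1.tif
#     sample_id: avsd_1
#     group: AVSD
#     membrane_channel: membrane
#   - path: stacks/myo_s1_cell1.tif
#     sample_id: myo_1
#     group: myocarditis
#     spacing: [0.2, 0.1, 0.1]    # when the TIFF carries no metadata
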