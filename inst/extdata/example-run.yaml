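# Desk-scale compact-spacer coexistence run for the `simulate` subcommand.
topology:
  preset: compact_spacer
  n_polymers: 20
  n_particles: 24
config:
  box: [80, 18, 18]
  anneal_steps: 80000
  wall_equil_steps: 40000
  equil_steps: 40000
  production_steps: 120000
  record_every: 1000
  confine_frac: 0.2
  seed: 42
insertion_model:
  a1: 4.18
  a2: 7.24
  nu: 0.588
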