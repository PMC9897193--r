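# Desk-scale scenario: the same pipeline rescaled by lambda = 40 so one CPU
# finishes in minutes. Scaled diploid sizes 250 -> 500 (recent expansion),
# scaled selection 0.1 / 0.2 (2Ns = 50 / 100). Selection runs for 100 scaled
# generations (0.2 coalescent units: the selected haplotype class stays
# conspicuously young relative to neutral variation) and the four ancient
# samples at 80/60/40/20 scaled generations span the allele's rise, where
# the weak and moderate trajectories differ most.
# Scaled theta = 4*N*mu*lambda*L = 20 per locus.
run:
  name: desk
simulation:
  locus_length: 40000
  mu: 1.25e-8
  rho: 1.25e-8
  generation_time: 25
  rescale_factor: 40
  burnin_factor: 5
  max_condition_attempts: 100
  demography:
    epochs:
      - {start: 4000, size: 10000}   # scaled: 250 diploids from 100 gens BP
      - {start: 400, size: 20000}    # scaled: 500 diploids from 10 gens BP
  selection:
    onset_time: 100000               # 4000 generations = 100 scaled generations
    focal_position: 20000
    s_classes: {D0.25: 0.0025, D0.5: 0.005}
  sampling:
    - {age: 80000, n_haplotypes: 10}            # 80 scaled generations BP
    - {age: 60000, n_haplotypes: 10}            # 60
    - {age: 40000, n_haplotypes: 10}            # 40
    - {age: 20000, n_haplotypes: 10}            # 20
    - {age: 0, n_haplotypes: 40}
  n_per_class: 380                   # 300 train / 30 validation / 50 test per class
encoding:
  width: 32
network:
  n_filters: 16
  kernel: [3, 3]
  padding: [1, 1]
  n_residual_blocks: 2
  embedding_dim: 32
  dropout: 0.25
training:
  fractions: [0.7895, 0.0789, 0.1316]
  batch_size: 32
  learning_rate: 0.001
  optimizer: adam
  max_epochs: 20
  patience: 0
  n_repeats: 3
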