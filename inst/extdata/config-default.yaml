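# Full-scale study design: 50 kbp loci, European-like demography (a
# documented stand-in with an ancestral size, out-of-Africa bottleneck and
# recent exponential growth -- NOT a reproduction of any published fit),
# overdominant de novo mutation at the locus center arising 10k years ago
# with s of 0.25% or 0.5%, sampled as 40 present-day haplotypes plus 10 at
# each of 8k, 4k, 2k and 1k years ago.
run:
  name: default
simulation:
  locus_length: 50000        # bp
  mu: 1.25e-8                # mutations / bp / generation
  rho: 1.25e-8               # crossovers / bp / generation
  generation_time: 25        # years / generation
  rescale_factor: 1
  burnin_factor: 10          # burn-in = 10 * ancestral diploid size, generations
  max_condition_attempts: 100
  demography:                # epochs oldest first; start in generations BP
    epochs:
      - {start: 5000, size: 10000}              # ancestral
      - {start: 2000, size: 1500}               # out-of-Africa bottleneck
      - {start: 1000, size: 10000}              # recovery
      - {start: 400, size: 10000, growth: 0.00275}  # recent growth (~3x by present)
  selection:
    onset_time: 10000        # years BP; de novo focal mutation
    focal_position: 25000    # bp (locus center)
    s_classes: {D0.25: 0.0025, D0.5: 0.005}
  sampling:                  # age in years BP
    - {age: 8000, n_haplotypes: 10}
    - {age: 4000, n_haplotypes: 10}
    - {age: 2000, n_haplotypes: 10}
    - {age: 1000, n_haplotypes: 10}
    - {age: 0, n_haplotypes: 40}
  n_per_class: 2000
encoding:
  width: 128                 # SNP columns kept around the focal position
network:
  n_filters: 64
  kernel: [3, 3]
  padding: [1, 1]
  n_residual_blocks: 2
  embedding_dim: 64
  dropout: 0.25
training:
  fractions: [0.8, 0.1, 0.1]
  batch_size: 32
  learning_rate: 0.001
  optimizer: adam
  max_epochs: 50
  patience: 10
  n_repeats: 10
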