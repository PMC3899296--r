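# 20 kb demo: simulate a pooled population, call, filter and evaluate.
seed: 7
reference:
  length: 20000
  gc: 0.35
  seed: 7        # reference sequence pinned independently of the run seed
pool:
  n_haplotypes: 10
  variants:
    - {contig: contig01, pos: 4000, kind: snp, alt: A, freq: 0.9}
    - {contig: contig01, pos: 9000, kind: snp, alt: T, freq: 0.4}
    - {contig: contig01, pos: 14000, kind: snp, alt: A, freq: 0.1}
sim:
  depth: 120
  read_length: 100
  mean_fragment: 230
  fragment_sd: 20
  per_base_error: 0.001
caller:
  haplotype_number: 10
  min_frequency: 0.05
sv:
  min_pairs: 4
evaluate:
  af_tolerance: 0.05
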