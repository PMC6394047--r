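# Demo pipeline: simulate the reference benchmark cohort, discover the
# signature, classify the training matrix and evaluate it.
out_dir: reosig_demo
seed: 1
simulate:
  n_normal: 100
  n_gastritis: 100
  n_gc: 100
  n_genes: 500
  noise_sd: 0.15
  n_batches: 3
mine:
  threshold: 0.99
select:
  vote_rule: at_least_half
classify: {}
evaluate:
  gc_adj_as: GC
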