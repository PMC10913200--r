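# Default triadex pipeline run: fully simulated study, study-scale thresholds.
simulation:
  n_genes: 2000
  replicates: 3
  seed: 1
thresholds:
  p: 0.05
  lfc: 1
  fpkm_filter: 1
  padj: 0.05
  min_count: 5
de_method: welch_log
ratio_mode: log2
meth_aggregate: sum
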