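# Default simulated scenario: 2x2 ChIP design over ~2000 base peaks,
# 5% differential at linear FC 3 (97:3 up:down), NB dispersion 0.05,
# mean depth 50, imbalanced libraries, PAR-like ratio 0.5. All values
# below are the package defaults, spelled out for editing.
simulate:
  seed: 1
thresholds:
  fc_cut: 1.5
  fdr_cut: 0.05
  quantile_cut: 0.05
  genic_flank: 1000
  tss_window: 1000
  at_min_len: 8
  min_overlap: 1
  pseudocount: 1
output_dir: diffmark_run
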