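# Full-scale run configuration: reproduces the published training protocol
# (dual-channel attention network, 12 x 15000 / 12 x 224 x 224 inputs,
# weighted multi-label cross-entropy, Adam, lr 0.001 halved every 10 epochs,
# 50 epochs, batch 64, dropout 0.4, 0.5 test split + 5-fold CV, model
# selection by validation mean F1). Requires the databases in
# download_manifest.tsv and GPU-scale compute; run one fold per invocation:
#   run_pipeline(out_dir, data_dir = <records>, profile = "full",
#                fold = k, train_cfg = do.call(train_config, yaml$train))
# The per-class CSV written by each fold (metrics_per_class.csv) has the
# Precision/Recall/F1/AUC/ACC columns of the published per-class table;
# average the five folds' CSVs for the cross-validated figures.
variant: EC-MAM
profile: full
folds: [1, 2, 3, 4, 5]
train:
  lr: 0.001
  decay_factor: 0.5
  decay_every: 10
  epochs: 50
  batch_size: 64
  seed: 1
  threshold: 0.5
  weighted: true
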