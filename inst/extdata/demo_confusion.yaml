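# Demo configuration: recompute the confusion statistics of the packaged
# printed region-level confusion matrix (adenoma / carcinoma / normal).
stages: ["confusion"]
confusion:
  csv: "table1_confusion.csv"
out_dir: "confusion_demo"
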