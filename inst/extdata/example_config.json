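{
  "seed": 1,
  "n_genes": 120,
  "mean_length": 200,
  "sdlog": 1,
  "flip_fraction": 0.5,
  "iterations": 4000
}
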