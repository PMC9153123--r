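Small plain-text examples for the command-line interface.

- `synthetic_optimality.csv` — a SYNTHETIC codon optimality
  classification (each family's alphabetical reference codon marked
  "optimal", all other synonyms "non-optimal"). It is a stand-in for an
  externally supplied translational-efficiency classification, used
  only to exercise the `positions` command; it encodes no empirical
  optimality data.
- `example_config.json` — example run configuration for
  `cub_cli(... --config ...)`.
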