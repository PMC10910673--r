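# Bundled example data

- `synthetic_table_s2.tsv` — a SYNTHETIC stand-in for an instrument-level
  association table (one row per instrument per metabolite-cancer pair:
  exposure/outcome effects, SEs, EAF, exposure GWAS N). It was generated by
  the package's own summary-statistic generator with arbitrary seeds and is
  shipped only so the worked examples and the CLI `report` subcommand have a
  small file to chew on. It is NOT real study data and reproduces no
  published estimate.
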