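# Worked-example data

Small plain-text tables used by the worked examples, tests and the
acceptance script.

- `flagged_ratio_block.csv` — published normalized MLPA ratios for the four
  cohort samples whose probes departed from unity (genes ABCA1, APOA4,
  CETP, SRBI; columns named by the default manifest's target probe ids).
- `count_confirmation_ratios.csv` — the orthogonal count-assay ratios
  published for those flagged (sample, gene) pairs; empty cells were not
  re-typed on that platform.
- `lipid_strata_counts.tsv` — published cohort group sizes by HDL stratum,
  LDL stratum and HIV status (n = 319 in total).
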