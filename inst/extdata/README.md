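# extdata

Drop-in location for the original per-patient cohort table:

    inst/extdata/s3_raw_table1.csv

When present, `read_cohort()` / `run_reproduction()` (and the clinical
acceptance test plus `scripts/acceptance.R`) use it; if its column
headers differ from the canonical names, supply a `column_map` via
`run_config()`. Without it, analyses run on the synthetic surrogate
cohort generated by `surrogate_study_cohort()`.

No patient data is distributed with this package.
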