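# On-disk formats

All DNAm levels are **percent (0–100) on disk** and beta fractions
[0, 1] in memory; conversion happens in the readers/writers only.

## Beta CSV (`read_beta_csv` / `write_beta_csv`)
Comma-separated, header row. Columns:
- `sample_id` (string), `age_weeks` (non-negative number),
  optional `strain`
- one column per CpG named `<amplicon>:<index>` (1-based CpG rank within
  the amplicon, 5'→3'), values in percent; malformed or out-of-range
  cells are read as missing with a warning.

## Pattern table TSV (`read_pattern_tsv` / `write_pattern_tsv`)
Tab-separated, header row: `sample_id`, `amplicon`, `pattern`, `count`.
`pattern` is a string over `1` (methylated), `0` (unmethylated), `?`
(missing call), one character per CpG in amplicon order; `count` is a
positive integer.

## Clock model JSON (`read_clock_json` / `write_clock_json`)
Schema `readclock/clock-model/1`. Fields, in order: `schema`, `kind`
(`multivariable-linear` | `lasso`), `terms` (array of
`{cpg_id, coefficient}`; coefficients in weeks per beta-fraction),
`intercept` (weeks), `meta` (`n`, `n_dropped`, `seed`, `lambda`,
`folds`). Numbers are serialized at full precision; the round trip is
exact.

## Single-read model JSON (`read_single_read_json` / `write_single_read_json`)
Schema `readclock/single-read-model/1`: `amplicon`, `epsilon`, and the
per-CpG `trajectories` table (`cpg_id`, `amplicon`, `cpg_index`,
`slope`, `intercept`, `pearson_r`, `r_squared`, `n_samples`). The
0–200-week age grid and likelihood tables are rebuilt on reading.

## Read-age distribution CSV (`read_distribution_csv` / `write_distribution_csv`)
Wide: `sample_id`, `amplicon`, then `age_0` … `age_200` holding
relative read frequencies on the linear scale; each row sums to 1.

## Amplicon panel YAML (`read_panel_yaml` / `write_panel_yaml`)
Top-level key `amplicons`: list of `{name, sequence, cpg_positions,
max_mismatch_frac, min_conversion}`; `cpg_positions` are 1-based
offsets of the C of each CG dinucleotide in `sequence` (the original,
unconverted top strand).

## ddPCR well CSV (`read_ddpcr_csv`)
Columns `sample_id`, `target`, `n_droplets`, `pos_meth`, `pos_unmeth`
(per-channel positive-droplet counts; double positives count in both
channels).

## FASTQ
Per sample and amplicon, plain or gzipped; reads are expected to be
anchored at the amplicon start (amplicon PCR products). Bottom-strand
reads are recognized automatically (`orient = "auto"`).
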