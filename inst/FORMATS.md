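# File formats

All files are plain text with mandatory headers. Times are serialized in
seconds, waveform samples in microvolts, both with six decimal places;
other numeric outputs use 12 significant digits.

## Unit dataset (consumed by `read_units()`, written by `write_units()`)

### spikes.csv (long format)
| column  | type   | meaning                    |
|---------|--------|----------------------------|
| unit_id | string | unit identifier            |
| time_s  | number | spike time in seconds      |

Times per unit must be sortable to a strictly increasing sequence.

### waveforms.csv (wide format)
| column  | type   | meaning                          |
|---------|--------|----------------------------------|
| unit_id | string | unit identifier                  |
| s0...sN | number | mean waveform samples in uV      |

The sampling rate lives in a JSON sidecar next to the file
(`waveforms.json`, field `sampling_rate_hz`; default 20000 Hz = one
sample per 0.05 ms).

### metadata.csv
| column     | type   | meaning                                 |
|------------|--------|-----------------------------------------|
| unit_id    | string | unit identifier                         |
| animal_id  | string | animal the unit was recorded from       |
| group      | string | experimental group (e.g. ND, Res, Sus)  |
| duration_s | number | recording span (optional; inferred from the last spike with a flag when absent) |

### ground_truth.csv (synthetic cohorts only)
`unit_id, true_class, true_ttp_ms, true_rate_hz,
true_ahp_slope_uv_per_ms, animal_id, group`

## Feature table (`features.tsv`)
`unit_id, ttp_ms, burst_index, ahp_uv_per_ms, rate_hz, flags`
(flags semicolon-separated; `burst_index` may be `Inf`).

## Labeled units (`labels.tsv`)
Feature table plus `class` (one of putative_PV, wide_interneuron,
putative_mossy, putative_granule, unclassifiable) and the metadata
columns.

## Group statistics (`stats.tsv`)
`class, comparison, test_name, statistic, p_value, p_adjusted, n` —
one `omnibus` row per class followed by one row per post hoc pair.

## Behavior table (`behavior.csv`)
In: `animal_id, group, defeated, phase1_s, phase2_s[, sucrose_ml,
water_ml]`. Out: same plus `si_ratio, phenotype, sucrose_pref_pct`.
Phase times are interaction-zone seconds out of 150 s phases.

## Intracellular sweeps
One CSV per sweep with columns `time_s, voltage_mv`, plus a sidecar JSON
listing `injected_current_pa` and optionally the step window; in code,
sweeps are `current_clamp_sweep` objects.

## manifest.json
Tool version, seed, config checksum, input checksums, per-stage record
counts (units in = labeled + unclassifiable), AHP threshold used,
accumulated warnings.
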