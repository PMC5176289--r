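# External data

This directory ships no data. To run the published-data reproduction
(`reproduce_deposited_results()` and the corresponding acceptance check),
place a copy of the experiments' deposited raw-data table here as
`s1_raw_data.txt`, converted to the canonical tab-separated layout described
in `?validate_trial_records`, or point `read_trial_records()` at the original
file with an explicit `raw_dialect()` mapping its column names and codes.
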