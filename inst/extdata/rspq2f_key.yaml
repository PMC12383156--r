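# Canonical R-SPQ-2F scale key: 10 deep + 10 surface items, per-scale sum
# scoring (range 10-50 per scale).  Sums are not missing-robust, so
# complete scales are required.
instrument: rspq2f
aggregation: sum
deep_items: [D1, D2, D3, D4, D5, D6, D7, D8, D9, D10]
surface_items: [S1, S2, S3, S4, S5, S6, S7, S8, S9, S10]
reverse_items: []
rating_min: 1
rating_max: 5
min_answered: 10
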