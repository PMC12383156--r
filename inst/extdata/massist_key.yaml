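# Canonical M-ASSIST scale key: 6 deep + 6 surface items, per-scale mean
# scoring on a 1-5 Likert range.  Item ids are generic placeholders; swap
# in instrument item ids when scoring real exports.
instrument: massist
aggregation: mean
deep_items: [D1, D2, D3, D4, D5, D6]
surface_items: [S1, S2, S3, S4, S5, S6]
reverse_items: []
rating_min: 1
rating_max: 5
min_answered: 5
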