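# per-gene, per-plate internal-standard anchors for the bp -> CAG map
- gene: ATXN3
  plate_id: plateA
  anchor_bp: 292
  anchor_cag: 70
  repeat_unit_bp: 3.0
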