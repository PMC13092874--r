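n_blocks: 11
set_size_sequence:
- 2
- 2
- 3
- 3
- 3
- 4
- 4
- 4
- 5
- 5
- 4
min_presentations: 9
max_presentations: 15
criterion:
  hits: 4
  window: 5
seed: 1
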