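adapter: ''
min_overlap: 3
max_err: 0.1
min_read_len: 30
k_map: 21
map_min_identity: 0.9
map_min_cov: 0.9
map_band: 8
k_scr: 21
min_hits: 2
include_mates: yes
k_grid:
- 21
- 25
- 31
min_abund: 3
hsp:
  seed_len: 11
  match: 1
  mismatch: 2
  gap: 2
  xdrop: 20
  min_len: 30
  min_identity: 0.9
  band: 8
tn_min_len: 16
max_q_overlap: 5
max_gap: 10
max_overlap: 5
tsd_len: 9
slack: 2
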