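# Water-absorption / noisy band drop lists, 1-based original band indices.
# Two-element entries are inclusive ranges [start, end]; single-element
# entries are individual bands. Editable: the benchmark literature fixes the
# retained counts (IP 220 -> 200, SA 224 -> 204) but not the exact indices.
ip:
  - [104, 108]
  - [150, 163]
  - [220]
sa:
  - [108, 112]
  - [154, 167]
  - [224]
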