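# Tail tube: extend three predicted stacked MTP hexamer rings by one more
# ring and fit the four-ring tube into the tail reconstruction, searching
# the map hand flip.
name: tail-stack
seed: 1
output: tail_out
steps:
  - id: qc_tube
    op: qc
    model: mtp_3rings.cif
    pae: mtp_3rings_pae.json
  - id: stack
    op: stack
    tube: "@qc_tube"
    add: 1
    direction: bottom
  - id: fit
    op: fitmap
    model: "@stack"
    map: tail.mrc
    resolution: 20
    try_flip: true
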