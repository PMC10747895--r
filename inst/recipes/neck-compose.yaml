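# Neck assembly: compose the full portal with the clip/adaptor prediction
# on the shared clip residues, add the stopper, report interfaces, and fit
# the composite into the neck reconstruction.
name: neck-compose
seed: 1
output: neck_out
steps:
  - id: compose
    op: compose
    parts:
      - model: portal_full12.cif
      - model: clip_adaptor.cif
        chains: [A, B, C, D, E, F, G, H, I, J, K, L]
        range: [246, 288]
      - model: adaptor_stopper.cif
        chains: [A, B, C, D, E, F, G, H, I, J, K, L]
  - id: interfaces
    op: interfaces
    model: "@compose"
  - id: fit
    op: fitmap
    model: "@compose"
    map: neck.mrc
    resolution: 20
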