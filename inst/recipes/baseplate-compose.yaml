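# Baseplate: compose the distal tail ring with the MTP/Dit/Tal prediction
# on the shared MTP chains, superpose the full-length Tal trimer onto its
# N-terminal domains, and report the Dit/Tal interfaces.
name: baseplate-compose
seed: 1
output: baseplate_out
steps:
  - id: compose
    op: compose
    parts:
      - model: tail_distal_ring.cif
      - model: mtp_dit_tal.cif
        chains: [A, B, C, D, E, F]
      - model: tal_full_trimer.cif
        chains: [M, N, O]
        range: [1, 380]
  - id: interfaces
    op: interfaces
    model: "@compose"
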