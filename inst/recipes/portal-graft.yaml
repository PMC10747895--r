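# Portal reconstruction beyond the predictor size limit: QC the short
# dodecamer, graft full-length monomers over the shared core, then check
# the C12 symmetry and monomer-monomer interfaces of the result.
name: portal-graft
seed: 1
output: portal_out
steps:
  - id: qc_short
    op: qc
    model: portal_short12.cif
    pae: portal_short12_pae.json
  - id: graft
    op: graft
    short_ring: "@qc_short"
    monomer: portal_monomer.cif
    shared: [65, 380]
  - id: sym
    op: symfit
    model: "@graft"
    order: 12
  - id: interfaces
    op: interfaces
    model: "@graft"
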