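# Capsid capsomer validation: QC two hexons and a penton, then rigid-fit
# them into the capsid reconstruction. Supply your own predicted
# coordinates and map in the working directory.
name: capsid-fit
seed: 1
output: capsid_out
steps:
  - id: qc_hexon
    op: qc
    model: hexon.cif
    pae: hexon_pae.json
  - id: qc_penton
    op: qc
    model: penton.cif
    pae: penton_pae.json
  - id: fit_hexon
    op: fitmap
    model: "@qc_hexon"
    map: capsid.mrc
    resolution: 15
  - id: fit_penton
    op: fitmap
    model: "@qc_penton"
    map: capsid.mrc
    resolution: 15
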