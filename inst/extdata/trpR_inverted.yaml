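name: trpR_inverted
temperature_note: 37C isothermal
initial_signal: 0.0
templates:
- name: aT
  role: aT
  concentration: 50.0
- name: rT
  role: rT
  concentration: 10.0
- name: pT
  role: pT
  concentration: 4.0
- name: sT
  role: sT
  concentration: 1.2
- name: pskT_TrpR
  role: pskT
  concentration: 10.0
  output_polarity: antisignal
  operator: TrpR
tfs:
- name: TrpR
  dimer_concentration: 210.0
  operator_kd: 5.0
  ligand_name: L-trp
  ligand_kd: 20.0
  ligand_hill: 2.0
  mode: corepressor
ligand_inputs:
  L-trp: 0.0
  L-thr: 0.0
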