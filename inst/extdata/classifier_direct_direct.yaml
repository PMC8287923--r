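name: classifier_direct_direct
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
  concentration: 7.0
- name: psT_TrpR
  role: psT
  concentration: 0.13
  output_polarity: signal
  operator: TrpR
- name: psT_LacI
  role: psT
  concentration: 2.5
  output_polarity: signal
  operator: LacI
tfs:
- name: LacI
  dimer_concentration: 110.0
  operator_kd: 10.0
  ligand_name: IPTG
  ligand_kd: 23.0
  ligand_hill: 2.0
  mode: inducer
  induction_fold: 10000.0
- name: TrpR
  dimer_concentration: 210.0
  operator_kd: 5.0
  ligand_name: L-trp
  ligand_kd: 20.0
  ligand_hill: 2.0
  mode: corepressor
ligand_inputs:
  IPTG: 0.0
  L-trp: 0.0
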