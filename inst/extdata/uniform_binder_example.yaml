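# Example scheme config: a uniform binder U on the irreversible conversion
# S -> P (k = 1e-3 s^-1), binding S and P equally at K = 1e-2 uM^-1.
# Units: uM, s, uM^-1, uM^-1 s^-1.
species:
- name: S
  role: substrate
  lineage: none
  conc0: 1.0
- name: P
  role: product
  lineage: none
  conc0: 0.0
- name: U
  role: binder
  lineage: none
  conc0: 1.0
- name: U.S
  role: complex
  lineage: none
  conc0: 0.0
- name: U.P
  role: complex
  lineage: none
  conc0: 0.0
bindings:
- binder: U
  ligand: S
  complex: U.S
  K_assoc: 0.01
  k_on: 1000.0
  k_off: 100000.0
- binder: U
  ligand: P
  complex: U.P
  K_assoc: 0.01
  k_on: 1000.0
  k_off: 100000.0
conversions:
- from: S
  to: P
  k: 0.001
- from: U.S
  to: U.P
  k: 0.001
metadata:
  kind: uniform_binder
  is_uniform: yes
  nc_fold: 1.0
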