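# Reduced neurogliaform cell (NGC): ball-and-stick, soma + 2 dendrites.
# Geometry from the two-stage reduction (best-fit length 245 um, 5
# subcompartments per dendrite); densities are this package's reduced
# parameter set for a small, high-input-resistance non-accommodating cell
# (0-0.2 nA protocol, < 100 Hz). Units: um, Ohm cm, uF/cm2, S/cm2, mV.
cell_class: NGC
v_init: -72
total_dendritic_area_um2: 3000
sections:
- name: soma
  length_um: 15
  diam_um: 15
  nseg: 1
  ra_ohm_cm: 100
  cm_uf_cm2: 1
  g_pas: 7.0e-5
  e_pas: -70
  channels:
    NaTa: 2.0
    Kv31: 0.9
    KvDet: 0.001
    Ih: 2.0e-5
- name: dend1
  length_um: 245
  diam_um: 1.9493
  nseg: 5
  ra_ohm_cm: 100
  cm_uf_cm2: 1
  g_pas: 7.0e-5
  e_pas: -70
  parent: soma
- name: dend2
  length_um: 245
  diam_um: 1.9493
  nseg: 5
  ra_ohm_cm: 100
  cm_uf_cm2: 1
  g_pas: 7.0e-5
  e_pas: -70
  parent: soma
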