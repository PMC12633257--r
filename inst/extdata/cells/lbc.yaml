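# Reduced large basket cell (LBC): ball-and-stick, soma + 2 dendrites.
# Geometry from the two-stage reduction (best-fit length 301 um, 1
# subcompartment per dendrite); densities are this package's reduced
# parameter set, tuned to a continuous-stuttering basket-cell f-I range
# (0-0.8 nA protocol, < 100 Hz). Units: um, Ohm cm, uF/cm2, S/cm2, mV.
cell_class: LBC
v_init: -72
total_dendritic_area_um2: 5000
sections:
- name: soma
  length_um: 20
  diam_um: 20
  nseg: 1
  ra_ohm_cm: 100
  cm_uf_cm2: 1
  g_pas: 1.3e-4
  e_pas: -70
  channels:
    NaTa: 2.2
    Kv31: 1.2
    KvDet: 0.002
    Im: 0.0003
    Ih: 1.0e-5
- name: dend1
  length_um: 301
  diam_um: 2.6446
  nseg: 1
  ra_ohm_cm: 100
  cm_uf_cm2: 1
  g_pas: 1.3e-4
  e_pas: -70
  parent: soma
- name: dend2
  length_um: 301
  diam_um: 2.6446
  nseg: 1
  ra_ohm_cm: 100
  cm_uf_cm2: 1
  g_pas: 1.3e-4
  e_pas: -70
  parent: soma
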