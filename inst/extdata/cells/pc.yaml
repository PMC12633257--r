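# Simplified thick-tufted layer-5 pyramidal cell: soma, basal dendrite,
# apical trunk and apical tuft. A reduced parameter set in the lineage of
# the full-morphology L5PC model (Na transient/persistent, fast and slow K,
# M-type, Ih with an apical gradient, HVA/LVA Ca with a distal LVA hot
# zone, Ca-activated SK, Ca2+ decay dynamics). Units: um, Ohm cm, uF/cm2,
# S/cm2, mV.
cell_class: PC
v_init: -75
sections:
- name: soma
  length_um: 30
  diam_um: 20
  nseg: 1
  ra_ohm_cm: 100
  cm_uf_cm2: 1
  g_pas: 3.38e-5
  e_pas: -90
  channels:
    NaTa: 2.0
    NaP: 1.7e-3
    Kv31: 0.7
    KPst: 0.08
    KTst: 0.08
    SK: 0.040
    CaHVA: 3.0e-3
    CaLVA: 1.0e-3
    Ih: 2.0e-5
  ca: {gamma: 5.0e-4, tau: 460, cainf: 1.0e-4, depth: 0.1}
- name: basal
  length_um: 200
  diam_um: 3.0
  nseg: 1
  ra_ohm_cm: 100
  cm_uf_cm2: 2
  g_pas: 4.67e-5
  e_pas: -90
  parent: soma
  channels:
    Ih: 3.0e-5
- name: trunk
  length_um: 400
  diam_um: 3.0
  nseg: 1
  ra_ohm_cm: 100
  cm_uf_cm2: 2
  g_pas: 4.67e-5
  e_pas: -90
  parent: soma
  channels:
    NaTa: 0.013
    Kv31: 4.0e-4
    Im: 6.75e-5
    SK: 1.2e-3
    CaHVA: 5.6e-4
    CaLVA: 1.0e-3
    Ih: 1.0e-4
  ca: {gamma: 5.0e-4, tau: 122, cainf: 1.0e-4, depth: 0.1}
- name: tuft
  length_um: 300
  diam_um: 2.5
  nseg: 1
  ra_ohm_cm: 100
  cm_uf_cm2: 2
  g_pas: 4.67e-5
  e_pas: -90
  parent: trunk
  channels:
    NaTa: 0.013
    Kv31: 4.0e-4
    Im: 6.75e-5
    SK: 1.2e-3
    CaHVA: 5.6e-4
    CaLVA: 3.0e-3
    Ih: 2.0e-4
  ca: {gamma: 5.0e-4, tau: 122, cainf: 1.0e-4, depth: 0.1}
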