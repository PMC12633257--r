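# Network defaults: connection classes, background drive and gap junctions.
#
# p_base: unscaled pairwise connection probability (microcircuit-resource
#   lineage values, adjusted upward for the inhibitory classes so that
#   small networks keep near-complete inhibitory coverage); the network
#   applies probability_scale (default 6) on top, clipping at 1.
# nsyn: synapse instances per connection.
# base_g_uS: per-synapse peak conductance (uS) before the dimensionless
#   class weight (g_EE, g_EI, g_EN, g_I, g_N) is applied. These carry the
#   calibration of the healthy-control operating point: with the best-fit
#   weights (g_EE=0.2, g_I=0.5, g_EI=0.7, g_EN=1.2, g_N=0.6) the network
#   produces a GABA_B-paced delta rhythm whose delta power collapses under
#   GABA_B blockade and survives GABA_A blockade.
# nmda_ratio: NMDA peak conductance as a fraction of the AMPA one
#   (glutamatergic classes only; kept small so that the GABA_B-blocked
#   state stays asynchronous instead of NMDA-driven slow bursting).
#
# Background drive (free calibration constants, no published values):
# Poisson event rate per PC cell (split uniformly over its dendritic
# compartments) and per-event peak conductance; only the PC population
# is driven.
connections:
- {class: "PC->PC",   p_base: 0.072, nsyn: 5,  symbol: g_EE, base_g_uS: 6.5e-3,   nmda_ratio: 0.25}
- {class: "PC->LBC",  p_base: 0.043, nsyn: 6,  symbol: g_EI, base_g_uS: 3.5714e-3, nmda_ratio: 0.4}
- {class: "PC->NGC",  p_base: 0.060, nsyn: 4,  symbol: g_EN, base_g_uS: 1.5e-4,   nmda_ratio: 0.4}
- {class: "LBC->PC",  p_base: 0.080, nsyn: 12, symbol: g_I,  base_g_uS: 4.0e-3}
- {class: "LBC->LBC", p_base: 0.080, nsyn: 10, symbol: g_I,  base_g_uS: 4.0e-3}
- {class: "NGC->LBC", p_base: 0.060, nsyn: 8,  symbol: g_N,  base_g_uS: 5.8333e-3}
- {class: "NGC->PC",  p_base: 0.200, nsyn: 9,  symbol: g_N,  base_g_uS: 4.2e-3}
background:
- {receptor: AMPA, rate_hz: 1400, weight_uS: 1.0e-3}
- {receptor: NMDA, rate_hz: 420, weight_uS: 0.7e-3}
- {receptor: GABA_A, rate_hz: 600, weight_uS: 1.0e-3}
gap_junctions: {p: 0.3, g_uS: 5.0e-4}
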