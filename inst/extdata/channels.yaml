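# Ion channel kinetics library.
#
# Each block defines one channel in Hodgkin-Huxley form: a `form` naming the
# parameterization implemented in the package, its parameters, the reversal
# potential and the permeant ion. Rates are per ms at `source_temp` (deg C)
# and are rescaled to the simulation temperature with the channel's q10.
# Users can add channels by appending blocks with one of the supported forms
# (trap-function sodium/potassium kinetics, thermodynamic A-type kinetics,
# generic Boltzmann activation, HVA/T-type calcium, HCN, and the joint
# voltage-calcium BK form).
reversal_potentials: # mV; fixed, not Nernst-updated
  na: 60
  k: -90
  h: -45
  ca: 140

channels:
  Na:
    form: trap_na
    ion: na
    params: {Ra: 0.182, Rb: 0.124, tha: -35, qa: 9,
             Rd: 0.015, Rg: 0.018, thi1: -50, thi2: -75, qi: 5,
             thinf: -60, qinf: 6.2, vshift: -8, source_temp: 23, q10: 2.3}
  Na_x: # axonal sodium: same functional form, hyperpolarized operating range
    form: trap_na
    ion: na
    params: {Ra: 0.182, Rb: 0.124, tha: -35, qa: 9,
             Rd: 0.015, Rg: 0.018, thi1: -50, thi2: -75, qi: 5,
             thinf: -60, qinf: 6.2, vshift: -8, source_temp: 23, q10: 2.3}
  Na_P: # persistent sodium: non-inactivating, activates near rest
    form: boltzmann_act
    ion: na
    params: {vhalf: -51.3, k: 3.2, tau_const: 1.0, source_temp: 22, q10: 2.3}
  K_V:
    form: trap_k
    ion: k
    params: {Ra: 0.06, Rb: 0.006, tha: 5, qa: 9, source_temp: 23, q10: 2.3}
  K_M: # slow non-inactivating M-type
    form: trap_k
    ion: k
    params: {Ra: 0.0005, Rb: 0.0005, tha: -42.5, qa: 9, source_temp: 23, q10: 2.3}
  K_AP: # A-type, proximal variant
    form: borg_graham_ka
    ion: k
    params: {vhalfn: 11, vhalfl: -56, a0n: 0.05, zetan: -1.5, pw: -1,
             tq: -40, qq: 5, gmn: 0.55, nmin: 0.1, a0l: 0.05, zetal: 3,
             gml: 1, lmin: 2, source_temp: 24, q10: 5}
  K_AD: # A-type, distal variant (hyperpolarized activation midpoint)
    form: borg_graham_ka
    ion: k
    params: {vhalfn: -1, vhalfl: -56, a0n: 0.1, zetan: -1.8, pw: -1,
             tq: -40, qq: 5, gmn: 0.39, nmin: 2, a0l: 0.05, zetal: 3,
             gml: 1, lmin: 2, source_temp: 24, q10: 5}
  K_BK: # large-conductance K, jointly gated by voltage and [Ca]i
    form: bk
    ion: k
    params: {vh_base: -10, shift_per_decade: 50, ca_ref: 0.001, kw: 12,
             tau_w: 3.0, source_temp: 32, q10: 1}
  Ca_HVA:
    form: hva_ca
    ion: ca
    ca_source: true
    params: {source_temp: 23, q10: 2.3}
  Ca_IT2: # low-voltage-activated (T-type), distal dendrites
    form: it2
    ion: ca
    ca_source: true
    params: {source_temp: 24, q10: 2.5}
  HCN1: # fast, less hyperpolarized isoform
    form: hcn
    ion: h
    params: {vhalf: -96, k: 7.0, tau_min: 15, tau_amp: 50, vpeak: -90,
             sigma: 20, source_temp: 32, q10: 1}
  HCN2: # slow, strongly hyperpolarized isoform
    form: hcn
    ion: h
    params: {vhalf: -101, k: 7.0, tau_min: 50, tau_amp: 350, vpeak: -98,
             sigma: 18, source_temp: 32, q10: 1}

calcium_pool: # single sub-membrane shell driving BK and IT2 feedback
  resting_concentration: 1.0e-4 # mM (100 nM)
  decay_time_constant: 150 # ms
  influx_scale: 0.10 # mM cm^2 / (ms mA); includes implicit fast buffering
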