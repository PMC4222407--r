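# Paired-cohort presets: group means and SEMs of the excitability features
# (input resistance MOhm, rheobase pA, F-I slope Hz/nA, AHP mV) for each
# pharmacological comparison, with the multiplicative treatment effect
# implied by the printed group means. Ages in postnatal days.
age_range: [11, 27]
variance_split_biological: 0.9 # share of the group variance that is between-cell

presets:
  pma: # control vs 4beta-PMA
    n_cells: 17
    features:
      input_resistance: {mean: 74.8, sem: 9.8, treatment_mean: 105.1, treatment_sem: 13.6}
      rheobase: {mean: 124.1, sem: 16, treatment_mean: 103.5, treatment_sem: 14.1}
      fi_slope: {mean: 76, sem: 4.9, treatment_mean: 96, treatment_sem: 7.5}
      ahp: {mean: 5.8, sem: 0.3, treatment_mean: 2.7, treatment_sem: 0.3}
  bryostatin: # control vs Bryostatin1
    n_cells: 7
    features:
      input_resistance: {mean: 69.13, sem: 15.3, treatment_mean: 87.3, treatment_sem: 25.5}
      rheobase: {mean: 120.8, sem: 20, treatment_mean: 105.6, treatment_sem: 17}
      fi_slope: {mean: 81, sem: 10, treatment_mean: 103, treatment_sem: 11}
      ahp: {mean: 6.4, sem: 0.64, treatment_mean: 3.6, treatment_sem: 0.42}
  ifn: # control vs IFN-beta
    n_cells: 8
    features:
      input_resistance: {mean: 76.5, sem: 9.7, treatment_mean: 89.1, treatment_sem: 11.1}
      rheobase: {mean: 185.2, sem: 28, treatment_mean: 146.9, treatment_sem: 20}
      fi_slope: {mean: 47.7, sem: 3.9, treatment_mean: 57.9, treatment_sem: 5.3}
      ahp: {mean: 5.0, sem: 0.25, treatment_mean: 3.4, treatment_sem: 0.5}
  gf_ifn: # control vs GF109203X + IFN-beta (PKC block)
    n_cells: 9
    features:
      input_resistance: {mean: 68.1, sem: 11.2, treatment_mean: 73.3, treatment_sem: 10}
      rheobase: {mean: 148.3, sem: 29, treatment_mean: 140.6, treatment_sem: 24}
      fi_slope: {mean: 91.1, sem: 9.9, treatment_mean: 87.8, treatment_sem: 6.8}
      ahp: {mean: 3.7, sem: 0.44, treatment_mean: 3.1, treatment_sem: 0.4}
  calphostin_ifn: # calphostin C vs calphostin C + IFN-beta
    n_cells: 12
    features:
      input_resistance: {mean: 67.7, sem: 10.3, treatment_mean: 74.2, treatment_sem: 11.9}
      rheobase: {mean: 170, sem: 19, treatment_mean: 200, treatment_sem: 17}
      fi_slope: {mean: 100, sem: 11.8, treatment_mean: 104, treatment_sem: 9.6}
      ahp: {mean: 3.9, sem: 0.5, treatment_mean: 2.6, treatment_sem: 0.4}

# Named scenario reproducing the reported tendency of the input-resistance
# effect to decline with age (r around -0.66 for the IFN-beta cohort).
age_scenarios:
  ifn_rin_age: {preset: ifn, feature: input_resistance, age_effect: -0.02}
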