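# Physiological filter bounds on the nine model observables, from primary
# cultures of human nasal epithelial cells. Concentrations in mM, potentials
# in mV. dVa_amil / dVt_amil and dVa_lowCl / dVt_lowCl are the changes
# (post-perturbation steady value minus basal value) induced by complete
# apical amiloride block and by low luminal chloride, respectively.
nonCF:
  Na_i:      {lower: 18.0,  upper: 43.2}
  Cl_i:      {lower: 32.5,  upper: 84.4}
  V_a:       {lower: -38.6, upper: -14.9}
  V_b:       {lower: -45.1, upper: -24.2}
  V_t:       {lower: -15.5, upper: -2.7}
  dVa_amil:  {lower: -14.0, upper: -5.5}
  dVt_amil:  {lower: 4.7,   upper: 10.1}
  dVa_lowCl: {lower: 9.2,   upper: 15.0}
  dVt_lowCl: {lower: -12.7, upper: -6.1}
CF:
  Na_i:      {lower: 21.0,  upper: 51.3}
  Cl_i:      {lower: 32.5,  upper: 84.4}
  V_a:       {lower: -37.7, upper: 6.7}
  V_b:       {lower: -59.3, upper: -33.6}
  V_t:       {lower: -59.2, upper: -8.2}
  dVa_amil:  {lower: -47.4, upper: -29.0}
  dVt_amil:  {lower: 30.1,  upper: 47.1}
  dVa_lowCl: {lower: -5.3,  upper: 11.1}
  dVt_lowCl: {lower: -16.5, upper: 9.9}
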