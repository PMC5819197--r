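# Calibrated reference surrogate wound-healing model.
# States: platelets P, inflammatory cells I, repair macrophages M,
# fibroblasts F, TGF-beta T, IL-6 C6, CXCL8 C8, IL-10 I10, MMP-9 M9,
# TIMP-1 T1, fibronectin FN, collagen COL. Rates per day; concentrations
# in arbitrary units.
name: wound_surrogate
state_names: [P, I, M, F, T, C6, C8, I10, M9, T1, FN, COL]
initial_state:
  P: 1.0
  I: 0.0
  M: 0.0
  F: 0.0
  T: 0.0
  C6: 0.0
  C8: 0.0
  I10: 0.0
  M9: 0.0
  T1: 0.0
  FN: 0.0
  COL: 0.0
default_params:
  kP: 0.7          # platelet decay
  rI: 0.4          # platelet-driven inflammatory-cell recruitment
  rI8: 1.1142      # CXCL8-driven recruitment (saturating)
  K8: 0.9
  KI10: 1.5        # IL-10 inhibition constant
  dI: 0.4
  rM: 0.25377      # macrophage differentiation from I
  dM: 0.08
  rF: 0.15    # TGF-beta-driven fibroblast recruitment
  KT: 0.5
  gF: 0.271215     # fibroblast logistic growth
  Fmax: 10.451     # fibroblast carrying capacity
  aF: 0.4          # fibroblast apoptosis
  pTP: 0.5         # TGF-beta production by platelets
  pTM: 0.005        #   ... by macrophages
  pTF: 0.12        #   ... by fibroblasts
  dT: 0.335223
  p6: 0.547978     # IL-6 production by I (IL-10-inhibited)
  d6: 0.5
  p8P: 0.289521    # CXCL8 production by platelets
  p8I: 0.8         #   ... by I
  d8: 1.25145
  p10: 0.343714    # IL-10 production by macrophages
  d10: 0.1
  p9: 0.45          # MMP-9 production by I
  d9: 0.045
  pT1M: 0.00719387 # TIMP-1 production by macrophages
  pT1F: 0.362209   #   ... by fibroblasts (IL-10-enhanced)
  e10: 7.08217     # IL-10 enhancement of TIMP-1 production
  K10e: 3.0
  dT1: 0.332943
  pFN: 0.08        # fibronectin deposition by fibroblasts
  dFN: 0.15
  pC: 0.0712724    # collagen production by fibroblasts
  dC: 0.15      # collagen degradation via MMP-9 (TIMP-1-inhibited)
  KT1: 3.55403
marker_roles:
  collagen: COL
  fibroblast: F
  screened: [T, C6, C8, I10, M9, T1, FN]
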