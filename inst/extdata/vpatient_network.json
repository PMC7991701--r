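{
  "fixture_version": "1.0.0",
  "reference_age": 40,
  "blood": {
    "rho": 1.06,
    "mu": 0.04
  },
  "inflow": {
    "segment": "asc_aorta",
    "cardiac_output_ml_min": 5000,
    "period_s": 0.9,
    "systole_s": 0.3
  },
  "segments": {
    "id": ["asc_aorta", "aortic_arch_1", "brachiocephalic", "aortic_arch_2", "thoracic_aorta", "R_subclavian", "L_subclavian", "R_brachial", "L_brachial", "R_CCA", "L_CCA", "R_ECA", "L_ECA", "R_ICA", "L_ICA", "R_VA", "L_VA", "BA", "R_PCA_P1", "L_PCA_P1", "R_PCA_P2", "L_PCA_P2", "R_Pcom", "L_Pcom", "R_MCA", "L_MCA", "R_ACA_A1", "L_ACA_A1", "R_ACA_A2", "L_ACA_A2", "Acom"],
    "name": ["ascending aorta", "aortic arch I", "brachiocephalic", "aortic arch II", "thoracic aorta", "right subclavian", "left subclavian", "right brachial", "left brachial", "right common carotid", "left common carotid", "right external carotid", "left external carotid", "right internal carotid", "left internal carotid", "right vertebral", "left vertebral", "basilar", "right PCA P1", "left PCA P1", "right PCA P2", "left PCA P2", "right posterior communicating", "left posterior communicating", "right MCA", "left MCA", "right ACA A1", "left ACA A1", "right ACA A2", "left ACA A2", "anterior communicating"],
    "length_cm": [4, 2, 3.4, 3.9, 15.6, 3.4, 3.4, 42.2, 42.2, 17.7, 20.8, 17.7, 17.7, 17.7, 17.7, 14.8, 14.8, 2.9, 0.5, 0.5, 8.6, 8.6, 1.5, 1.5, 11.9, 11.9, 1.2, 1.2, 10.3, 10.3, 0.5],
    "r_prox_cm": [1.2, 1.12, 0.62, 1.07, 1, 0.423, 0.423, 0.403, 0.403, 0.25, 0.25, 0.15, 0.15, 0.47, 0.47, 0.15, 0.165, 0.17, 0.11, 0.11, 0.125, 0.125, 0.074, 0.074, 0.135, 0.135, 0.14, 0.14, 0.15, 0.15, 0.062],
    "r_dist_cm": [1.2, 1.12, 0.62, 1.07, 1, 0.423, 0.423, 0.403, 0.403, 0.25, 0.25, 0.15, 0.15, 0.2, 0.2, 0.15, 0.165, 0.17, 0.11, 0.11, 0.125, 0.125, 0.074, 0.074, 0.135, 0.135, 0.14, 0.14, 0.15, 0.15, 0.062],
    "h_cm": [0.12, 0.11, 0.08, 0.1, 0.1, 0.067, 0.067, 0.067, 0.067, 0.063, 0.063, 0.038, 0.038, 0.062, 0.062, 0.038, 0.04, 0.04, 0.022, 0.022, 0.025, 0.025, 0.015, 0.015, 0.027, 0.027, 0.028, 0.028, 0.03, 0.03, 0.013],
    "E_dyn_cm2": [4000000, 4000000, 4000000, 4000000, 4000000, 4000000, 4000000, 4000000, 4000000, 4000000, 4000000, 8000000, 8000000, 8000000, 8000000, 8000000, 8000000, 8000000, 6000000, 6000000, 6000000, 6000000, 6000000, 6000000, 6000000, 6000000, 6000000, 6000000, 6000000, 6000000, 6000000],
    "alpha": [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1],
    "K_R": [2.60811465581039, 2.60811465581039, 2.60811465581039, 2.60811465581039, 2.60811465581039, 2.60811465581039, 2.60811465581039, 2.60811465581039, 2.60811465581039, 2.60811465581039, 2.60811465581039, 0.948405329385598, 0.948405329385598, 2.60811465581039, 2.60811465581039, 0.948405329385598, 0.948405329385598, 0.948405329385598, 0.948405329385598, 0.948405329385598, 0.948405329385598, 0.948405329385598, 0.948405329385598, 0.948405329385598, 0.948405329385598, 0.948405329385598, 0.948405329385598, 0.948405329385598, 0.948405329385598, 0.948405329385598, 0.948405329385598]
  },
  "junctions": {
    "node_id": ["j_arch1", "j_arch2", "j_arch3", "j_brceph", "j_r_subcl", "j_l_subcl", "j_r_bif", "j_l_bif", "j_vb", "j_ba_top", "j_r_pca", "j_l_pca", "j_r_term", "j_l_term", "j_r_acom", "j_l_acom"],
    "attached": [
      [
        ["asc_aorta", "distal"],
        ["brachiocephalic", "proximal"],
        ["aortic_arch_1", "proximal"]
      ],
      [
        ["aortic_arch_1", "distal"],
        ["L_CCA", "proximal"],
        ["aortic_arch_2", "proximal"]
      ],
      [
        ["aortic_arch_2", "distal"],
        ["L_subclavian", "proximal"],
        ["thoracic_aorta", "proximal"]
      ],
      [
        ["brachiocephalic", "distal"],
        ["R_CCA", "proximal"],
        ["R_subclavian", "proximal"]
      ],
      [
        ["R_subclavian", "distal"],
        ["R_brachial", "proximal"],
        ["R_VA", "proximal"]
      ],
      [
        ["L_subclavian", "distal"],
        ["L_brachial", "proximal"],
        ["L_VA", "proximal"]
      ],
      [
        ["R_CCA", "distal"],
        ["R_ICA", "proximal"],
        ["R_ECA", "proximal"]
      ],
      [
        ["L_CCA", "distal"],
        ["L_ICA", "proximal"],
        ["L_ECA", "proximal"]
      ],
      [
        ["R_VA", "distal"],
        ["L_VA", "distal"],
        ["BA", "proximal"]
      ],
      [
        ["BA", "distal"],
        ["R_PCA_P1", "proximal"],
        ["L_PCA_P1", "proximal"]
      ],
      [
        ["R_PCA_P1", "distal"],
        ["R_PCA_P2", "proximal"],
        ["R_Pcom", "proximal"]
      ],
      [
        ["L_PCA_P1", "distal"],
        ["L_PCA_P2", "proximal"],
        ["L_Pcom", "proximal"]
      ],
      [
        ["R_ICA", "distal"],
        ["R_Pcom", "distal"],
        ["R_MCA", "proximal"],
        ["R_ACA_A1", "proximal"]
      ],
      [
        ["L_ICA", "distal"],
        ["L_Pcom", "distal"],
        ["L_MCA", "proximal"],
        ["L_ACA_A1", "proximal"]
      ],
      [
        ["R_ACA_A1", "distal"],
        ["R_ACA_A2", "proximal"],
        ["Acom", "proximal"]
      ],
      [
        ["L_ACA_A1", "distal"],
        ["L_ACA_A2", "proximal"],
        ["Acom", "distal"]
      ]
    ]
  },
  "terminals": {
    "segment": ["thoracic_aorta", "R_brachial", "L_brachial", "R_ECA", "L_ECA", "R_MCA", "L_MCA", "R_ACA_A2", "L_ACA_A2", "R_PCA_P2", "L_PCA_P2"],
    "kind": ["windkessel", "windkessel", "windkessel", "windkessel", "windkessel", "autoregulating_bed", "autoregulating_bed", "autoregulating_bed", "autoregulating_bed", "autoregulating_bed", "autoregulating_bed"],
    "R1": [169.233924621811, 1343.57592123165, 1343.57592123165, 16930.3553888128, 16930.3553888128, 16083.498261139, 16083.498261139, 13027.6335915226, 13027.6335915226, 18759.7923717925, 18759.7923717925],
    "R2": [1989.31274204486, 13766.250745435, 13766.250745435, 37465.0206111872, 37465.0206111872, 29245.981738861, 29245.981738861, 54966.5864084774, 54966.5864084774, 49234.4276282075, 49234.4276282075],
    "C": [0.000653492018888746, 9.44338457899359e-05, 9.44338457899359e-05, 3.46990333594482e-05, 3.46990333594482e-05, 2.05156388784426e-05, 2.05156388784426e-05, 1.09157224270973e-05, 1.09157224270973e-05, 1.21865943995711e-05, 1.21865943995711e-05],
    "Pv": [6666.1, 6666.1, 6666.1, 6666.1, 6666.1, 6666.1, 6666.1, 6666.1, 6666.1, 6666.1, 6666.1],
    "q0_ml_min": ["NA", "NA", "NA", "NA", "NA", 150, 150, 100, 100, 100, 100]
  },
  "stenoses": {
    "segment": [],
    "start_offset_mm": [],
    "length_mm": [],
    "ratio": []
  },
  "clamps": {
    "segment": [],
    "position_mm": []
  }
}
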