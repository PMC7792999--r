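{
  "planted": {
    "water_r": 3.47,
    "water_theta": 6,
    "thr_torsion": -110.4,
    "d_thr_dg1_w1": 2.16,
    "ang_og1_dg1_w1": 160,
    "d_lys_dz1_og1": 1.97,
    "ang_nz_dz1_og1": 165,
    "d_aza_d9_w2": 1.84,
    "d_asn_dd21_w1": {
      "A": 2.23,
      "B": 2.25
    },
    "asn_occupancies": {
      "A": 0.75,
      "B": 0.25
    }
  },
  "realized": {
    "pi_d_om": 3.63999999995754,
    "pi_omega": 23.7999999980312,
    "pi_angle_ohm": 141.00000000357,
    "w1_plane_tilt": 45.0000000046586,
    "d_thr_dg1_n7": 2.77000046980717
  },
  "n_atoms": 42
}
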