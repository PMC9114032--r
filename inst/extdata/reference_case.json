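{
  "segments": [
    {
      "id": "AI",
      "kind": "feeding",
      "diameter": 3.8,
      "length": 20
    },
    {
      "id": "AO",
      "kind": "arterial_outlet",
      "diameter": 2,
      "length": 15
    },
    {
      "id": "VO1",
      "kind": "venous",
      "diameter": 1.6,
      "length": 15
    },
    {
      "id": "VO2",
      "kind": "venous",
      "diameter": 2.3,
      "length": 15
    }
  ],
  "nidus": {
    "L": 16,
    "W": 12,
    "H": 9
  },
  "fluid": {
    "density": 1060,
    "viscosity": 0.004
  },
  "boundary": {
    "P_in": 20.837,
    "R_art": 24.138,
    "P_ven": 0
  },
  "stages": [
    {
      "name": "baseline",
      "K": 2e-08,
      "R_nidus": 0.33,
      "Q_target": 1.645,
      "Q_nidus_target": 1.168
    },
    {
      "name": "Post AE I",
      "Q_target": 1.011
    },
    {
      "name": "Post AE III",
      "K": 1.5e-12,
      "R_nidus": 3970,
      "Q_target": 0.511
    }
  ],
  "dsa_targets": [
    {
      "stage": "baseline",
      "Q_mean": 1.645,
      "Q_sd": 0.04,
      "n": 3
    },
    {
      "stage": "Post AE I",
      "Q_mean": 1.011,
      "n": 1
    },
    {
      "stage": "Post AE III",
      "Q_mean": 0.231,
      "Q_sd": 0.021,
      "n": 3
    }
  ],
  "bolus": {
    "amplitude": 1,
    "width": 1.5,
    "total_time": 5,
    "time_step": 0.01
  },
  "dsa": {
    "frame_rate": 2,
    "diffusivity": 2.2e-10
  }
}
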