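{
  "shape": 0.68,
  "fixed": {
    "shape": true,
    "sigma_G2": true,
    "sigma_M": true
  },
  "phases": {
    "G1": {
      "round0": {
        "mu": 7.11,
        "sigma": 0.18
      },
      "later": {
        "mu": 14.76,
        "sigma": 2.33
      }
    },
    "S": {
      "round0": {
        "mu": 14.76,
        "sigma": 0.37
      },
      "later": {
        "mu": 8.14,
        "sigma": 3.91
      }
    },
    "G2": {
      "round0": {
        "mu": 4.84,
        "sigma": 0.1
      },
      "later": {
        "mu": 4.84,
        "sigma": 0.1
      }
    },
    "M": {
      "round0": {
        "mu": 1.69,
        "sigma": 0.1
      },
      "later": {
        "mu": 1.69,
        "sigma": 0.1
      }
    }
  },
  "blocking": {
    "G1": 0,
    "S": 0.6,
    "G2": 0,
    "M": 0.8,
    "drug_time_h": 32
  }
}
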