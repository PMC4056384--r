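{
  "water": {
    "density_g_cm3": 1,
    "composition": {
      "H": 0.1119,
      "O": 0.8881
    }
  },
  "perpex": {
    "density_g_cm3": 1.19,
    "composition": {
      "H": 0.080538,
      "C": 0.599848,
      "O": 0.319614
    }
  },
  "air": {
    "density_g_cm3": 0.001205,
    "composition": {
      "N": 0.755,
      "O": 0.232,
      "Ar": 0.013
    }
  },
  "NaI": {
    "density_g_cm3": 3.67,
    "composition": {
      "Na": 0.1534,
      "I": 0.8466
    }
  },
  "BGO": {
    "density_g_cm3": 7.13,
    "composition": {
      "Bi": 0.6712,
      "Ge": 0.1749,
      "O": 0.1539
    }
  },
  "GSO": {
    "density_g_cm3": 6.71,
    "composition": {
      "Gd": 0.7442,
      "Si": 0.0665,
      "O": 0.1893
    }
  },
  "CdWO4": {
    "density_g_cm3": 7.9,
    "composition": {
      "Cd": 0.312,
      "W": 0.5103,
      "O": 0.1777
    }
  },
  "lead": {
    "density_g_cm3": 11.34,
    "composition": {
      "Pb": 1
    }
  },
  "tungsten": {
    "density_g_cm3": 19.3,
    "composition": {
      "W": 1
    }
  },
  "tin": {
    "density_g_cm3": 7.31,
    "composition": {
      "Sn": 1
    }
  }
}
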