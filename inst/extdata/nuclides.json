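{
  "comment": "Default nuclear data. Half-lives in hours; emission energies in keV per emission; yields in emissions per decay. Charged lines are mean-energy summaries (beta mean energy, conversion/Auger electrons folded in); photon lines are the principal gamma/X lines. gamma_dose_rate_constant is a nominal point-source screening value in uSv.m2/(MBq.h) and is a configuration quantity, not asserted physics.",
  "nuclides": [
    {
      "name": "Zr-89",
      "half_life_h": 78.41,
      "emissions": [
        {"kind": "charged", "mean_energy_kev": 395.5, "yield": 0.227},
        {"kind": "photon",  "mean_energy_kev": 511.0, "yield": 0.454},
        {"kind": "photon",  "mean_energy_kev": 909.0, "yield": 0.99}
      ],
      "gamma_dose_rate_constant": 0.25
    },
    {
      "name": "Lu-177",
      "half_life_h": 159.53,
      "emissions": [
        {"kind": "charged", "mean_energy_kev": 147.9, "yield": 1.0},
        {"kind": "photon",  "mean_energy_kev": 208.4, "yield": 0.104},
        {"kind": "photon",  "mean_energy_kev": 112.9, "yield": 0.062}
      ],
      "gamma_dose_rate_constant": 0.006
    }
  ]
}
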