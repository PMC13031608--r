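{
  "best_screening_yield": {
    "value": 79.64, "sd": 1.95, "units": "mg/L",
    "source": "20-run screening, run 18"
  },
  "best_ascent_yield": {
    "value": 104.42, "sd": 1.51, "units": "mg/L",
    "source": "steepest-ascent trial 3"
  },
  "optimized_yield": {
    "value": 155.32, "sd": 14.39, "units": "mg/L",
    "source": "third active-learning round, optimized condition"
  },
  "scaffold_assembly_yield": {
    "value": 439.42, "sd": 19.53, "units": "mg/L",
    "source": "scaffold-assembled system at 5 mg/mL scaffold protein"
  }
}
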