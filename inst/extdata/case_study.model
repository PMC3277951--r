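{
  "description": "Negative-feedback enzymatic motif: X converted to Y by enzyme U via complex UX; Y autoinhibits its own production (inverse-linear factor); constant total enzyme u_tot is the input, y the output.",
  "species": ["x", "ux", "y"],
  "parameters": {
    "k1": 1.0,
    "k2": 2.0,
    "k3": 10.0,
    "k4": 0.5,
    "k5": 0.5,
    "k_m1": 3.0,
    "k_m3": 1.0
  },
  "reactions": [
    {"reactants": {}, "products": {"x": 1}, "rate": "k3"},
    {"reactants": {"u": 1, "x": 1}, "products": {"ux": 1}, "rate": "k1"},
    {"reactants": {"ux": 1}, "products": {"u": 1, "x": 1}, "rate": "k_m1"},
    {"reactants": {"ux": 1}, "products": {"u": 1, "y": 1}, "rate": "k2",
     "feedback": {"type": "inverse_linear", "on": "y", "constant": "k5"}},
    {"reactants": {"x": 1}, "products": {}, "rate": "k_m3"},
    {"reactants": {"y": 1}, "products": {}, "rate": "k4"}
  ],
  "input": {"name": "u_tot", "healthy": 0.2, "diseased": 2.0},
  "output": "y",
  "conservation": {"free": "u", "bound": "ux"}
}
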