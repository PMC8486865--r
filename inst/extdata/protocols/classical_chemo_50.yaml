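# Preset: classical_chemo at the base dose (50 mg/m^2 doxorubicin equivalent).
# All omitted parameters take the package defaults (see default_params()).
run:
  protocol: classical_chemo
  dose: 50
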