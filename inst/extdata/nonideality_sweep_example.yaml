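# Example sweep configuration: the four-enthalpy-case non-ideality study of
# a hypothetical 600 K / 300 K binary. Energies in kJ/mol (converted on read).
mode: nonideal
units: kJ/mol
Tm1: [600]
Tm2: [300]
dHm1: [32.64, 12.0]
dHm2: [16.32, 6.0]
a1: [0, -6, -12, -18, -24, -30]
a2: [0, -6, -12, -18, -24, -30]
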