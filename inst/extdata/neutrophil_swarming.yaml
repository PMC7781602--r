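# Neutrophil swarming chamber: cells on glass under 2 mm of medium.
# Cth/(a*rho) = 3.67e5 s/m  =>  v = 2/(pi*3.67e5) ~ 1.73 um/s.
D: 1.25e-10      # m^2/s
a: 1.0           # molecules/s
rho: 1.0         # 1/m^2
Cth: 3.67e+5     # molecules/m^3 with a*rho = 1 (only Cth/(a*rho) matters)
h: 2.0e-3        # m
d: 50.0e-6       # mean neutrophil spacing
H: 10.0e-6       # cell thickness
cell_dim: 2
diff_dim: 3
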