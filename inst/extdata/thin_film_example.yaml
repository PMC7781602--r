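# Thin-film relay example: cells on a surface under a shallow (10 um) medium.
# v = sqrt(a*rho*D/(h*Cth)) = 2e-6 m/s; h*Cth/(a*rho) = 25 s; h << D/v.
D: 1.0e-10       # m^2/s
a: 1.0           # molecules/s
rho: 1.0         # 1/m^2
Cth: 2.5e+6      # molecules/m^3
h: 1.0e-5        # m
d: 2.0e-5        # mean cell spacing (m)
cell_dim: 2
diff_dim: 2
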