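# Canonical parameter sets used across the suite. All are built so the
# asymptotic Heaviside wave speed is exactly 2 um/s, giving natural scales
# D/v = 50 um and D/v^2 = 25 s at D = 1e-10 m^2/s.

v_ref <- 2e-6
D_ref <- 1e-10

# thin film, cells in 2D: h*Cth/(a*rho) = D/v^2 = 25 s
params_22 <- function(D = D_ref) {
  relay_params(D = D, a = 1, rho = 1, Cth = (D_ref / v_ref^2) / 1e-3, h = 1e-3)
}

# channel, cells in 1D: h^2*Cth/(a*rho) = D/v^2
params_11 <- function(D = D_ref) {
  relay_params(D = D, a = 1, rho = 1, Cth = (D_ref / v_ref^2) / (1e-3)^2, h = 1e-3)
}

# half-space, cells in 2D: Cth/(a*rho) = 2/(pi*v)
params_23 <- function(D = D_ref) {
  relay_params(D = D, a = 1, rho = 1, Cth = 2 / (pi * v_ref))
}

# sheet (half-plane), cells in 1D: h*Cth/(a*rho) = 2/(pi*v)
params_12 <- function(D = D_ref) {
  relay_params(D = D, a = 1, rho = 1, Cth = 2 / (pi * v_ref) / 1e-3, h = 1e-3)
}

# full 3D: Cth/(a*rho) = D/v^2
params_33 <- function(D = D_ref) {
  relay_params(D = D, a = 1, rho = 1, Cth = D_ref / v_ref^2)
}

geom_11 <- relay_geometry(1, 1)
geom_12 <- relay_geometry(1, 2)
geom_22 <- relay_geometry(2, 2)
geom_23 <- relay_geometry(2, 3)
geom_33 <- relay_geometry(3, 3)

# neutrophil swarming worked example (thick medium)
swarm_truth <- list(Cth_over_arho = 3.66e5, D = 1.25e-10, ri = 100e-6)
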