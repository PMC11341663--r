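# Shared fixtures: the published operating point and the three materials.

op_geom <- function(h1_over_h2 = 0.5, h2_over_r = 0.2, alpha_deg = 30) {
  geometry_from_ratios(h2_over_r, h1_over_h2, alpha_deg)
}

nh <- function() material("neo_hookean")
gent1 <- function(Jm = 1) material("gent", Jm = Jm)
hgo_mat <- function(K1 = 0.05, K2 = 1) material("hgo", K1 = K1, K2 = K2)

# Central finite difference with step h.
fd_central <- function(f, x, h) (f(x + h) - f(x - h)) / (2 * h)
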