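# Shared fixtures and independent oracles used across the suite.

default_tissue <- tissue_params()          # fixed post-mortem white matter
proto_hib <- ssfp_protocol(TR = 42, alpha = 37, delta = 16.7)
proto_lob <- ssfp_protocol(TR = 27, alpha = 37, delta = 1.2)

# Freeman-Hill style closed form for the unspoiled steady-state echo
# (pre-pulse, no diffusion): an independent analytic reference for the
# q = 0 limit of both SSFP implementations.
fh_ssfp_echo <- function(TR, alpha_deg, T1, T2) {
  a <- alpha_deg * pi / 180
  E1 <- exp(-TR / T1); E2 <- exp(-TR / T2); ca <- cos(a)
  p <- 1 - E1 * ca - E2^2 * (E1 - ca)
  q0 <- E2 * (1 - E1) * (1 + ca)
  r <- (1 - E2^2) / sqrt(p^2 - q0^2)
  abs(tan(a / 2) * (1 - (1 - E1 * ca) * r))
}

angle_deg <- function(a, b) acos(pmin(abs(sum(a * b)), 1)) * 180 / pi

# small direction scheme reused by simulation tests
scheme54 <- generate_directions(54, seed = 2, n_lowb = 6)
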