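## Steady-state DW-SSFP signal.
##
## The magnetization of a repeated [RF pulse -- gradient lobe -- readout]
## block is decomposed into configuration states: transverse orders F_k and
## longitudinal orders Z_k, where one order corresponds to the dephasing
## imparted by one gradient lobe of moment q = gamma*G*delta. Per TR, an RF
## pulse of flip alpha mixes (F_k, F_-k, Z_k); the lobe shifts transverse
## orders up by one; relaxation applies E1/E2; and diffusion attenuates each
## interval by exp(-b_interval * D) with the exact b-factor of a rectangular
## lobe. The acquired signal is the echo pathway: the coherence that the
## lobe refocuses to order zero during the readout (equivalently F_0 just
## before the next pulse).
##
## The steady state of this linear recursion is computed exactly by a
## backward recursion on the ratio r_k = F_-k / F_k (a two-sided continued
## fraction), which costs O(max_order) per protocol and vectorizes over
## protocol/tissue grids. An independently coded iterative simulator
## (epg_steady_state) serves as the numerical oracle for this solution.

# Per-interval diffusion b-factors for a rectangular lobe of duration
# delta at the start of each TR. A transverse state entering the TR at
# order k leaves at order k+1:
#   b_T(k) = q^2 [ delta (k^2 + k + 1/3) + (TR - delta) (k+1)^2 ]
# A longitudinal state keeps its order for the whole TR:
#   b_L(k) = q^2 k^2 TR
# (q in rad/mm, times in s, so b is in s/mm^2.)

#' Steady-state DW-SSFP echo amplitude (vectorized core)
#'
#' Low-level, fully vectorized evaluation of the steady-state
#' diffusion-weighted SSFP echo amplitude as a fraction of M0. All
#' arguments are recycled to a common length. Prefer [dwssfp_signal()] for
#' single protocol objects.
#'
#' @param TR Repetition time, ms.
#' @param alpha Flip angle, degrees.
#' @param delta Diffusion-gradient duration, ms.
#' @param G Gradient amplitude, mT/m.
#' @param T1,T2 Relaxation times, ms.
#' @param D Diffusion coefficient, mm^2/s (0 disables attenuation).
#' @param gamma Gyromagnetic ratio, rad/s/T.
#' @param max_order Highest configuration order retained.
#' @return Echo amplitude(s), fraction of M0.
#' @export
ssfp_echo <- function(TR, alpha, delta, G = 38, T1 = 400, T2 = 45,
                      D = 0.08e-3, gamma = 2.6752e8, max_order = 100L) {
  n <- max(length(TR), length(alpha), length(delta), length(G),
           length(T1), length(T2), length(D))
  TR <- rep_len(as.numeric(TR), n); alpha <- rep_len(as.numeric(alpha), n)
  delta <- rep_len(as.numeric(delta), n); G <- rep_len(as.numeric(G), n)
  T1 <- rep_len(as.numeric(T1), n); T2 <- rep_len(as.numeric(T2), n)
  D <- rep_len(as.numeric(D), n)

  a <- alpha * pi / 180
  cc <- cos(a / 2)^2; ss <- sin(a / 2)^2
  sa <- sin(a); ca <- cos(a)
  E1 <- exp(-TR / T1); E2 <- exp(-TR / T2)
  q <- gamma * G * delta * 1e-9              # rad/mm
  TRs <- TR * 1e-3; ds <- delta * 1e-3       # s
  q2D <- q * q * D

  aT <- function(k) exp(-q2D * (ds * (k * k + k + 1 / 3) +
                                  (TRs - ds) * (k + 1)^2))
  wz <- function(k) {                        # Z_k = wz(k) * (F_k + F_-k)
    aL <- exp(-q2D * k * k * TRs)
    E1 * aL * (sa / 2) / (1 - E1 * aL * ca)
  }

  r <- numeric(n)                            # ratio F_-k / F_k, r_{K+1} = 0
  for (k in seq(max_order, 1L)) {
    wk1 <- wz(k + 1)
    P <- E2 * aT(k) * (cc - sa * wz(k))
    Q <- -E2 * aT(k) * (ss + sa * wz(k))
    R <- E2 * aT(-k - 1) * (cc - sa * wk1)
    S <- -E2 * aT(-k - 1) * (ss + sa * wk1)
    Tk <- R * r + S
    r <- P * Tk / (1 - Q * Tk)
  }
  w1 <- wz(1)
  beta <- E2 * aT(-1) * (cc * r - ss - sa * w1 * (1 + r))  # F_0 = beta F_1
  g <- E2 * aT(0)
  denom <- 1 - g * (ca * beta - E1 * sa * sa * beta / (1 - E1 * ca))
  f1 <- -g * sa * (1 - E1) / (1 - E1 * ca) / denom
  abs(beta * f1)
}

#' Diffusion-weighted SSFP signal for a protocol
#'
#' Exact steady-state echo amplitude of a pulsed-gradient SSFP sequence,
#' evaluated from the configuration-state recursion (see [ssfp_echo()] for
#' the model). The returned value is the coherence refocused by the
#' diffusion gradient before the next RF pulse, as a fraction of M0.
#'
#' With `include_diffusion_attenuation = FALSE` the attenuation factors are
#' disabled (equivalent to D = 0), which gives the "raw" signal level used
#' for SNR bookkeeping: diffusion contrast is then carried entirely by the
#' effective b-value of the protocol.
#'
#' @param protocol An [ssfp_protocol()].
#' @param tissue A [tissue_params()] object.
#' @param include_diffusion_attenuation Logical; include exp(-b D)-type
#'   attenuation of every configuration pathway (default `TRUE`).
#' @param constants A [physical_constants()] object.
#' @param max_order Highest configuration order retained (default 100).
#' @return Signal as a fraction of M0.
#' @examples
#' p <- ssfp_protocol(TR = 42, alpha = 37, delta = 16.7)
#' dwssfp_signal(p, tissue_params())
#' @export
dwssfp_signal <- function(protocol, tissue = tissue_params(),
                          include_diffusion_attenuation = TRUE,
                          constants = physical_constants(),
                          max_order = 100L) {
  stopifnot(inherits(protocol, "ssfp_protocol"),
            inherits(tissue, "tissue_params"))
  D <- if (include_diffusion_attenuation) tissue$D else 0
  ssfp_echo(protocol$TR, protocol$alpha, protocol$delta, protocol$G,
            tissue$T1, tissue$T2, D, gamma = constants$gamma,
            max_order = max_order)
}

#' Effective b-value of a DW-SSFP protocol
#'
#' The b-value of a spin-echo scan that would produce the same fractional
#' diffusion attenuation as the given DW-SSFP protocol in the given tissue:
#' `b_eff = -(1/D) log( S(delta, D) / S(delta, D = 0) )`.
#' Unlike in spin echo, DW-SSFP diffusion contrast depends on T1, T2 and
#' flip angle, so b_eff is tissue- and protocol-specific. It is strictly
#' increasing in both `delta` and `G`, independent of the readout duration,
#' and invariant to overall M0 scaling.
#'
#' @inheritParams dwssfp_signal
#' @return Effective b-value, s/mm^2.
#' @examples
#' beff(ssfp_protocol(TR = 42, alpha = 37, delta = 16.7))  # approx 4450
#' @export
beff <- function(protocol, tissue = tissue_params(),
                 constants = physical_constants(), max_order = 100L) {
  stopifnot(inherits(protocol, "ssfp_protocol"),
            inherits(tissue, "tissue_params"))
  if (tissue$D <= 0)
    stop("b_eff requires D > 0; for D = 0 the attenuation ratio is ",
         "identically 1 -- compare signals directly instead")
  beff_core(protocol$TR, protocol$alpha, protocol$delta, protocol$G,
            tissue$T1, tissue$T2, tissue$D, gamma = constants$gamma,
            max_order = max_order)
}

# vectorized b_eff on raw parameter vectors (optimizer hot path)
beff_core <- function(TR, alpha, delta, G, T1, T2, D, gamma = 2.6752e8,
                      max_order = 100L) {
  S1 <- ssfp_echo(TR, alpha, delta, G, T1, T2, D, gamma, max_order)
  S0 <- ssfp_echo(TR, alpha, delta, G, T1, T2, 0, gamma, max_order)
  -log(S1 / S0) / D
}
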