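#' Iterative steady-state simulator for DW-SSFP (numerical oracle)
#'
#' Simulates the configuration-state (extended-phase-graph) evolution of a
#' repeated pulsed-gradient SSFP block TR by TR until the echo amplitude
#' reaches steady state, and returns its magnitude as a fraction of M0.
#' Each iteration applies, in order: the RF mixing of (F_k, F_-k, Z_k) at
#' constant pulse phase, relaxation over one TR, per-order diffusion
#' attenuation with the exact rectangular-lobe b-factors, longitudinal
#' recovery into Z_0, and the +1 shift of transverse orders by the gradient.
#'
#' This routine shares no code with the closed-path solver in
#' [ssfp_echo()]; it exists to validate that solution (and is what the
#' `validate` verb of the command-line tool tabulates). Agreement is at
#' machine precision for converged tolerances.
#'
#' @param protocol An [ssfp_protocol()].
#' @param tissue A [tissue_params()] object.
#' @param max_order Highest configuration order retained (>= 10).
#' @param tol Relative change in echo amplitude declared converged.
#' @param max_iter Iteration cap (number of TRs).
#' @param constants A [physical_constants()] object.
#' @param start `"equilibrium"` (M0 along z) or `"saturated"` (zero
#'   magnetization); the steady state must not depend on this.
#' @return Echo amplitude, fraction of M0, with attribute `iterations`.
#' @examples
#' p <- ssfp_protocol(TR = 42, alpha = 37, delta = 16.7)
#' epg_steady_state(p, tissue_params())
#' @export
epg_steady_state <- function(protocol, tissue = tissue_params(),
                             max_order = 100L, tol = 1e-8,
                             max_iter = 1e5,
                             constants = physical_constants(),
                             start = c("equilibrium", "saturated")) {
  stopifnot(inherits(protocol, "ssfp_protocol"),
            inherits(tissue, "tissue_params"))
  start <- match.arg(start)
  if (max_order < 10) stop("max_order must be >= 10")
  if (tol <= 0) stop("tol must be > 0")

  K <- as.integer(max_order)
  a <- protocol$alpha * pi / 180
  cc <- cos(a / 2)^2; ss <- sin(a / 2)^2; sa <- sin(a); ca <- cos(a)
  E1 <- exp(-protocol$TR / tissue$T1)
  E2 <- exp(-protocol$TR / tissue$T2)
  q <- constants$gamma * protocol$G * protocol$delta * 1e-9
  TRs <- protocol$TR * 1e-3; ds <- protocol$delta * 1e-3
  q2D <- q * q * tissue$D

  ks <- seq(-K, K)                      # order of each transverse slot
  aT <- exp(-q2D * (ds * (ks^2 + ks + 1 / 3) + (TRs - ds) * (ks + 1)^2))
  kz <- seq(0, K)
  aL <- exp(-q2D * kz^2 * TRs)

  f <- numeric(2 * K + 1)               # F_k before the pulse, k = -K..K
  z <- numeric(K + 1)                   # Z_k before the pulse, k = 0..K
  if (start == "equilibrium") z[1] <- 1
  mid <- K + 1L                         # index of k = 0

  prev <- Inf
  for (it in seq_len(max_iter)) {
    zfull <- z[abs(ks) + 1L]
    fneg <- rev(f)                      # F_{-k}
    fplus <- cc * f - ss * fneg - sa * zfull
    zplus <- ca * z + (sa / 2) * (f[mid + kz] + f[mid - kz])
    f <- c(0, E2 * aT[-(2 * K + 1)] * fplus[-(2 * K + 1)])
    z <- E1 * aL * zplus
    z[1] <- z[1] + (1 - E1)
    cur <- abs(f[mid])
    if (it > 5 && abs(cur - prev) <= tol * max(cur, 1e-30)) {
      if (abs(f[2]) > 1e-8 || abs(f[2 * K + 1]) > 1e-8)
        stop("max_order = ", K, " too small: boundary configuration ",
             "amplitude above 1e-8")
      return(structure(cur, iterations = it))
    }
    prev <- cur
  }
  stop("epg_steady_state did not converge within ", max_iter, " iterations")
}
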