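#' SNR efficiency
#'
#' SNR per square root of total scan time, up to hardware constants:
#' `eta = S[%] * sqrt(T_acq / TR)`. `S` is the raw signal level (fraction
#' of M0) and `rho = T_acq/TR` the readout efficiency, the fraction of each
#' repetition spent acquiring data.
#'
#' @param S Signal, fraction of M0.
#' @param T_acq Readout duration, ms.
#' @param TR Repetition time, ms.
#' @return SNR efficiency in percent-of-M0 units.
#' @examples
#' snr_efficiency(0.0995, 4.11, 100)   # 9.95% M0 at rho = 4.11% -> 2.02
#' @export
snr_efficiency <- function(S, T_acq, TR) {
  if (any(T_acq <= 0) || any(T_acq > TR))
    stop("need 0 < T_acq <= TR")
  100 * S * sqrt(T_acq / TR)
}

# flip angle maximizing the diffusion-weighted echo at fixed (TR, delta)
.best_alpha_ssfp <- function(TR, delta, G, tissue, constants,
                             interval = c(1, 90)) {
  stats::optimize(function(a)
    ssfp_echo(TR, a, delta, G, tissue$T1, tissue$T2, tissue$D,
              gamma = constants$gamma),
    interval = interval, maximum = TRUE, tol = 1e-6)$maximum
}

#' Evaluate a DW-SSFP protocol at fixed TR and delta
#'
#' Computes signal, readout efficiency, SNR efficiency and effective
#' b-value for a DW-SSFP protocol with given repetition time and diffusion
#' gradient duration. With `alpha = "optimal"` the flip angle is chosen to
#' maximise the diffusion-weighted echo by bounded scalar search; the
#' reported `S` (and hence `eta`) is the raw signal level at that flip
#' angle, with diffusion contrast summarised by `b_achieved`.
#'
#' @param TR Repetition time, ms.
#' @param delta Diffusion-gradient duration, ms.
#' @param tissue A [tissue_params()] object.
#' @param alpha Flip angle in degrees, or `"optimal"`.
#' @param G Gradient amplitude, mT/m.
#' @param T_dead Per-TR overhead, ms.
#' @param T_acq_max Readout cap, ms.
#' @param constants A [physical_constants()] object.
#' @return An [optimization_result()].
#' @examples
#' evaluate_ssfp_protocol(42, 16.7)$eta   # about 1.69
#' @export
evaluate_ssfp_protocol <- function(TR, delta, tissue = tissue_params(),
                                   alpha = "optimal", G = 38, T_dead = 5,
                                   T_acq_max = 30,
                                   constants = physical_constants()) {
  T_acq <- min(TR - delta - T_dead, T_acq_max)
  if (T_acq <= 0)
    stop("infeasible timing: TR - delta - T_dead = ", TR - delta - T_dead,
         " ms <= 0")
  if (identical(alpha, "optimal"))
    alpha <- .best_alpha_ssfp(TR, delta, G, tissue, constants)
  proto <- ssfp_protocol(TR = TR, alpha = alpha, delta = delta, G = G,
                         T_dead = T_dead, T_acq_max = T_acq_max)
  S <- dwssfp_signal(proto, tissue, include_diffusion_attenuation = FALSE,
                     constants = constants)
  S_dw <- dwssfp_signal(proto, tissue, constants = constants)
  optimization_result(proto, S = S, S_dw = S_dw, rho = T_acq / TR,
                      b_achieved = beff(proto, tissue, constants))
}

# Vectorized inner solve: for vectors (TR, alpha), find delta such that
# b_eff = target (b_eff is strictly increasing in delta, so bisection is
# safe), then score eta from the D = 0 signal. Returns a data frame.
.score_ssfp_grid <- function(TR, alpha, target, tissue, constants, G,
                             T_dead, T_acq_max, bisect_iter = 40L,
                             max_order = 48L) {
  n <- length(TR)
  lo <- rep(1e-3, n)
  hi <- pmax(TR - T_dead - 1e-3, 2e-3)
  g <- constants$gamma
  # the unweighted signal does not depend on delta: compute once per cell
  S <- ssfp_echo(TR, alpha, 1, G, tissue$T1, tissue$T2, 0, g, max_order)
  att_target <- exp(-target * tissue$D)   # S1/S0 at the target b_eff
  Shi <- ssfp_echo(TR, alpha, hi, G, tissue$T1, tissue$T2, tissue$D,
                   g, max_order)
  feas <- Shi / S <= att_target
  for (i in seq_len(bisect_iter)) {
    mid <- 0.5 * (lo + hi)
    S1 <- ssfp_echo(TR, alpha, mid, G, tissue$T1, tissue$T2, tissue$D,
                    g, max_order)
    high <- S1 / S <= att_target
    hi <- ifelse(high, mid, hi)
    lo <- ifelse(high, lo, mid)
  }
  delta <- 0.5 * (lo + hi)
  T_acq <- pmin(TR - delta - T_dead, T_acq_max)
  ok <- feas & T_acq > 0
  eta <- ifelse(ok, 100 * S * sqrt(pmax(T_acq, 0) / TR), -Inf)
  data.frame(TR = TR, alpha = alpha, delta = delta, S = S,
             T_acq = T_acq, eta = eta, feasible = ok)
}

#' Optimize a DW-SSFP protocol for SNR efficiency at a target b_eff
#'
#' Maximises `eta = S[%] sqrt(T_acq/TR)` over the triplet (TR, delta,
#' alpha) subject to the protocol achieving the requested effective
#' b-value in the given tissue. The readout is assumed to fill the
#' repetition time not spent on the diffusion gradient or overhead
#' (`T_acq = TR - delta - T_dead`, capped). For each (TR, alpha) candidate
#' the gradient duration is solved by bisection (b_eff is strictly
#' increasing in delta, tolerance well below 1e-3 relative); the outer
#' search is a coarse grid followed by two local refinement passes, with
#' ties broken toward shorter TR. Fully deterministic.
#'
#' @param beff_target Target effective b-value, s/mm^2 (> 0).
#' @param tissue A [tissue_params()] object.
#' @param TR_range Search range for TR, ms (default 10-200).
#' @param TR_step,alpha_step Coarse grid steps (ms, degrees).
#' @param alpha_range Search range for the flip angle, degrees.
#' @param G Gradient amplitude, mT/m.
#' @param T_dead Per-TR overhead, ms.
#' @param T_acq_max Readout cap, ms.
#' @param constants A [physical_constants()] object.
#' @param refine Number of local refinement passes (default 2).
#' @param store_trace Keep the coarse grid as `search_trace`.
#' @return An [optimization_result()].
#' @examples
#' \donttest{
#' optimize_dwssfp(4500)   # TR/delta near 33/17.1 ms, eta near 1.86
#' }
#' @export
optimize_dwssfp <- function(beff_target, tissue = tissue_params(),
                            TR_range = c(10, 200), TR_step = 0.5,
                            alpha_range = c(1, 90), alpha_step = 1,
                            G = 38, T_dead = 5, T_acq_max = 30,
                            constants = physical_constants(),
                            refine = 2L, store_trace = FALSE) {
  if (beff_target <= 0) stop("beff_target must be > 0 s/mm^2")
  TRs <- seq(TR_range[1], TR_range[2], by = TR_step)
  als <- seq(alpha_range[1], alpha_range[2], by = alpha_step)
  grid <- expand.grid(alpha = als, TR = TRs)   # TR varies slowest
  sc <- .score_ssfp_grid(grid$TR, grid$alpha, beff_target, tissue,
                         constants, G, T_dead, T_acq_max)
  if (!any(sc$feasible))
    stop("b_eff target ", beff_target, " s/mm^2 unreachable within ",
         "TR <= ", TR_range[2], " ms and G = ", G,
         " mT/m: increase TR_range or G")
  # ties toward shorter TR: grid is ordered by TR, which.max takes the first
  best <- sc[which.max(sc$eta), ]
  trace <- if (store_trace) sc else NULL
  spanTR <- TR_step; spanA <- alpha_step
  for (pass in seq_len(refine)) {
    TRs <- seq(max(TR_range[1], best$TR - spanTR),
               min(TR_range[2], best$TR + spanTR), length.out = 21)
    als <- seq(max(alpha_range[1], best$alpha - spanA),
               min(alpha_range[2], best$alpha + spanA), length.out = 21)
    grid <- expand.grid(alpha = als, TR = TRs)
    sc <- .score_ssfp_grid(grid$TR, grid$alpha, beff_target, tissue,
                           constants, G, T_dead, T_acq_max)
    best <- sc[which.max(sc$eta), ]
    spanTR <- spanTR / 10; spanA <- spanA / 10
  }
  proto <- ssfp_protocol(TR = best$TR, alpha = best$alpha,
                         delta = best$delta, G = G, T_dead = T_dead,
                         T_acq_max = T_acq_max)
  b_ach <- beff(proto, tissue, constants)
  res <- optimization_result(
    proto, S = best$S,
    S_dw = dwssfp_signal(proto, tissue, constants = constants),
    rho = best$T_acq / best$TR, b_achieved = b_ach,
    converged = abs(b_ach - beff_target) / beff_target <= 1e-3,
    search_trace = trace)
  res
}

#' Optimize the DW-SE repetition time for SNR efficiency
#'
#' For a 3D DW-SE acquisition the readout is fixed (30 ms cap) and the
#' echo time is set by the diffusion preparation, leaving TR as the key
#' free parameter: long TR buys longitudinal recovery, short TR buys
#' readout duty cycle. This routine sets TE from the minimum-TE anchor
#' table (or an explicit override), uses the Ernst angle for the
#' excitation, and maximises `eta = S[%] sqrt(T_acq/TR)` over TR by
#' bounded scalar search (the objective is unimodal in TR).
#'
#' @param b Nominal b-value, s/mm^2 (within the anchor range unless `TE`
#'   is given).
#' @param tissue A [tissue_params()] object.
#' @param TE Echo-time override, ms; default `min_te_dwse(b)`.
#' @param T_acq Readout duration, ms.
#' @param T_dead Per-excitation overhead, ms.
#' @param TR_range Search range for TR, ms.
#' @param recovery_model Passed to [dwse_signal()].
#' @param anchors Passed to [min_te_dwse()].
#' @return An [optimization_result()]; `b_achieved` is the nominal `b`.
#' @examples
#' optimize_dwse(4500)$eta    # about 1.1
#' @export
optimize_dwse <- function(b, tissue = tissue_params(), TE = NULL,
                          T_acq = 30, T_dead = 5, TR_range = c(150, 3000),
                          recovery_model = c("ernst", "saturation"),
                          anchors = NULL) {
  recovery_model <- match.arg(recovery_model)
  if (is.null(TE)) TE <- min_te_dwse(b, anchors = anchors)
  TR_min <- max(TR_range[1], TE + T_acq / 2 + T_dead)
  if (TR_min >= TR_range[2]) stop("empty TR search range")
  obj <- function(TR) {
    p <- se_protocol(TR = TR, TE = TE, T_acq = T_acq, b = b,
                     T_dead = T_dead)
    100 * dwse_signal(p, tissue, recovery_model = recovery_model) *
      sqrt(T_acq / TR)
  }
  opt <- stats::optimize(obj, interval = c(TR_min, TR_range[2]),
                         maximum = TRUE, tol = 1e-4)
  TR <- opt$maximum
  proto <- se_protocol(TR = TR, TE = TE, T_acq = T_acq, b = b,
                       T_dead = T_dead)
  S <- dwse_signal(proto, tissue, recovery_model = recovery_model)
  optimization_result(proto, S = S,
                      S_dw = S * exp(-b * tissue$D),
                      rho = T_acq / TR, b_achieved = b)
}

#' Repetition time required by a 2D multi-slice DW-SE acquisition
#'
#' Each slice needs its own excitation block of `TE + T_acq/2 + T_dead`
#' milliseconds, so covering `n_slices` slices forces
#' `TR = n_slices * (TE + T_acq/2 + T_dead)`. At 120 slices and TE =
#' 122 ms this is about 17 s, which is why 3D acquisitions are so much
#' more SNR-efficient post mortem.
#'
#' @param n_slices Number of slices (>= 1).
#' @param TE Echo time, ms.
#' @param T_acq Readout duration, ms.
#' @param T_dead Per-slice overhead, ms.
#' @return Required TR, ms.
#' @examples
#' required_tr_2d(120, 122)   # 17040 ms
#' @export
required_tr_2d <- function(n_slices, TE, T_acq = 30, T_dead = 5) {
  if (any(n_slices < 1)) stop("n_slices must be >= 1")
  if (any(TE <= 0) || any(T_acq <= 0) || any(T_dead < 0))
    stop("timings must be positive")
  n_slices * (TE + T_acq / 2 + T_dead)
}

#' Optimized-efficiency landscape over b, T1 and T2
#'
#' Runs both sequence optimizers over a grid of b-values and relaxation
#' times and tabulates the optimal SNR efficiencies and their ratio
#' (DW-SSFP : DW-SE). Over the plausible fixed-tissue range (T2 = 35-50 ms,
#' T1 = 350-500 ms, b up to 10,000 s/mm^2) the ratio exceeds one
#' everywhere and grows with b.
#'
#' @param b_list b-values, s/mm^2.
#' @param T1_range,T2_range Relaxation times to evaluate, ms.
#' @param tissue_D Diffusion coefficient, mm^2/s.
#' @param TR_step,alpha_step SSFP optimizer grid resolution; the defaults
#'   are coarser than [optimize_dwssfp()]'s for tractable grid sweeps.
#' @param ... Further arguments passed to both optimizers' shared
#'   parameters ([optimize_dwssfp()] / [optimize_dwse()]).
#' @return Data frame with columns `b`, `T1`, `T2`, `eta_ssfp`, `eta_se`,
#'   `ratio`.
#' @examples
#' \donttest{
#' efficiency_landscape(c(1000, 5000), 400, 45)
#' }
#' @export
efficiency_landscape <- function(b_list, T1_range, T2_range,
                                 tissue_D = 0.08e-3, TR_step = 1,
                                 alpha_step = 2, ...) {
  if (!length(b_list) || !length(T1_range) || !length(T2_range))
    stop("empty grid")
  grid <- expand.grid(b = b_list, T1 = T1_range, T2 = T2_range)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    tis <- tissue_params(T1 = grid$T1[i], T2 = grid$T2[i], D = tissue_D)
    es <- optimize_dwssfp(grid$b[i], tis, TR_step = TR_step,
                          alpha_step = alpha_step, refine = 1L, ...)$eta
    ee <- optimize_dwse(grid$b[i], tis)$eta
    c(eta_ssfp = es, eta_se = ee)
  })
  res <- do.call(rbind, res)
  out <- cbind(grid, as.data.frame(res))
  out$ratio <- out$eta_ssfp / out$eta_se
  out
}

#' Stejskal-Tanner echo time matching DW-SSFP efficiency
#'
#' Finds the DW-SE echo time at which the TR-optimized DW-SE SNR
#' efficiency equals the optimal DW-SSFP SNR efficiency at the same
#' b-value. This quantifies how much the diffusion preparation would have
#' to be shortened (e.g. by a single-refocused Stejskal-Tanner scheme) for
#' spin echo to catch up.
#'
#' @param b b-value, s/mm^2.
#' @param tissue A [tissue_params()] object.
#' @param eta_target Optional precomputed DW-SSFP efficiency to match;
#'   when `NULL` it is obtained from [optimize_dwssfp()].
#' @param TE_range Search interval for the echo time, ms.
#' @param ... Passed to [optimize_dwssfp()].
#' @return Matching echo time, ms.
#' @examples
#' \donttest{
#' match_te_equal_efficiency(1000)  # about 74-80 ms
#' }
#' @export
match_te_equal_efficiency <- function(b, tissue = tissue_params(),
                                      eta_target = NULL,
                                      TE_range = c(16, 300), ...) {
  if (is.null(eta_target))
    eta_target <- optimize_dwssfp(b, tissue, ...)$eta
  f <- function(TE) optimize_dwse(b, tissue, TE = TE)$eta - eta_target
  flo <- f(TE_range[1]); fhi <- f(TE_range[2])
  if (flo * fhi > 0)
    stop("no DW-SE echo time in (", TE_range[1], ", ", TE_range[2],
         ") ms matches eta = ", signif(eta_target, 4))
  stats::uniroot(f, TE_range, tol = 1e-4)$root
}

#' Optimal-protocol comparison table
#'
#' Runs both optimizers at a set of b-values and lays out signal (percent
#' of M0), readout efficiency (rho x 100), SNR efficiency and the
#' DW-SSFP : DW-SE efficiency ratio, one sequence per row per b-value.
#'
#' @param b_values b-values / b_eff targets, s/mm^2.
#' @param tissue A [tissue_params()] object.
#' @param ... Passed to [optimize_dwssfp()].
#' @return Data frame with columns `b`, `sequence`, `signal_pct_M0`,
#'   `rho_pct`, `eta`, `ratio`.
#' @examples
#' \donttest{
#' comparison_table(c(1000, 5000))
#' }
#' @export
comparison_table <- function(b_values = c(1000, 3000, 5000, 10000),
                             tissue = tissue_params(), ...) {
  rows <- lapply(b_values, function(b) {
    se <- optimize_dwse(b, tissue)
    sf <- optimize_dwssfp(b, tissue, ...)
    data.frame(
      b = c(b, b), sequence = c("DW-SE", "DW-SSFP"),
      signal_pct_M0 = 100 * c(se$S, sf$S),
      rho_pct = 100 * c(se$rho, sf$rho),
      eta = c(se$eta, sf$eta),
      ratio = c(NA_real_, sf$eta / se$eta))
  })
  do.call(rbind, rows)
}
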