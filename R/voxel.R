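#' Ball-and-stick fiber compartment model
#'
#' Voxel signal model: an isotropic ("ball") compartment of diffusivity `d`
#' plus up to three perfectly anisotropic ("stick") compartments along unit
#' directions `v` with volume fractions `f`. All compartments share the
#' diffusivity. `T1`/`T2` are carried for the DW-SSFP forward model, whose
#' diffusion contrast depends on relaxation (they are ignored by DW-SE).
#'
#' @param S0 Unweighted signal scale (arbitrary units, > 0).
#' @param d Diffusivity, mm^2/s (> 0). The default 1.5e-4 is the stick
#'   (axial) diffusivity for which the default 0.7-stick/0.3-ball voxel
#'   has an orientation-averaged ADC of about 0.08e-3 mm^2/s, the
#'   fixed-tissue value (stick ADC averages to d/3 over the sphere).
#' @param f Stick volume fractions, each in `[0, 1]`, summing to <= 1.
#' @param v Matrix of unit stick directions, one row per stick.
#' @param T1,T2 Relaxation times, ms.
#' @return An object of class `fiber_model`.
#' @examples
#' fiber_model(1, f = 0.7, v = c(0, 0, 1))
#' @export
fiber_model <- function(S0 = 1, d = 1.5e-4, f = numeric(0),
                        v = matrix(numeric(0), 0, 3), T1 = 400, T2 = 45) {
  v <- matrix(as.numeric(v), ncol = 3)
  f <- as.numeric(f)
  if (length(f) != nrow(v))
    stop("need one volume fraction per stick direction")
  if (S0 <= 0) stop("S0 must be > 0")
  if (d <= 0) stop("d must be > 0 mm^2/s")
  if (any(f < 0) || any(f > 1) || sum(f) > 1)
    stop("fractions must lie in [0, 1] and sum to <= 1")
  if (length(f)) {
    nrm <- sqrt(rowSums(v^2))
    if (any(abs(nrm - 1) > 1e-9)) stop("stick directions must be unit norm")
  }
  structure(list(S0 = S0, d = d, f = f, v = v, T1 = T1, T2 = T2),
            class = "fiber_model")
}

#' @export
print.fiber_model <- function(x, ...) {
  cat(sprintf(
    "Ball-and-stick model: %d stick(s), d = %g mm^2/s, f = [%s], S0 = %g\n",
    length(x$f), x$d, paste(signif(x$f, 3), collapse = ", "), x$S0))
  invisible(x)
}

# ---- sequence forward models -------------------------------------------
#
# A forward model is a list with elements
#   att(D)  : attenuation of the weighted volumes at diffusivity D
#   att_low(D): attenuation of the low-b volumes
#   label   : "dwse" or "dwssfp"
# Attenuations are relative to the sequence's unweighted signal, so the
# predicted measurement is S0 * (mixture of compartment attenuations); S0
# absorbs the sequence's absolute signal level.

.forward_dwse <- function(b, b_low = 0) {
  list(att = function(D) exp(-b * D),
       att_low = function(D) exp(-b_low * D),
       label = "dwse")
}

# DW-SSFP attenuation is S(D)/S(0) at the voxel's T1/T2; evaluated through
# a monotone spline lookup so that MCMC never re-solves the steady state.
.forward_dwssfp <- function(protocol, lowb_protocol, T1, T2,
                            D_max = 2.5e-3, n_grid = 401L,
                            constants = physical_constants()) {
  grid <- seq(0, D_max, length.out = n_grid)
  tab <- function(p) {
    S <- ssfp_echo(p$TR, p$alpha, p$delta, p$G, T1, T2, grid,
                   gamma = constants$gamma)
    stats::splinefun(grid, S / S[1], method = "monoH.FC")
  }
  list(att = tab(protocol), att_low = tab(lowb_protocol), label = "dwssfp")
}

.forward_for <- function(sequence, lowb_sequence, tissue,
                         constants = physical_constants()) {
  if (inherits(sequence, "se_protocol")) {
    b_low <- if (is.null(lowb_sequence)) 0 else lowb_sequence$b
    .forward_dwse(sequence$b, b_low)
  } else if (inherits(sequence, "ssfp_protocol")) {
    if (is.null(lowb_sequence))
      lowb_sequence <- ssfp_protocol(TR = 27, alpha = 37, delta = 1.2,
                                     G = sequence$G)
    .forward_dwssfp(sequence, lowb_sequence, tissue$T1, tissue$T2,
                    constants = constants)
  } else stop("sequence must be an se_protocol or ssfp_protocol")
}

# compartment attenuation matrix: rows = measurements (low-b first, then
# weighted), cols = ball, stick_1, ...
.compartment_atts <- function(fwd, vectors, n_lowb, d, V) {
  nf <- if (is.null(V)) 0L else nrow(V)
  ndw <- nrow(vectors)
  out <- matrix(0, n_lowb + ndw, nf + 1L)
  out[, 1] <- c(rep(fwd$att_low(d), n_lowb), rep(fwd$att(d), ndw))
  if (nf) for (j in seq_len(nf)) {
    u2 <- (vectors %*% V[j, ])^2
    # low-b spoiler gradient taken along z; its weighting is negligible
    out[, j + 1] <- c(rep(fwd$att_low(d * V[j, 3]^2), n_lowb),
                      fwd$att(d * u2))
  }
  out
}

#' Predict noiseless voxel signals
#'
#' Evaluates the ball-and-stick mixture for every measurement of a scheme
#' under a given sequence. For DW-SE the compartment attenuations are
#' `exp(-b d)` (ball) and `exp(-b d (g.v)^2)` (sticks); for DW-SSFP the
#' same mixture is taken over the steady-state signal evaluated at the
#' compartment's effective diffusivity, at the voxel's T1/T2. Low-b
#' volumes (`scheme$n_lowb` of them, returned first) use the corresponding
#' low-b protocol: `b = 0` for spin echo, the short-spoiler SSFP protocol
#' (TR 27 ms, 37 deg, delta 1.2 ms by default) for SSFP.
#'
#' @param model A [fiber_model()].
#' @param sequence An [se_protocol()] or [ssfp_protocol()].
#' @param scheme A [direction_scheme()].
#' @param lowb_sequence Optional protocol for the low-b volumes.
#' @param constants A [physical_constants()] object.
#' @return Numeric vector of length `scheme$n_lowb + nrow(scheme$vectors)`.
#' @examples
#' sch <- direction_scheme(diag(3), n_lowb = 1)
#' m <- fiber_model(1, 0.08e-3, f = 0.7, v = c(0, 0, 1))
#' predict_voxel_signals(m, se_protocol(530, 122, b = 4500), sch)
#' @export
predict_voxel_signals <- function(model, sequence, scheme,
                                  lowb_sequence = NULL,
                                  constants = physical_constants()) {
  stopifnot(inherits(model, "fiber_model"),
            inherits(scheme, "direction_scheme"))
  tissue <- tissue_params(T1 = model$T1, T2 = model$T2, D = model$d)
  fwd <- .forward_for(sequence, lowb_sequence, tissue, constants)
  A <- .compartment_atts(fwd, scheme$vectors, scheme$n_lowb, model$d,
                         if (length(model$f)) model$v else NULL)
  wts <- c(1 - sum(model$f), model$f)
  as.numeric(model$S0 * (A %*% wts))
}

#' Add Rician (magnitude) noise
#'
#' Each average receives independent complex Gaussian noise of standard
#' deviation `sigma` per channel; its magnitude is taken, and the
#' `n_averages` magnitudes are averaged. This reproduces the noise floor
#' of magnitude MRI: a zero signal acquires mean `sigma * sqrt(pi/2)`, and
#' at high SNR the mean approaches `sqrt(signal^2 + sigma^2)`.
#'
#' @param signals Noiseless signal vector.
#' @param sigma Noise standard deviation (>= 0).
#' @param n_averages Number of magnitude averages.
#' @param seed Optional integer seed (deterministic output when given).
#' @return Noisy signal vector of the same length.
#' @examples
#' add_rician_noise(rep(0, 5), 1, seed = 1)
#' @export
add_rician_noise <- function(signals, sigma, n_averages = 1L, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(signals)
  if (!is.null(seed)) set.seed(seed)
  n <- length(signals)
  acc <- numeric(n)
  for (a in seq_len(n_averages)) {
    re <- signals + stats::rnorm(n, 0, sigma)
    im <- stats::rnorm(n, 0, sigma)
    acc <- acc + sqrt(re^2 + im^2)
  }
  acc / n_averages
}
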