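#' Physical constants
#'
#' Container for the physical constants used throughout the package. The
#' proton gyromagnetic ratio defaults to 2.6752e8 rad s^-1 T^-1 and the
#' maximum gradient amplitude to 38 mT/m (a typical whole-body clinical
#' system). Both may be overridden, e.g. from a configuration file, but the
#' gyromagnetic ratio should normally be left alone.
#'
#' @param gamma Proton gyromagnetic ratio, rad s^-1 T^-1.
#' @param G_max Maximum gradient amplitude, mT/m.
#' @return An object of class `physical_constants`.
#' @examples
#' physical_constants()
#' @export
physical_constants <- function(gamma = 2.6752e8, G_max = 38) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, is.numeric(G_max),
            length(G_max) == 1L)
  if (gamma <= 0) stop("gamma must be > 0 (got ", gamma, ")")
  if (G_max <= 0) stop("G_max must be > 0 mT/m (got ", G_max, ")")
  structure(list(gamma = gamma, G_max = G_max),
            class = "physical_constants")
}

#' Tissue relaxation and diffusion parameters
#'
#' Describes a voxel (or tissue compartment) by its longitudinal and
#' transverse relaxation times and apparent diffusion coefficient. The
#' default preset corresponds to formalin-fixed post-mortem white matter:
#' T1 = 400 ms, T2 = 45 ms, D = 0.08e-3 mm^2/s. Fixation shortens T2 and T1
#' and reduces the ADC by roughly a factor of 5-10 relative to in-vivo
#' tissue, which is what makes sequence choice so consequential here.
#'
#' @param T1 Longitudinal relaxation time, ms. Must be positive.
#' @param T2 Transverse relaxation time, ms. Must be positive and <= T1.
#' @param D Apparent diffusion coefficient, mm^2/s. Must be >= 0.
#' @return An object of class `tissue_params`.
#' @examples
#' tissue_params()                       # fixed-tissue default
#' tissue_params(T1 = 1000, T2 = 80, D = 0.8e-3)
#' @export
tissue_params <- function(T1 = 400, T2 = 45, D = 0.08e-3) {
  stopifnot(is.numeric(T1), is.numeric(T2), is.numeric(D),
            length(T1) == 1L, length(T2) == 1L, length(D) == 1L)
  if (T1 <= 0) stop("T1 must be > 0 ms (got ", T1, ")")
  if (T2 <= 0) stop("T2 must be > 0 ms (got ", T2, ")")
  if (T2 > T1) stop("T2 must not exceed T1 (got T2 = ", T2,
                    " > T1 = ", T1, " ms)")
  if (D < 0) stop("D must be >= 0 mm^2/s (got ", D, ")")
  structure(list(T1 = T1, T2 = T2, D = D), class = "tissue_params")
}

#' @export
print.tissue_params <- function(x, ...) {
  cat(sprintf("Tissue: T1 = %g ms, T2 = %g ms, D = %g mm^2/s\n",
              x$T1, x$T2, x$D))
  invisible(x)
}

#' @export
print.physical_constants <- function(x, ...) {
  cat(sprintf("Constants: gamma = %g rad/s/T, G_max = %g mT/m\n",
              x$gamma, x$G_max))
  invisible(x)
}

#' Diffusion-weighted spin-echo protocol
#'
#' Timing and flip-angle description of one DW-SE configuration. The
#' repetition block of one excitation is `TE + T_acq/2 + T_dead` (echo time,
#' half the readout, plus fixed overhead), so `TR` must be at least that
#' long. The readout duration is capped (30 ms by default) because longer
#' EPI readouts incur unacceptable distortion.
#'
#' @param TR Repetition time, ms.
#' @param TE Echo time, ms. Must satisfy `0 < TE < TR`.
#' @param alpha Excitation flip angle, degrees, in (0, 90].
#' @param T_acq Readout duration, ms (default 30, the distortion-limited cap).
#' @param b Nominal b-value, s/mm^2 (>= 0).
#' @param T_dead Non-acquisition overhead per excitation block, ms.
#' @param T_acq_max Cap on the readout duration, ms.
#' @return An object of class `se_protocol`.
#' @examples
#' se_protocol(TR = 530, TE = 122, b = 4500)
#' @export
se_protocol <- function(TR, TE, alpha = NULL, T_acq = 30, b = 0,
                        T_dead = 5, T_acq_max = 30) {
  stopifnot(is.numeric(TR), is.numeric(TE), is.numeric(T_acq), is.numeric(b))
  if (TE <= 0) stop("TE must be > 0 ms (got ", TE, ")")
  if (TE >= TR) stop("TE must be < TR (got TE = ", TE, ", TR = ", TR, " ms)")
  if (b < 0) stop("b must be >= 0 s/mm^2 (got ", b, ")")
  if (T_acq <= 0) stop("T_acq must be > 0 ms (got ", T_acq, ")")
  if (T_acq > T_acq_max)
    stop("T_acq must be <= ", T_acq_max, " ms cap (got ", T_acq, ")")
  if (!is.null(alpha)) {
    if (alpha <= 0 || alpha > 90)
      stop("alpha must be in (0, 90] degrees (got ", alpha, ")")
  }
  block <- TE + T_acq / 2 + T_dead
  if (TR < block)
    stop("TR must be >= TE + T_acq/2 + T_dead = ", block,
         " ms for a feasible excitation block (got TR = ", TR, ")")
  structure(list(TR = TR, TE = TE, alpha = alpha, T_acq = T_acq, b = b,
                 T_dead = T_dead),
            class = "se_protocol")
}

#' @export
print.se_protocol <- function(x, ...) {
  cat(sprintf(
    "DW-SE protocol: TR/TE = %g/%g ms, T_acq = %g ms, b = %g s/mm^2%s\n",
    x$TR, x$TE, x$T_acq, x$b,
    if (is.null(x$alpha)) ", alpha = Ernst" else sprintf(", alpha = %g deg",
                                                        x$alpha)))
  invisible(x)
}

#' Diffusion-weighted SSFP protocol
#'
#' Timing, flip-angle and diffusion-gradient description of one DW-SSFP
#' configuration: a short-TR sequence with a single unbalanced gradient lobe
#' of duration `delta` and amplitude `G` per TR. The readout fills whatever
#' time is not spent on the diffusion gradient or fixed overhead,
#' `T_acq = TR - delta - T_dead`, capped at `T_acq_max`. The gradient
#' first moment `q = gamma * G * delta` (rad/mm) is recomputed from the
#' stored fields whenever needed, never cached.
#'
#' @param TR Repetition time, ms.
#' @param alpha Flip angle, degrees, in (0, 180).
#' @param delta Diffusion-gradient lobe duration, ms, in (0, TR).
#' @param G Diffusion-gradient amplitude, mT/m.
#' @param T_dead Non-acquisition overhead per TR, ms (default 5, conservative).
#' @param T_acq_max Cap on the readout duration, ms (default 30).
#' @param require_readout If `TRUE` (default), constructions whose derived
#'   readout `TR - delta - T_dead` is non-positive are rejected. Signal
#'   modelling does not need a readout, so validation-grid code may disable
#'   this check.
#' @return An object of class `ssfp_protocol` with the derived `T_acq`.
#' @examples
#' ssfp_protocol(TR = 42, alpha = 37, delta = 16.7)   # implemented high-b
#' ssfp_protocol(TR = 27, alpha = 37, delta = 1.2)    # low-b / spoiler
#' @export
ssfp_protocol <- function(TR, alpha, delta, G = 38, T_dead = 5,
                          T_acq_max = 30, require_readout = TRUE) {
  stopifnot(is.numeric(TR), is.numeric(alpha), is.numeric(delta),
            is.numeric(G))
  if (TR <= 0) stop("TR must be > 0 ms (got ", TR, ")")
  if (delta <= 0 || delta >= TR)
    stop("delta must lie in (0, TR) ms (got delta = ", delta,
         ", TR = ", TR, ")")
  if (alpha <= 0 || alpha >= 180)
    stop("alpha must be in (0, 180) degrees (got ", alpha, ")")
  if (G <= 0) stop("G must be > 0 mT/m (got ", G, ")")
  T_acq <- min(TR - delta - T_dead, T_acq_max)
  if (require_readout && T_acq <= 0)
    stop("infeasible readout: TR - delta - T_dead = ", TR - delta - T_dead,
         " ms <= 0")
  if (delta / TR > 0.9)
    warning("delta/TR = ", round(delta / TR, 3),
            " > 0.9: readout likely infeasible")
  structure(list(TR = TR, alpha = alpha, delta = delta, G = G,
                 T_dead = T_dead, T_acq = T_acq),
            class = "ssfp_protocol")
}

#' @export
print.ssfp_protocol <- function(x, ...) {
  cat(sprintf(
    "DW-SSFP protocol: TR = %g ms, alpha = %g deg, delta = %g ms, G = %g mT/m, T_acq = %g ms\n",
    x$TR, x$alpha, x$delta, x$G, x$T_acq))
  invisible(x)
}

#' Gradient first moment of an SSFP protocol
#'
#' `q = gamma * G * delta` converted to rad/mm. Computed from the protocol
#' fields on every call.
#'
#' @param protocol An [ssfp_protocol()].
#' @param constants A [physical_constants()] object.
#' @return q in rad/mm.
#' @export
q_moment <- function(protocol, constants = physical_constants()) {
  stopifnot(inherits(protocol, "ssfp_protocol"))
  # G [mT/m] * 1e-6 -> T/mm ; delta [ms] * 1e-3 -> s
  constants$gamma * (protocol$G * 1e-6) * (protocol$delta * 1e-3)
}

#' Bundle an evaluated or optimized protocol with its figures of merit
#'
#' @param protocol An [se_protocol()] or [ssfp_protocol()].
#' @param S Steady-state signal as a fraction of M0, with diffusion
#'   attenuation excluded (the "raw" signal level that sets SNR).
#' @param S_dw Diffusion-weighted signal (fraction of M0) at the achieved
#'   b-value, for reference.
#' @param rho Readout efficiency `T_acq/TR` (fraction).
#' @param b_achieved Achieved (effective) b-value, s/mm^2.
#' @param converged Logical search-status flag.
#' @param search_trace Optional data frame of evaluated candidates.
#' @return An object of class `optimization_result` whose `eta` element is
#'   `100 * S * sqrt(rho)` (SNR efficiency in percent-of-M0 units).
#' @export
optimization_result <- function(protocol, S, S_dw = NA_real_, rho,
                                b_achieved, converged = TRUE,
                                search_trace = NULL) {
  stopifnot(is.numeric(S), is.numeric(rho))
  if (rho <= 0 || rho > 1) stop("rho must lie in (0, 1] (got ", rho, ")")
  if (S < 0) stop("S must be >= 0 (got ", S, ")")
  structure(list(protocol = protocol, S = S, S_dw = S_dw, rho = rho,
                 eta = 100 * S * sqrt(rho), b_achieved = b_achieved,
                 converged = converged, search_trace = search_trace),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  print(x$protocol)
  cat(sprintf(
    "  S = %.3f %%M0, rho = %.2f %%, eta = %.3f, b_achieved = %.0f s/mm^2%s\n",
    100 * x$S, 100 * x$rho, x$eta, x$b_achieved,
    if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Read a flat key/value configuration file
#'
#' Configuration files are flat YAML mappings. Recognised keys (all
#' optional): `T1`, `T2`, `D` (tissue); `gamma`, `G_max` (constants);
#' `T_acq_max`, `T_dead`, `TR_min`, `TR_max` (constraints). Unknown keys are
#' kept so callers can round-trip user settings.
#'
#' @param path Path to a YAML file.
#' @return A named list with elements `tissue` ([tissue_params()]),
#'   `constants` ([physical_constants()]), `constraints` (list), and `extra`
#'   (unrecognised keys).
#' @seealso [write_config()]
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a flat key/value mapping: ", path)
  pick <- function(key, default) if (!is.null(raw[[key]])) raw[[key]] else default
  tissue <- tissue_params(T1 = pick("T1", 400), T2 = pick("T2", 45),
                          D = pick("D", 0.08e-3))
  constants <- physical_constants(gamma = pick("gamma", 2.6752e8),
                                  G_max = pick("G_max", 38))
  constraints <- list(T_acq_max = pick("T_acq_max", 30),
                      T_dead = pick("T_dead", 5),
                      TR_min = pick("TR_min", NULL),
                      TR_max = pick("TR_max", NULL))
  known <- c("T1", "T2", "D", "gamma", "G_max", "T_acq_max", "T_dead",
             "TR_min", "TR_max")
  list(tissue = tissue, constants = constants, constraints = constraints,
       extra = raw[setdiff(names(raw), known)])
}

#' Write a flat key/value configuration file
#'
#' Inverse of [read_config()]: serialises tissue parameters, constants and
#' constraints to a flat YAML mapping at full precision.
#'
#' @param config A list as returned by [read_config()], or a list with any
#'   of the elements `tissue`, `constants`, `constraints`, `extra`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  flat <- list()
  if (!is.null(config$tissue))
    flat[c("T1", "T2", "D")] <- config$tissue[c("T1", "T2", "D")]
  if (!is.null(config$constants))
    flat[c("gamma", "G_max")] <- config$constants[c("gamma", "G_max")]
  for (key in names(config$constraints))
    if (!is.null(config$constraints[[key]]))
      flat[[key]] <- config$constraints[[key]]
  for (key in names(config$extra)) flat[[key]] <- config$extra[[key]]
  yaml::write_yaml(flat, path, precision = 17)
  invisible(path)
}
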