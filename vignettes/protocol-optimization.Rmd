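---
title: "Choosing between DW-SE and DW-SSFP for post-mortem diffusion MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing between DW-SE and DW-SSFP for post-mortem diffusion MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwssfp)
```

## The problem

Formalin fixation changes brain tissue in three ways that matter for
diffusion imaging: T2 falls to roughly 45 ms, T1 falls to roughly 400 ms,
and the apparent diffusion coefficient drops five- to ten-fold, to about
0.08e-3 mm^2/s. Conventional diffusion-weighted spin echo (DW-SE) needs a
long echo time to play out its diffusion-encoding gradients, and at
T2 = 45 ms an echo time above 100 ms discards most of the signal before
it is ever read out. Diffusion-weighted steady-state free precession
(DW-SSFP) instead applies one short unbalanced gradient lobe per
repetition; diffusion sensitivity accumulates over many repetitions
through the coherence pathways that survive from one TR to the next, so
strong effective weighting is reached at echo times of tens of
milliseconds. The price is a signal that depends on T1, T2 and flip
angle in a complicated way, which this package models exactly.

All interfaces use milliseconds for times, mT/m for gradients, mm^2/s
for diffusivities, s/mm^2 for b-values and degrees for angles; signals
are fractions of the equilibrium magnetization M0 and are reported in
percent.

## Signal models

**DW-SE.** `dwse_signal()` is `L * exp(-TE/T2)`, optionally times
`exp(-b D)`, with the longitudinal factor `L` evaluated over the
recovery period `TR - TE` (recovery is treated as suppressed until the
echo, since the refocusing pulses disrupt it). Two recovery models are
provided: the spoiled steady state at a flip angle (the Ernst angle by
default) and plain saturation recovery; they agree in the long-TR limit.
The minimum achievable echo time versus b-value is not modelled from
gradient waveforms; it is interpolated through three anchors of an
implemented twice-refocused sequence (91 ms at b = 1000, 122 ms at
4500, 148 ms at 10000 s/mm^2) using a monotone spline on `b^(1/3)`,
because encoding duration grows sublinearly with b at fixed gradient
amplitude. Absolute DW-SE signal levels inherit the ambiguity of the
unstated details of that implementation (exact intermediate echo times,
excitation history); the package documents a 15% band for them, and the
tests hold the long-TR example (6.65% of M0 at TR = 17 s, TE = 122 ms)
to 0.5%.

**DW-SSFP.** The magnetization of the repeated
[pulse - gradient lobe - readout] block is expanded in configuration
states: transverse orders F_k and longitudinal orders Z_k, one order per
gradient-lobe dephasing `q = gamma G delta` (rad/mm). An RF pulse mixes
(F_k, F_-k, Z_k); the lobe shifts transverse orders up by one;
relaxation multiplies by E1/E2; and diffusion attenuates each interval
by `exp(-b_int D)` with the exact b-factor of a rectangular lobe (for a
transverse state entering at order k,
`b_int = q^2 [delta (k^2 + k + 1/3) + (TR - delta)(k + 1)^2]`; for a
longitudinal state, `q^2 k^2 TR`). The measured signal is the echo
pathway: the coherence the lobe refocuses to order zero during the
readout, equal to F_0 just before the next pulse.

`ssfp_echo()` computes the **exact** steady state of this recursion by a
backward recursion on the order ratios (a two-sided continued fraction),
which costs O(max order) per evaluation and vectorizes over parameter
grids. We deliberately implement the exact solution rather than one of
the classical approximate closed forms for this sequence: the package
carries an independently coded, pulse-by-pulse iterative simulator
(`epg_steady_state()`), and the test suite holds the two to within
5e-3 relative over a factorial grid of TR, delta, alpha, T1, T2
(observed agreement is at machine precision, since both solve the same
recursion by different algorithms). Approximate treatments that freeze
the per-order attenuation factors lose accuracy as `delta/TR` grows;
reproductions of protocol tables computed with such approximations can
therefore differ from ours by a few percent at the strongest weightings,
which is visible in one of the acceptance comparisons.

Truncation: configuration orders above `max_order` (default 100) are
dropped; amplitudes decay at least like E2 per order, and the tests
verify the echo is unchanged to 1e-8 when the order is doubled. The
simulator declares convergence when the echo changes by less than 1e-8
relative between repetitions (cap 1e5), and errors out if the boundary
order carries amplitude above 1e-8.

## Effective b-value

DW-SSFP has no b-value in the spin-echo sense, so comparisons use the
effective b-value: `beff()` returns
`-(1/D) log[S(delta, D) / S(delta, D = 0)]`, the spin-echo b-value that
would give the same fractional attenuation in the same tissue. It is
strictly increasing in delta and G, independent of readout bookkeeping,
invariant to M0, and only weakly dependent on the D used to define it
(a few percent across the plausible fixed-tissue range, which the tests
check). For the implemented high-b protocol (TR/alpha/delta =
42 ms/37 deg/16.7 ms at 38 mT/m) the exact model gives 4453 s/mm^2; for
the low-b companion (27/37/1.2) it gives 19.95 s/mm^2.

## SNR-efficiency optimization

SNR efficiency is `eta = S[%] sqrt(T_acq/TR)`: signal times the square
root of the fraction of scan time spent acquiring. Throughout the
optimizers, `S` is the **raw** signal with diffusion attenuation
excluded — diffusion contrast is fixed by the b_eff constraint, so the
raw level is what sets the SNR of the fitted contrast. The readout of
DW-SSFP fills the repetition time not used by the gradient or overhead
(`T_acq = TR - delta - T_dead`, `T_dead` = 5 ms, capped at 30 ms, the
duration beyond which EPI distortion becomes unacceptable); DW-SE uses
the full 30 ms cap and leaves TR as its only free parameter.

`optimize_dwssfp()` maximizes eta over (TR, delta, alpha) subject to
hitting the b_eff target: for each (TR, alpha) on a grid (TR 10-200 ms
in 0.5 ms steps, alpha 1-90 deg in 1 deg steps) the gradient duration is
solved by bisection — b_eff is strictly increasing in delta, so bisection
is safe and reaches the target to much better than 0.1% — followed by
two local refinement passes; ties break toward shorter TR. The search is
deterministic and is checked against a brute-force grid at 4x finer
resolution in the tests. `optimize_dwse()` uses bounded scalar search on
its unimodal objective and is checked against a 0.1 ms brute-force grid.
With the fixed-tissue defaults this machinery reproduces the expected
behaviour: the b_eff = 4500 optimum sits at TR/delta close to
33/17.1 ms, the duty-cycle-limited 42/16.7 protocol loses about 10% of
that efficiency, and the DW-SSFP : DW-SE efficiency ratio exceeds one
over the whole plausible tissue grid (T1 350-500 ms, T2 35-50 ms,
b up to 10000 s/mm^2) and grows with b.

## Synthetic voxels and the uncertainty comparison

The generator mirrors the study acquisition: 54 electrostatically
repelled, antipodally symmetric gradient directions (energy within 1% of
a multi-restart optimum), 6 low-b volumes in the spin-echo arm and 30
short-spoiler volumes (TR 27 ms, delta 1.2 ms) in the SSFP arm, and
Rician magnitude noise with optional averaging. Voxels follow the
ball-and-stick mixture: an isotropic compartment plus up to three
sticks, all sharing one diffusivity `d`. The stick is the *axial*
diffusivity, and a stick's orientation average is d/3, so the default
`d = 1.5e-4 mm^2/s` is chosen to give the default 0.7-stick/0.3-ball
voxel an orientation-averaged ADC of about 0.08e-3 mm^2/s — the
fixed-tissue value. (Using 0.08e-3 for `d` itself would simulate voxels
with mean ADC near 0.04e-3, inconsistent with the tissue the protocols
are optimized for.)

The spin-echo forward model is mono-exponential per compartment; the
SSFP forward model evaluates the exact steady-state signal at each
compartment's effective diffusivity and the voxel's T1/T2, through a
monotone spline lookup over D (401 knots to 2.5e-3 mm^2/s) so the MCMC
never re-solves the steady state.

`fit_ball_and_stick()` samples (S0, log d, log sigma, directions,
fractions) by blockwise Metropolis-Hastings under a Gaussian likelihood
with unknown noise level. The Gaussian likelihood on Rician data is the
usual approximation, adequate at SNR of about 5 and above; at very low
SNR the noise floor biases d downward. Priors are uniform on the sphere
(random-walk proposals on the embedded vector are symmetric and
area-correct), uniform fractions with `sum(f) <= 1`, and broad uniform
on the logs. Proposal scales adapt toward 40% acceptance during the
1000-iteration burn-in and are then frozen; 1250 further iterations are
thinned by 25 into 50 retained draws, and a diagnostic warning flags
post-burn-in acceptance outside [0.05, 0.8] (noiseless inputs trigger it
by design, as sigma collapses). Two extra moves address the geometry of
two-stick posteriors: a coordinated in-plane rotation of the stick pair
(equal-fraction orthogonal crossings are first-order degenerate under
that rotation, because the summed stick dyads form a projector) and a
fraction exchange at constant sum (when two sticks overlap, only such a
move lets mass drain from the redundant one). Automatic relevance
determination places the classical `1/f` shrinkage density (shape
parameter 0, truncated at a 1e-6 floor) on secondary fractions; draws
are reported with sticks ordered by descending fraction, and a second
fiber is called "supported" when the posterior mean of f2 is at least
0.05.

`cone_of_uncertainty()` reports the 95th percentile (default quantile
definition) of the angles between the sampled directions and their mean,
where the mean is the principal eigenvector of the average dyad (so
antipodal draws reinforce rather than cancel).

`compare_protocols_uncertainty()` encodes matched scan time through the
noise levels: each arm's per-volume noise is its (normalized) unweighted
signal divided by its SNR, and the SNR ratio between the arms equals the
ratio of the protocols' SNR efficiencies, since SNR per volume at equal
total time scales with eta. With the implemented protocols and the
package's DW-SE model this computed ratio is about 1.53. Per voxel the
comparison reports `100 (u_SE - u_SSFP) / mean(u_SE, u_SSFP)`, positive
when DW-SSFP has the lower uncertainty; the acceptance test requires the
DW-SSFP arm's mean cone angle to be strictly lower over 100 voxels.

What the generator does **not** emulate: spatial structure and partial
voluming, eddy currents and distortion, B1 or B0 inhomogeneity, noise
correlations between coils, orientation dispersion within a stick, or
relaxation differences between compartments. Passing tests therefore
demonstrate correctness of the models and the fitting machinery under
the stated noise model, not performance on real scans.

## Identifiability of crossings

At the acquisition's effective b-value (about 4500 s/mm^2) and
fixed-tissue diffusivity, an equal-fraction 90-degree crossing is only
marginally identifiable: the first-order term of the two-stick
attenuation depends on the pair's plane but not on the in-plane angle,
and the symmetry-breaking quartic term is comparable to the noise at
SNR 30 with 54 directions. The test suite therefore checks crossing
recovery at b = 10000 s/mm^2, the strongest weighting the optimization
study covers, where recovery to within 10 degrees is reliable; this
mirrors the empirical situation, in which second-fiber support at
b near 4500 is borderline.

## Problem sizes used by the checks

The acceptance checks run the full optimizer grids for five b_eff
targets, a 324-point model-vs-simulator factorial, a 64-cell efficiency
landscape at a coarsened grid (TR step 2 ms, alpha step 3 deg), 100
voxels per arm for the matched-time comparison, 100 voxels per forward
model for orientation recovery, 40 voxels for the ARD false-support
rate (with a doubled chain for stable posterior means), and 10 noise
realizations for the crossing check. These sizes keep every property
estimate's Monte-Carlo error well inside the margins being asserted.
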