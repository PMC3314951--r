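# dwssfp

Quantitative sequence comparison for diffusion MRI of whole post-mortem
human brains. Fixation leaves tissue with short T2 (~45 ms), moderate T1
(~400 ms) and a five- to ten-fold reduced diffusivity
(~0.08 × 10⁻³ mm²/s). Under those conditions diffusion-weighted spin
echo (DW-SE) pays for its diffusion encoding with long echo times and
loses most of its signal, while diffusion-weighted steady-state free
precession (DW-SSFP) accumulates diffusion sensitivity across many short
repetitions. This package puts that trade-off on a quantitative footing
for protocol design, and simulates its consequences for fiber-orientation
estimation.

It provides:

- **Steady-state signal models.** `dwse_signal()` for spin echo;
  `dwssfp_signal()` computes the exact steady-state echo of the
  pulsed-gradient SSFP sequence from its configuration-state
  (extended-phase-graph) recursion, solved in closed path by a two-sided
  continued fraction. An independently coded iterative simulator,
  `epg_steady_state()`, validates it.
- **Effective b-value.** `beff()` maps a DW-SSFP protocol onto the
  spin-echo b-value giving the same fractional attenuation,
  `b_eff = -(1/D) ln[S(δ, D) / S(δ, 0)]`.
- **SNR-efficiency optimization.** With readout efficiency
  `ρ = T_acq/TR`, the figure of merit is `η = S[%]·√ρ` (SNR per unit
  square-root scan time). `optimize_dwssfp()` maximizes η over
  (TR, δ, α) subject to a b_eff target; `optimize_dwse()` optimizes the
  spin-echo TR; `efficiency_landscape()` sweeps both over b, T1, T2;
  `comparison_table()` lays the optima out side by side.
- **Synthetic voxels and Bayesian fitting.** `generate_directions()`
  (electrostatic repulsion), `predict_voxel_signals()` (ball-and-stick
  mixture under either sequence, including the T1/T2-dependent DW-SSFP
  forward model), `add_rician_noise()`, `fit_ball_and_stick()`
  (Metropolis–Hastings with optional automatic relevance determination
  for a second fiber), `cone_of_uncertainty()` (95% orientation
  confidence angle) and `compare_protocols_uncertainty()` (matched
  scan-time comparison of the two sequences).

A command-line wrapper (`exec/dwssfp`) exposes the same functionality as
verbs (`signal`, `beff`, `optimize-ssfp`, `optimize-se`, `landscape`,
`table1`, `match-te`, `validate`, `simulate`, `fit`,
`compare-uncertainty`), each writing CSV/JSON plus a manifest into a run
directory.

## Worked example

```r
library(dwssfp)

tissue <- tissue_params()        # T1 = 400 ms, T2 = 45 ms, D = 0.08e-3 mm^2/s

# the implemented high-b protocol: TR 42 ms, flip 37 deg, 16.7 ms lobe
p <- ssfp_protocol(TR = 42, alpha = 37, delta = 16.7)
beff(p, tissue)
#> [1] 4453.365

# efficiency of that duty-cycle-limited protocol, flip angle optimized
evaluate_ssfp_protocol(42, 16.7, tissue)$eta
#> [1] 1.688698

# unconstrained optimum at the same diffusion weighting
opt <- optimize_dwssfp(4500, tissue)
opt
#> DW-SSFP protocol: TR = 32.855 ms, alpha = 32.72 deg, delta = 17.1345 ms, G = 38 mT/m, T_acq = 10.7205 ms
#>   S = 3.249 %M0, rho = 32.63 %, eta = 1.856, b_achieved = 4500 s/mm^2

# spin echo at the same b-value manages far less
optimize_dwse(4500, tissue)$eta
#> [1] 1.087302
```

Read: at b_eff = 4500 s/mm² in fixed tissue, the optimal DW-SSFP
protocol (TR ≈ 33 ms, δ ≈ 17.1 ms) achieves η ≈ 1.86 — 3.2% of M0 raw
signal while spending a third of every repetition acquiring — and the
gradient-heating-limited implementable protocol still reaches η ≈ 1.69,
whereas TR-optimized DW-SE reaches only η ≈ 1.09: DW-SSFP delivers
roughly 1.6–1.7× the SNR efficiency, a factor that grows with b-value.

The uncertainty side of the story:

```r
cmp <- compare_protocols_uncertainty(n_voxels = 20, snr_se = 20, seed = 1)
round(c(mean_u_se = mean(cmp$u_se), mean_u_ssfp = mean(cmp$u_ssfp),
        mean_pct_diff = attr(cmp, "mean_pct_diff")), 2)
#>     mean_u_se   mean_u_ssfp mean_pct_diff
#>          4.73          3.36         33.64
```

At matched scan time the DW-SSFP arm's 95% orientation-uncertainty cone
is systematically smaller (positive percent difference favours
DW-SSFP).

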