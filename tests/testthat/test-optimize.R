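test_that("SNR efficiency is the advertised arithmetic", {
  # Table-style check: 9.95 %M0 at rho = 4.11% gives eta = 2.02
  expect_equal(snr_efficiency(0.0995, 4.11, 100), 2.02, tolerance = 0.005)
  expect_equal(snr_efficiency(0.0314, 32.35, 100), 1.79, tolerance = 0.005)
  # full-duty readout: eta equals the percent signal
  expect_equal(snr_efficiency(0.05, 42, 42), 5)
  expect_error(snr_efficiency(0.05, 50, 42), "T_acq")
})

test_that("protocol evaluation reports a consistent figure set", {
  r <- evaluate_ssfp_protocol(42, 16.7, alpha = 37)
  expect_equal(r$eta, 100 * r$S * sqrt(r$rho), tolerance = 1e-12)
  expect_equal(r$rho, (42 - 16.7 - 5) / 42)
  expect_equal(r$b_achieved, beff(proto_hib), tolerance = 1e-6)
  # near-spoiler gradient: diffusion weighting (and its cost) vanish
  r0 <- evaluate_ssfp_protocol(42, 0.1, alpha = 37)
  expect_lt(r0$b_achieved, 10)
  expect_gt(r0$eta, r$eta)
  expect_error(evaluate_ssfp_protocol(20, 16.7), "infeasible")
})

test_that("flip-angle optimization beats any fixed angle", {
  ropt <- evaluate_ssfp_protocol(42, 16.7)
  for (al in c(20, 37, 75))
    expect_gte(ropt$S_dw,
               evaluate_ssfp_protocol(42, 16.7, alpha = al)$S_dw)
})

test_that("DW-SE optimizer agrees with a brute-force TR grid", {
  for (b in c(1000, 10000)) {
    r <- optimize_dwse(b)
    TRs <- seq(r$protocol$TE + 20, 3000, by = 0.1)
    eta_grid <- vapply(TRs, function(TR)
      snr_efficiency(dwse_signal(se_protocol(TR, r$protocol$TE, b = b)),
                     30, TR), numeric(1))
    expect_equal(r$eta, max(eta_grid), tolerance = 1e-3)
    expect_equal(r$protocol$TR, TRs[which.max(eta_grid)], tolerance = 1)
  }
})

test_that("DW-SE optimal TR sits in the expected band and eta falls with b", {
  etas <- TRs <- numeric(0)
  for (b in c(1000, 3000, 5000, 10000)) {
    r <- optimize_dwse(b)
    etas <- c(etas, r$eta); TRs <- c(TRs, r$protocol$TR)
  }
  expect_true(all(TRs > 450 & TRs < 850))
  expect_true(all(diff(etas) < 0))
  # instant recovery pushes the optimum to the shortest feasible TR
  rfast <- optimize_dwse(4500, tissue_params(T1 = 1, T2 = 1),
                         TR_range = c(100, 3000))
  expect_lt(rfast$protocol$TR, 122 + 15 + 5 + 3)
})

test_that("constrained DW-SSFP optimizer hits its target and the oracle", {
  r <- optimize_dwssfp(3000)
  expect_true(r$converged)
  expect_lt(abs(r$b_achieved - 3000) / 3000, 1e-3)
  expect_equal(r$eta, 100 * r$S * sqrt(r$rho), tolerance = 1e-10)
  # brute-force oracle at 4x finer resolution near the reported optimum
  fine <- dwssfp:::.score_ssfp_grid(
    TR = rep(seq(r$protocol$TR - 2, r$protocol$TR + 2, by = 0.125),
             each = 33),
    alpha = rep(seq(r$protocol$alpha - 4, r$protocol$alpha + 4,
                    by = 0.25), 33),
    target = 3000, tissue = default_tissue,
    constants = physical_constants(), G = 38, T_dead = 5, T_acq_max = 30)
  expect_equal(r$eta, max(fine$eta), tolerance = 5e-3)
  # unreachable target is diagnosed
  expect_error(optimize_dwssfp(5e5, TR_range = c(10, 60)), "unreachable")
})

test_that("duty-cycle-limited protocol is below the unconstrained optimum", {
  eta_limited <- evaluate_ssfp_protocol(42, 16.7)$eta
  eta_opt <- optimize_dwssfp(4500)$eta
  expect_gt(eta_opt, eta_limited)
})

test_that("2D slice-coverage TR is the per-slice block times slice count", {
  expect_equal(required_tr_2d(120, 122, 30, 5), 17040)
  expect_equal(required_tr_2d(1, 122, 30, 5), 142)
  expect_error(required_tr_2d(0, 122), "n_slices")
})

test_that("landscape cells equal direct optimizer calls", {
  cell <- efficiency_landscape(4500, 400, 45)
  expect_equal(nrow(cell), 1L)
  direct_ssfp <- optimize_dwssfp(4500, TR_step = 1, alpha_step = 2,
                                 refine = 1L)$eta
  expect_equal(cell$eta_ssfp, direct_ssfp, tolerance = 1e-6)
  expect_equal(cell$eta_se, optimize_dwse(4500)$eta, tolerance = 1e-6)
  expect_equal(cell$ratio, cell$eta_ssfp / cell$eta_se)
  expect_error(efficiency_landscape(numeric(0), 400, 45), "empty")
})

test_that("matched echo time reproduces the DW-SSFP efficiency", {
  eta_ssfp <- optimize_dwssfp(1000)$eta
  te <- match_te_equal_efficiency(1000, eta_target = eta_ssfp)
  expect_equal(optimize_dwse(1000, TE = te)$eta, eta_ssfp,
               tolerance = 5e-3)
  expect_error(match_te_equal_efficiency(1000, eta_target = 100,
                                         TE_range = c(20, 200)),
               "matches eta")
})
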