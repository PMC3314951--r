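test_that("constructors validate physical bounds with named diagnostics", {
  expect_error(tissue_params(T1 = -1), "T1")
  expect_error(tissue_params(T2 = 0), "T2")
  expect_error(tissue_params(T1 = 40, T2 = 45), "T2 must not exceed T1")
  expect_error(tissue_params(D = -1e-4), "D")
  expect_error(se_protocol(TR = 100, TE = 122), "TE must be < TR")
  expect_error(se_protocol(TR = 500, TE = 122, b = -1), "b")
  expect_error(se_protocol(TR = 500, TE = 122, T_acq = 40), "cap")
  expect_error(se_protocol(TR = 115, TE = 100), "feasible excitation block")
  expect_error(ssfp_protocol(TR = 42, alpha = 37, delta = 50), "delta")
  expect_error(ssfp_protocol(TR = 42, alpha = 0, delta = 10), "alpha")
  expect_error(ssfp_protocol(TR = 20, alpha = 37, delta = 16.7),
               "infeasible readout")
  expect_warning(ssfp_protocol(TR = 42, alpha = 37, delta = 40,
                               T_dead = 0, require_readout = FALSE),
                 "0.9")
  expect_error(physical_constants(G_max = 0), "G_max")
})

test_that("default presets match the fixed-tissue and scanner values", {
  tis <- tissue_params()
  expect_equal(tis$T1, 400)
  expect_equal(tis$T2, 45)
  expect_equal(tis$D, 0.08e-3)
  cst <- physical_constants()
  expect_equal(cst$gamma, 2.6752e8)
  expect_equal(cst$G_max, 38)
})

test_that("SSFP readout is derived, and q is recomputed from fields", {
  p <- ssfp_protocol(TR = 42, alpha = 37, delta = 16.7, T_dead = 5)
  expect_equal(p$T_acq, 42 - 16.7 - 5)
  # a long-TR protocol hits the 30 ms readout cap
  p2 <- ssfp_protocol(TR = 80, alpha = 37, delta = 16.7)
  expect_equal(p2$T_acq, 30)
  q <- q_moment(p)
  expect_equal(q, 2.6752e8 * 38e-6 * 16.7e-3)   # rad/mm
  p$delta <- 10   # mutate field: q must follow
  expect_equal(q_moment(p), 2.6752e8 * 38e-6 * 10e-3)
})

test_that("optimization_result enforces the eta identity", {
  p <- ssfp_protocol(TR = 42, alpha = 37, delta = 16.7)
  r <- optimization_result(p, S = 0.0243, rho = 20.3 / 42,
                           b_achieved = 4470)
  expect_equal(r$eta, 100 * 0.0243 * sqrt(20.3 / 42), tolerance = 1e-12)
  expect_error(optimization_result(p, S = 0.02, rho = 1.2,
                                   b_achieved = 1), "rho")
})

test_that("config files round-trip tissue, constants and constraints", {
  path <- tempfile(fileext = ".yaml")
  cfg <- list(tissue = tissue_params(T1 = 385.5, T2 = 47.25, D = 9.5e-5),
              constants = physical_constants(gamma = 2.675e8, G_max = 40),
              constraints = list(T_acq_max = 25, T_dead = 4.5),
              extra = list(note = "roundtrip"))
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$tissue$T1, 385.5)
  expect_equal(back$tissue$T2, 47.25)
  expect_equal(back$tissue$D, 9.5e-5)
  expect_equal(back$constants$G_max, 40)
  expect_equal(back$constraints$T_acq_max, 25)
  expect_equal(back$constraints$T_dead, 4.5)
  expect_equal(back$extra$note, "roundtrip")
})
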