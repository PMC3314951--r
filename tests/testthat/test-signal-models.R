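test_that("Ernst angle matches its closed form and maximises the signal", {
  expect_equal(ernst_angle(1e6, 400), 90, tolerance = 1e-6)
  expect_lt(ernst_angle(1e-6, 400), 0.01)
  expect_equal(ernst_angle(639, 400), acos(exp(-639 / 400)) * 180 / pi)
  expect_equal(ernst_angle(639, 400), 78.32, tolerance = 1e-2)
  # grid-search oracle: the spoiled steady state is maximal at that angle
  E1 <- exp(-639 / 400)
  spgr <- function(a_deg) {
    a <- a_deg * pi / 180
    sin(a) * (1 - E1) / (1 - cos(a) * E1)
  }
  grid <- seq(0.1, 90, by = 0.01)
  expect_equal(grid[which.max(spgr(grid))], ernst_angle(639, 400),
               tolerance = 0.01)
  # at the Ernst angle the longitudinal factor is sqrt((1-E1)/(1+E1))
  expect_equal(spgr(ernst_angle(639, 400)), sqrt((1 - E1) / (1 + E1)),
               tolerance = 1e-10)
  expect_error(ernst_angle(-5, 400), "recovery_time")
})

test_that("DW-SE signal reproduces the long-TR 2D protocol level", {
  p2d <- se_protocol(TR = 17000, TE = 122, b = 4500)
  for (model in c("ernst", "saturation"))
    expect_equal(dwse_signal(p2d, recovery_model = model), 0.0665,
                 tolerance = 0.005)
  # fully relaxed limit
  prelax <- se_protocol(TR = 1e9, TE = 1e-5, alpha = 90)
  expect_equal(dwse_signal(prelax), 1, tolerance = 1e-6)
  # optimal-TR protocol at b = 1000: within the documented 15% of 9.95 %M0
  p730 <- se_protocol(TR = 730, TE = 91, b = 1000)
  expect_equal(dwse_signal(p730, recovery_model = "saturation"), 0.0995,
               tolerance = 0.15)
  # recovery models agree as TR grows
  for (TE in c(91, 122, 148)) {
    pl <- se_protocol(TR = 30000, TE = TE)
    expect_equal(dwse_signal(pl, recovery_model = "ernst"),
                 dwse_signal(pl, recovery_model = "saturation"),
                 tolerance = 1e-4)
  }
  # diffusion attenuation flag multiplies by exp(-b D)
  expect_equal(dwse_signal(p2d, include_diffusion_attenuation = TRUE) /
                 dwse_signal(p2d), exp(-4500 * 0.08e-3))
})

test_that("minimum TE interpolation honours anchors and monotonicity", {
  expect_equal(min_te_dwse(1000), 91)
  expect_equal(min_te_dwse(4500), 122)
  expect_equal(min_te_dwse(10000), 148)
  te <- min_te_dwse(seq(1000, 10000, by = 100))
  expect_true(all(diff(te) > 0))
  expect_error(min_te_dwse(500), "anchored range")
  expect_silent(min_te_dwse(12000, extrapolate = TRUE))
})

test_that("DW-SSFP closed form reduces to the analytic echo at D = 0", {
  for (TR in c(20, 42, 80)) for (al in c(15, 37, 70)) {
    p <- suppressWarnings(ssfp_protocol(TR, al, delta = 5,
                                        require_readout = FALSE))
    expect_equal(
      dwssfp_signal(p, tissue_params(D = 0)),
      fh_ssfp_echo(TR, al, 400, 45), tolerance = 1e-9,
      label = sprintf("TR=%g alpha=%g", TR, al))
  }
  # vanishing excitation gives vanishing signal
  p0 <- ssfp_protocol(42, 0.01, 16.7)
  expect_lt(dwssfp_signal(p0), 1e-4)
})

test_that("DW-SSFP signal decreases monotonically with diffusivity", {
  Ds <- seq(0, 4e-4, length.out = 9)
  s <- ssfp_echo(42, 37, 16.7, 38, 400, 45, Ds)
  expect_true(all(diff(s) < 0))
  s2 <- ssfp_echo(27, 70, 8, 38, 350, 50, Ds)
  expect_true(all(diff(s2) < 0))
})

test_that("effective b-value behaves like a diffusion contrast measure", {
  # strictly increasing in delta and in G
  ds <- seq(2, 25, by = 2)
  be <- vapply(ds, function(d)
    beff(ssfp_protocol(42, 37, d, require_readout = FALSE)), numeric(1))
  expect_true(all(diff(be) > 0))
  Gs <- seq(10, 38, by = 4)
  bg <- vapply(Gs, function(G)
    beff(ssfp_protocol(42, 37, 16.7, G = G)), numeric(1))
  expect_true(all(diff(bg) > 0))
  # vanishing gradient area gives vanishing b_eff
  expect_lt(beff(ssfp_protocol(42, 37, 1e-3, require_readout = FALSE)),
            1e-3)
  # independent of readout bookkeeping (T_dead only changes T_acq)
  expect_equal(beff(ssfp_protocol(42, 37, 16.7, T_dead = 5)),
               beff(ssfp_protocol(42, 37, 16.7, T_dead = 10)))
  # weak D-dependence across plausible fixed-tissue D
  b1 <- beff(proto_hib, tissue_params(D = 0.07e-3))
  b2 <- beff(proto_hib, tissue_params(D = 0.09e-3))
  expect_lt(abs(b1 - b2) / beff(proto_hib, default_tissue), 0.05)
  # D = 0 rejected with guidance
  expect_error(beff(proto_hib, tissue_params(D = 0)), "D > 0")
})
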