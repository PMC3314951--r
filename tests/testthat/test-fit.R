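make_samples <- function(V) {
  structure(list(draws = data.frame(v1x = V[, 1], v1y = V[, 2],
                                    v1z = V[, 3]),
                 n_fibers = 1L), class = "posterior_samples")
}

test_that("cone of uncertainty: degenerate, uniform and Watson cases", {
  # identical draws collapse to zero angle
  V <- matrix(rep(c(0, 0, 1), 25), ncol = 3, byrow = TRUE)
  expect_equal(cone_of_uncertainty(make_samples(V)), 0)
  expect_error(cone_of_uncertainty(make_samples(V[1:5, ])), "20")

  # uniform draws: 95th percentile of acos|cos(theta)| (antipodal) --
  # brute-force Monte-Carlo oracle
  set.seed(42)
  U <- matrix(stats::rnorm(3 * 4000), ncol = 3)
  U <- U / sqrt(rowSums(U^2))
  cone <- cone_of_uncertainty(make_samples(U))
  mc <- stats::quantile(acos(abs(U %*% c(0, 0, 1))) * 180 / pi, 0.95,
                        names = FALSE)
  expect_equal(cone, mc, tolerance = 0.02)

  # Watson-concentrated draws vs numerically integrated 95% quantile
  kappa <- 20
  set.seed(43)
  tt <- numeric(0)
  while (length(tt) < 3000) {
    u <- stats::runif(5000)
    keep <- stats::runif(5000) < exp(kappa * (u^2 - 1))
    tt <- c(tt, u[keep])
  }
  tt <- tt[1:3000]
  phi <- stats::runif(3000, 0, 2 * pi)
  st <- sqrt(1 - tt^2)
  W <- cbind(st * cos(phi), st * sin(phi), tt)
  coneW <- cone_of_uncertainty(make_samples(W))
  dens <- function(th) exp(kappa * cos(th)^2) * sin(th)
  Z <- stats::integrate(dens, 0, pi / 2)$value
  cdf <- function(th) stats::integrate(dens, 0, th)$value / Z
  q95 <- stats::uniroot(function(th) cdf(th) - 0.95, c(1e-4, pi / 2))$root
  expect_equal(coneW, q95 * 180 / pi, tolerance = 0.04)
})

test_that("noiseless single-fiber data are recovered almost exactly", {
  truth <- c(0.6, 0.64, 0.48); truth <- truth / sqrt(sum(truth^2))
  m <- fiber_model(1, f = 0.7, v = truth)
  se <- se_protocol(530, 122, b = 4500)
  y <- predict_voxel_signals(m, se, scheme54)
  fit <- suppressWarnings(fit_ball_and_stick(y, se, scheme54, seed = 7))
  expect_lt(angle_deg(mean_direction(fit), truth), 1)
  expect_lt(cone_of_uncertainty(fit), 1)
  expect_equal(mean(fit$draws$f1), 0.7, tolerance = 0.02)
  expect_equal(mean(fit$draws$d), m$d, tolerance = 0.05 * m$d)
})

test_that("draws respect the model invariants and record their seed", {
  truth <- c(0, 0, 1)
  m <- fiber_model(1, f = 0.6, v = truth)
  se <- se_protocol(530, 122, b = 4500)
  y <- add_rician_noise(predict_voxel_signals(m, se, scheme54), 0.05,
                        seed = 21)
  fit <- fit_ball_and_stick(y, se, scheme54, seed = 31)
  expect_equal(fit$seed, 31)
  expect_true(all(fit$draws$f1 >= 0 & fit$draws$f1 <= 1))
  expect_true(all(fit$draws$d > 0))
  nrm <- sqrt(rowSums(as.matrix(fit$draws[, c("v1x", "v1y", "v1z")])^2))
  expect_equal(nrm, rep(1, nrow(fit$draws)), tolerance = 1e-9)
  refit <- fit_ball_and_stick(y, se, scheme54, seed = 31)
  expect_identical(fit$draws, refit$draws)   # seed reproduces the chain
})

test_that("orientation recovery at SNR 20 with both forward models", {
  se <- se_protocol(530, 122, b = 4500)
  set.seed(5)
  errs <- matrix(NA_real_, 8, 2)
  sch_sf <- direction_scheme(scheme54$vectors, n_lowb = 30)
  for (i in 1:8) {
    v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
    m <- fiber_model(1, f = 0.7, v = v)
    y1 <- add_rician_noise(predict_voxel_signals(m, se, scheme54),
                           1 / 20, seed = 50 + i)
    f1 <- fit_ball_and_stick(y1, se, scheme54, seed = 60 + i)
    y2 <- add_rician_noise(
      predict_voxel_signals(m, proto_hib, sch_sf, proto_lob),
      1 / 20, seed = 70 + i)
    f2 <- fit_ball_and_stick(y2, proto_hib, sch_sf,
                             lowb_sequence = proto_lob, seed = 80 + i)
    errs[i, ] <- c(angle_deg(mean_direction(f1), v),
                   angle_deg(mean_direction(f2), v))
  }
  expect_lt(stats::median(errs[, 1]), 5)
  expect_lt(stats::median(errs[, 2]), 5)
})

test_that("chains from different seeds agree on the mean direction", {
  truth <- c(1, 2, 2) / 3
  m <- fiber_model(1, f = 0.7, v = truth)
  se <- se_protocol(530, 122, b = 4500)
  y <- add_rician_noise(predict_voxel_signals(m, se, scheme54), 1 / 20,
                        seed = 77)
  mu1 <- mean_direction(fit_ball_and_stick(y, se, scheme54, seed = 1))
  mu2 <- mean_direction(fit_ball_and_stick(y, se, scheme54, seed = 2))
  expect_lt(angle_deg(mu1, mu2), 2)
})

test_that("ARD suppresses an unsupported second fiber", {
  se <- se_protocol(530, 122, b = 4500)
  v <- c(0.28, 0.96, 0) / sqrt(0.28^2 + 0.96^2)
  m <- fiber_model(1, f = 0.7, v = v)
  y <- add_rician_noise(predict_voxel_signals(m, se, scheme54), 1 / 20,
                        seed = 91)
  fit <- suppressWarnings(
    fit_ball_and_stick(y, se, scheme54, n_fibers = 2, ard = TRUE,
                       seed = 92))
  expect_lt(mean(fit$draws$f2), 0.05)
  # the dominant fiber is still recovered
  expect_lt(angle_deg(mean_direction(fit, 1), v), 5)
  expect_error(fit_ball_and_stick(y, se, scheme54, n_fibers = 1,
                                  ard = TRUE), "ard requires")
})

test_that("cone shrinks (on average) as averaging increases", {
  se <- se_protocol(530, 122, b = 4500)
  truth <- c(0, 1, 0)
  m <- fiber_model(1, f = 0.7, v = truth)
  y0 <- predict_voxel_signals(m, se, scheme54)
  cones <- vapply(c(1L, 4L, 16L), function(na) {
    cs <- vapply(1:4, function(r) {
      y <- add_rician_noise(y0, 0.08, n_averages = na, seed = 200 + r)
      cone_of_uncertainty(fit_ball_and_stick(y, se, scheme54,
                                             seed = 300 + r))
    }, numeric(1))
    mean(cs)
  }, numeric(1))
  expect_true(all(diff(cones) < 0))
})

test_that("matched-time comparison favours DW-SSFP and scales with time", {
  res <- compare_protocols_uncertainty(n_voxels = 6, snr_se = 20,
                                       seed = 11)
  expect_gt(attr(res, "eta_ratio"), 1)
  expect_gt(attr(res, "mean_pct_diff"), 0)
  expect_true(all(res$u_se > 0 & res$u_ssfp > 0))
  # quadrupling the spin-echo scan time halves its noise: cones shrink
  res4 <- compare_protocols_uncertainty(n_voxels = 6, snr_se = 20,
                                        seed = 11, time_factor_se = 4)
  expect_lt(mean(res4$u_se), mean(res$u_se))
})
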