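test_that("bleach-rate estimation recovers linear decay exactly", {
  k <- 0:999
  expect_equal(estimate_bleach_rate(rep(5, 1000))$R_per_sample, 0)

  est <- estimate_bleach_rate(1000 * (1 - 1e-6 * k))
  expect_equal(est$R_per_sample, 1e-6, tolerance = 1e-12)
  expect_equal(est$intercept, 1000, tolerance = 1e-9)
  expect_lt(est$residual_rms, 1e-9)

  ## two-point slope
  r <- 0.01
  est2 <- estimate_bleach_rate(c(1000, 1000 * (1 - r)))
  expect_equal(est2$R_per_sample, r, tolerance = 1e-12)

  expect_error(estimate_bleach_rate(c(5), list(c(1, 1))), "singular")
  expect_error(estimate_bleach_rate(rep(5, 10), c(3, 20)), "invalid")
})

test_that("bleach estimation over window unions ignores excluded samples", {
  k <- 0:999
  f <- 1000 * (1 - 2e-5 * k)
  f[301:700] <- 0  # corrupted mid-section, excluded from the windows
  est <- estimate_bleach_rate(f, list(c(1, 300), c(701, 1000)))
  expect_equal(est$R_per_sample, 2e-5, tolerance = 1e-10)
})

test_that("additive compensation inverts linear decay of a flat baseline", {
  k <- 0:499
  f <- 800 * (1 - 5e-6 * k)
  est <- estimate_bleach_rate(f)
  out <- compensate_additive(f, est)
  expect_equal(out, rep(800, 500), tolerance = 1e-10)
  ## R = 0 is the identity; sample 0 is always unchanged
  expect_identical(compensate_additive(f, 0), f)
  expect_equal(compensate_additive(f, est)[1], f[1])
})

test_that("multiplicative compensation: exact inverse and first-order bound", {
  k <- 0:999
  R <- 0.05 / 999  # 5% total bleach: R * k_max = 0.05
  f <- 1200 * (1 - R * k)

  expect_identical(compensate_multiplicative(f, 0, "first_order"), f)
  expect_identical(compensate_multiplicative(f, 0, "exact_division"), f)

  out_exact <- compensate_multiplicative(f, R, "exact_division")
  expect_equal(out_exact, rep(1200, 1000), tolerance = 1e-10)

  out_fo <- compensate_multiplicative(f, R, "first_order")
  rel <- abs(out_fo - 1200) / 1200
  expect_lte(max(rel), (R * max(k))^2)     # documented residual bound
  expect_equal(max(rel), 0.05^2, tolerance = 0.01)  # bound is tight

  ## envelope collapse guards exact division
  expect_error(compensate_multiplicative(rep(1, 300), 0.01, "exact_division"),
               "envelope")
})

test_that("averaging repeats is a per-sample mean with metadata bookkeeping", {
  proto <- tiny_protocol()
  g <- const_tau_gating()
  fl0 <- quiet_fluorophore()
  co <- conductance_params()
  sw <- simulate_sweep(proto, 0, g, fl0, co)
  same <- average_repeats(list(sw, sw, sw))
  expect_equal(same$F_channels, sw$F_channels)
  expect_equal(same$meta$n_averaged, 3L)

  ## symmetric perturbation cancels exactly
  up <- sw; dn <- sw
  up$F_channels[[1]] <- sw$F_channels[[1]] + 0.25
  dn$F_channels[[1]] <- sw$F_channels[[1]] - 0.25
  expect_equal(average_repeats(list(up, dn))$F_channels[[1]],
               sw$F_channels[[1]])

  other <- simulate_sweep(tiny_protocol(step_mV = -80), 0, g, fl0, co)
  expect_error(average_repeats(list(sw, other)), "mismatch")
})

test_that("baseline normalisation and delta-F/F arithmetic", {
  ## already at baseline 1: unchanged; constant 5: becomes 1
  n1 <- normalize_baseline(rep(1, 100), c(1, 50))
  expect_equal(n1$F_norm, rep(1, 100))
  expect_equal(mean(n1$F_norm[1:50]), 1, tolerance = 1e-9)
  n5 <- normalize_baseline(rep(5, 100), c(1, 50))
  expect_equal(n5$F_norm, rep(1, 100))

  ## baseline mean 2.0, step level 1.9: step reads 0.95, dF/F = -5%
  tr <- c(rep(2, 50), rep(1.9, 50))
  nn <- normalize_baseline(tr, c(1, 50))
  expect_equal(delta_f_over_f(nn, c(51, 100)), -5, tolerance = 1e-12)
  expect_equal(delta_f_over_f(nn, c(1, 50)), 0, tolerance = 1e-12)

  ## F_norm = 0.983 over the window reads -1.7%
  n983 <- normalize_baseline(c(rep(1, 10), rep(0.983, 10)), c(1, 10))
  expect_equal(delta_f_over_f(n983, c(11, 20)), -1.7, tolerance = 1e-12)

  expect_error(normalize_baseline(rep(-1, 10), c(1, 5)), "baseline")
  expect_error(delta_f_over_f(n1, c(90, 200)), "window")
})

test_that("simulate -> estimate -> compensate -> normalize round trip", {
  ## the pipeline must reproduce the bleach-free decomposition: exactly for
  ## exact division, within the first-order bound otherwise
  preset <- get_preset("K308R_A337_300ATP")
  fl_clean <- preset$fluorophore
  fl_clean$noise_sd_pct <- 0
  fl_bleach_free <- fl_clean
  fl_bleach_free$bleach_R_per_sample <- 0

  sw_b <- simulate_sweep(preset$protocol, preset$atp_uM, preset$gating,
                         fl_clean, preset$conductance)
  sw_0 <- simulate_sweep(preset$protocol, preset$atp_uM, preset$gating,
                         fl_bleach_free, preset$conductance)
  d0 <- decompose_sweep(sw_0, compensation = "exact_division")
  d_exact <- decompose_sweep(sw_b, compensation = "exact_division")
  d_fo <- decompose_sweep(sw_b, compensation = "first_order")

  expect_equal(d_exact$dF_steady_pct, d0$dF_steady_pct, tolerance = 1e-9)
  expect_equal(d_exact$dF_fast_pct, d0$dF_fast_pct, tolerance = 1e-9)
  ## first-order mode: residual bounded by (R * k_max)^2 = 1e-4 of F, i.e. 0.01%
  R_tot <- fl_clean$bleach_R_per_sample *
    (protocol_n_samples(preset$protocol) - 1)
  expect_lt(max(abs(d_fo$dF_steady_pct - d0$dF_steady_pct)),
            100 * R_tot^2)
})

test_that("additive and exact multiplicative compensation agree for small bleach", {
  ## gap-free trace, small signal, R * k_max = 1e-3
  k <- 0:999
  R <- 1e-3 / 999
  signal <- 1 + 1e-4 * sin(k / 50)  # 0.01% modulation
  f <- 1000 * (1 - R * k) * signal
  est <- estimate_bleach_rate(f, list(c(1, 100)))
  a <- compensate_additive(f, est)
  m <- compensate_multiplicative(f, est, "exact_division")
  expect_lt(max(abs(a - m) / m), 1e-6)
})

test_that("averaging commutes with baseline normalisation (noiseless)", {
  proto <- tiny_protocol()
  g <- const_tau_gating()
  co <- conductance_params()
  fl_a <- fluorophore_params(F0 = 900, s_ec_pct_per_mV = 0.01,
                             noise_sd_pct = 0)
  fl_b <- fluorophore_params(F0 = 900, s_ec_pct_per_mV = 0.01,
                             noise_sd_pct = 0)
  sweeps <- list(simulate_sweep(proto, 0, g, fl_a, co),
                 simulate_sweep(proto, 0, g, fl_b, co))
  avg <- average_repeats(sweeps)
  w <- c(1, 20)
  norm_after <- normalize_baseline(avg$F_channels[[1]], w)$F_norm
  norm_before <- (normalize_baseline(sweeps[[1]]$F_channels[[1]], w)$F_norm +
                  normalize_baseline(sweeps[[2]]$F_channels[[1]], w)$F_norm) / 2
  expect_equal(norm_after, norm_before, tolerance = 1e-12)
})
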