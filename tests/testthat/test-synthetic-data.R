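test_that("open probability hits the Boltzmann midpoint and closed-form values", {
  g <- const_tau_gating(Vhalf = -60, z = 1)
  expect_equal(open_probability(-60, 0, g), 0.5, tolerance = 1e-12)

  ## hand evaluation of the closed form, constants written out independently
  f <- f_per_mV_oracle(297.15)
  expect_equal(open_probability(-60 - 59, 0, g),
               1 / (1 + exp(-f * 59)), tolerance = 1e-12)
  expect_gt(open_probability(-119, 0, g), 0.90)  # ~0.909 at 59 mV past V1/2

  ## no agonist, agonist-dependent channel: occupancy zero, channel closed
  glig <- gating_params(atp_ec50_uM = 30)
  expect_equal(open_probability(-200, 0, glig), 0)

  expect_error(open_probability(NaN, 10, g), "finite")
  expect_error(open_probability(-60, -1, g), "finite")
})

test_that("open probability stays within [0, 1] across the parameter surface", {
  g <- gating_params(Vhalf_ref_mV = -100, z = 1.5, Pmin = 0.05, Pmax = 0.95)
  for (atp in c(0, 1, 30, 300, 3000)) {
    p <- open_probability(seq(-250, 250, by = 10), atp, g)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("gating relaxes mono-exponentially with the closed-form value", {
  f <- f_per_mV_oracle(297.15)
  ## choose voltages whose steady open probabilities are exactly 0.2 and 0.8
  vh <- -60
  v_p02 <- vh + log(4) / f
  v_p08 <- vh - log(4) / f
  g <- const_tau_gating(Vhalf = vh, z = 1, tau_ms = 50)
  proto <- vcf_protocol(hold_mV = v_p02, steps_mV = v_p08, pre_ms = 10,
                        step_ms = 200, tail_ms = 0, post_ms = 0,
                        rate_kHz = 20)
  po <- simulate_gating_trace(proto, 0, g)
  segs <- protocol_segments(proto)
  stp <- segs[segs$segment == "step", ]
  ## one relaxation time into the step: P = 0.8 - 0.6 * exp(-1)
  i_tau <- stp$start + as.integer(50 * proto$rate_kHz)
  expect_equal(po[i_tau], 0.8 - 0.6 * exp(-1), tolerance = 1e-9)
  ## baseline sits at the resting steady state
  expect_equal(po[1], 0.2, tolerance = 1e-12)
})

test_that("gating limits: instantaneous tau and constant protocols", {
  g_fast <- const_tau_gating(Vhalf = -60, z = 1, tau_ms = 1e-9)
  proto <- tiny_protocol(step_mV = -100, hold_mV = 0)
  po <- simulate_gating_trace(proto, 0, g_fast)
  segs <- protocol_segments(proto)
  for (i in seq_len(nrow(segs))) {
    idx <- segs$start[i] + seq_len(segs$n[i]) - 1L
    pinf <- open_probability(segs$v_mV[i], 0, g_fast)
    expect_equal(po[idx][-1L], rep(pinf, length(idx) - 1L), tolerance = 1e-9)
  }

  ## no voltage excursion: flat at the holding steady state
  proto_const <- vcf_protocol(hold_mV = -40, steps_mV = -40, pre_ms = 10,
                              step_ms = 50, tail_ms = 0, post_ms = 10,
                              rate_kHz = 2)
  g <- const_tau_gating(Vhalf = -60)
  po_const <- simulate_gating_trace(proto_const, 0, g)
  expect_equal(po_const, rep(open_probability(-40, 0, g), length(po_const)),
               tolerance = 1e-12)
})

test_that("sweep fluorescence follows the generative model exactly", {
  proto <- tiny_protocol()
  g <- const_tau_gating()
  co <- conductance_params(N_gamma_uS = 10, Erev_mV = 0)

  ## all couplings off: constant F0
  sw <- simulate_sweep(proto, 0, g, quiet_fluorophore(), co)
  expect_equal(sw$F_channels[[1]], rep(1000, length(sw$t_ms)))

  ## linear bleach alone: F at sample index k = F0 * (1 - R * k)
  proto_long <- vcf_protocol(hold_mV = 0, steps_mV = 0 + 1e-9, pre_ms = 0,
                             step_ms = 6000, tail_ms = 0, post_ms = 0,
                             rate_kHz = 20)
  fl <- fluorophore_params(F0 = 1000, s_ec_pct_per_mV = 0, c_slow_pct = 0,
                           bleach_R_per_sample = 1e-6, noise_sd_pct = 0)
  swb <- simulate_sweep(proto_long, 0, g, fl, co)
  expect_equal(swb$F_channels[[1]][100001], 1000 * 0.9, tolerance = 1e-12)

  ## bleach envelope reaching zero is rejected
  fl_bad <- fluorophore_params(F0 = 1000, bleach_R_per_sample = 1e-2,
                               noise_sd_pct = 0)
  expect_error(simulate_sweep(proto_long, 0, g, fl_bad, co), "envelope")

  ## current is zero when Po = 0 or V = Erev
  g_closed <- gating_params(atp_ec50_uM = 30)  # agonist-gated, 0 ATP
  sw0 <- simulate_sweep(proto, 0, g_closed, quiet_fluorophore(), co)
  expect_true(all(sw0$I_uA == 0))
})

test_that("identical seeds give bit-identical sweeps, distinct seeds differ", {
  proto <- tiny_protocol()
  g <- const_tau_gating()
  fl <- fluorophore_params(noise_sd_pct = 0.4, s_ec_pct_per_mV = 0)
  co <- conductance_params()
  a <- simulate_sweep(proto, 0, g, fl, co, seed = 42L)
  b <- simulate_sweep(proto, 0, g, fl, co, seed = 42L)
  c <- simulate_sweep(proto, 0, g, fl, co, seed = 43L)
  expect_identical(a$F_channels, b$F_channels)
  expect_false(identical(a$F_channels, c$F_channels))
})

test_that("repeat experiments derive distinct substreams deterministically", {
  proto <- tiny_protocol()
  g <- const_tau_gating()
  co <- conductance_params()

  ## noiseless: one repeat reproduces simulate_sweep; all repeats identical
  fl0 <- quiet_fluorophore()
  e1 <- simulate_experiment(proto, 0, g, fl0, co, n_repeats = 1, seed = 7L)
  sw <- simulate_sweep(proto, 0, g, fl0, co)
  expect_equal(e1[[1]]$F_channels, sw$F_channels)
  e20 <- simulate_experiment(proto, 0, g, fl0, co, n_repeats = 3, seed = 7L)
  expect_identical(e20[[1]]$F_channels, e20[[3]]$F_channels)

  ## noisy: repeats differ, full experiment reproducible from the seed
  fl <- fluorophore_params(noise_sd_pct = 0.4, s_ec_pct_per_mV = 0)
  ea <- simulate_experiment(proto, 0, g, fl, co, n_repeats = 3, seed = 7L)
  eb <- simulate_experiment(proto, 0, g, fl, co, n_repeats = 3, seed = 7L)
  expect_identical(lapply(ea, `[[`, "F_channels"),
                   lapply(eb, `[[`, "F_channels"))
  expect_false(identical(ea[[1]]$F_channels, ea[[2]]$F_channels))
})

test_that("20-repeat averaging reduces noise by sqrt(n)", {
  ## Monte-Carlo over replicate experiments; sd of the averaged trace should
  ## approach noise_sd / sqrt(20) = 0.0894 percent of F0
  proto <- vcf_protocol(hold_mV = 0, steps_mV = 1e-9, pre_ms = 0,
                        step_ms = 100, tail_ms = 0, post_ms = 0, rate_kHz = 2)
  g <- const_tau_gating()
  fl <- fluorophore_params(F0 = 1000, s_ec_pct_per_mV = 0, c_slow_pct = 0,
                           noise_sd_pct = 0.4)
  co <- conductance_params(N_gamma_uS = 0)
  devs <- unlist(lapply(1:100, function(r) {
    avg <- average_repeats(simulate_experiment(proto, 0, g, fl, co,
                                               n_repeats = 20, seed = r))
    100 * (avg$F_channels[[1]] - 1000) / 1000
  }))
  expect_equal(sd(devs), 0.4 / sqrt(20), tolerance = 0.03)
})

test_that("preset registry returns the published configurations", {
  expect_setequal(list_presets(),
                  c("P2X2_A337_EC_FIT", "P2X2_I341_EC_FIT",
                    "K308R_A337_300ATP", "K308R_A337_0ATP",
                    "K308R_A337_300ATP_FIG6", "CiVSP_F401"))
  expect_equal(get_preset("P2X2_A337_EC_FIT")$fluorophore$s_ec_pct_per_mV,
               0.011)
  expect_equal(get_preset("P2X2_I341_EC_FIT")$fluorophore$s_ec_pct_per_mV,
               0.007)
  expect_equal(get_preset("K308R_A337_300ATP")$fluorophore$s_ec_pct_per_mV,
               3.9 / 180, tolerance = 1e-12)
  p <- get_preset("K308R_A337_300ATP")
  ## slow gain is solved from the gating, not stored: reproduce it
  dpo <- open_probability(-160, 300, p$gating) -
    open_probability(20, 300, p$gating)
  expect_equal(p$fluorophore$c_slow_pct, 0.5 / dpo, tolerance = 1e-12)
  expect_equal(get_preset("CiVSP_F401")$channel, "F500")
  expect_equal(get_preset("K308R_A337_0ATP")$n_repeats, 5L)
  expect_error(get_preset("NO_SUCH_PRESET"), "unknown preset")
})

test_that("electrochromic-only presets give dF/F = s_ec * dV after the pipeline", {
  ## bleach-corrected, baseline-normalised fast deflection is linear in the
  ## voltage excursion, to within the first-order bleach residual
  rep1 <- run_noiseless("P2X2_A337_EC_FIT")
  d <- rep1$decomposition
  expect_equal(d$dF_fast_pct, 0.011 * d$dV_mV, tolerance = 1e-3)
  at_m140 <- d$dF_fast_pct[d$step_mV == -140]
  expect_equal(at_m140, 0.011 * -160, tolerance = 5e-3)
})

test_that("slow-only signal is a single exponential after bleach correction", {
  g <- const_tau_gating(Vhalf = -60, z = 1, tau_ms = 40)
  proto <- vcf_protocol(hold_mV = 0, steps_mV = -120, pre_ms = 50,
                        step_ms = 400, tail_ms = 0, post_ms = 50,
                        rate_kHz = 20)
  fl <- fluorophore_params(F0 = 1000, s_ec_pct_per_mV = 0, c_slow_pct = 5,
                           bleach_R_per_sample = 5e-7, noise_sd_pct = 0)
  sw <- simulate_sweep(proto, 0, g, fl, conductance_params())
  fit <- fit_slow_kinetics(sw, step_mV = -120, skip_ms = 0,
                           compensation = "exact_division")
  expect_true(fit$converged)
  expect_equal(fit$tau_ms, 40, tolerance = 1e-4)
})
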