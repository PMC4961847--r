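test_that("langmuir_theta matches its closed-form anchor points", {
  truth <- kinetic_truth(1e6, 1e-4)
  # zero at onset
  expect_equal(langmuir_theta(60, 1e-9, truth, t0 = 60), 0)
  expect_equal(langmuir_theta(10, 1e-9, truth, t0 = 60), 0)
  # equilibrium symmetry: C = kd_bi gives theta -> 1/2
  expect_equal(langmuir_theta(1e9, truth$kd_bi, truth, t0 = 0), 0.5,
               tolerance = 1e-12)
  # one time constant after onset: theta = theta_eq (1 - 1/e)
  C <- 1e-9
  k_obs <- truth$kon_bi * C + truth$koff_bi
  theta_eq <- truth$kon_bi * C / k_obs
  expect_equal(langmuir_theta(1 / k_obs, C, truth, t0 = 0),
               theta_eq * (1 - exp(-1)), tolerance = 1e-12)
  expect_error(langmuir_theta(10, 0, kinetic_truth(1e6, 0), t0 = 0),
               "degenerate")
})

test_that("closed form agrees with independent ODE integration to 1e-8", {
  times <- seq(0, 500, by = 5.5)
  for (kon in c(1e5, 1e6, 1e7)) {
    for (koff in c(1e-5, 1e-4, 1e-3)) {
      truth <- kinetic_truth(kon, koff)
      closed <- langmuir_theta(times, 1e-9, truth, t0 = 0)
      oracle <- ode_theta(times, 1e-9, kon, koff, t0 = 0)
      expect_lt(max(abs(closed - oracle)), 1e-8)
    }
  }
})

test_that("zero-noise simulation equals the closed form to 1e-12 relative", {
  layout <- small_layout()
  batch <- mnp_batch(1, layout)
  traces <- simulate_dataset(layout, batch, default_truth(), noiseless())
  binder <- dplyr::filter(traces, bait == "PD-L2", channel == 1,
                          sensor == 0)
  expected <- langmuir_theta(binder$time_s, batch$channel_M[2],
                             default_truth()[["PD-L2"]],
                             t0 = layout$onset_time)
  expect_equal(binder$signal, expected, tolerance = 1e-12)
  # controls and non-binders are exactly flat at zero noise
  ctrl <- dplyr::filter(traces, role == "negative_control")
  expect_true(all(ctrl$signal == 0))
})

test_that("no baseline step at sample introduction for non-binders", {
  layout <- small_layout()
  traces <- simulate_dataset(layout, mnp_batch(1, layout), default_truth(),
                             noise_model(0.02, 0, seed = 5))
  ctrl <- dplyr::filter(traces, role == "negative_control",
                        channel == 0, sensor == 2)
  pre <- ctrl$signal[ctrl$time_s < layout$onset_time]
  post <- ctrl$signal[ctrl$time_s >= layout$onset_time]
  # flat noise around zero on both sides of the onset
  expect_lt(abs(mean(post) - mean(pre)), 5 * 0.02 / sqrt(length(post)) * 2)
  expect_lt(abs(mean(ctrl$signal)), 0.02)
})

test_that("same seed gives bit-identical datasets; duplicates share nothing", {
  layout <- chip_layout()
  batch <- mnp_batch(1, layout)
  nm <- noise_model(0.02, 0.1, seed = 17)
  a <- simulate_dataset(layout, batch, default_truth(), nm)
  b <- simulate_dataset(layout, batch, default_truth(), nm)
  expect_identical(a$signal, b$signal)
  # different seed changes the noise
  c_ <- simulate_dataset(layout, batch, default_truth(),
                         noise_model(0.02, 0.1, seed = 18))
  expect_false(identical(a$signal, c_$signal))
  # duplicate sensors carry independent noise
  s1 <- dplyr::filter(a, channel == 0, sensor == 4)$signal
  s2 <- dplyr::filter(a, channel == 0, sensor == 5)$signal
  expect_false(identical(s1, s2))
})

test_that("binder traces rise faster at higher concentration", {
  layout <- chip_layout()
  traces <- simulate_dataset(layout, mnp_batch(1, layout), default_truth(),
                             noiseless())
  t_probe <- layout$onset_time + 40 * layout$sampling_interval
  sig_at <- function(ch) {
    d <- dplyr::filter(traces, bait == "PD-L2", channel == ch, sensor == 4)
    d$signal[which.min(abs(d$time_s - t_probe))]
  }
  sigs <- vapply(0:3, sig_at, numeric(1))
  expect_true(all(diff(sigs) < 0))  # channel 0 (100%) fastest
})

test_that("k_obs and theta_eq increase strictly with concentration", {
  truth <- kinetic_truth(1e6, 1e-4)
  C <- c(0.1, 0.25, 0.5, 1, 2) * 1e-9
  k_obs <- truth$kon_bi * C + truth$koff_bi
  theta_late <- vapply(C, function(cc)
    langmuir_theta(1e7, cc, truth, t0 = 0), numeric(1))
  expect_true(all(diff(k_obs) > 0))
  expect_true(all(diff(theta_late) > 0))
})

test_that("two-compartment simulation converges to the Langmuir limit", {
  layout <- small_layout(n_channels = 1L)
  batch <- mnp_batch(1, layout)
  truth <- default_truth()
  b_m <- 1e-9
  k_m_huge <- 1e9 * (truth[["PD-L2"]]$kon_bi * 1e-3) * b_m
  tc <- simulate_two_compartment(layout, batch, truth, b_m = b_m,
                                 k_M = k_m_huge, noise = noiseless())
  rl <- simulate_dataset(layout, batch, truth, noiseless())
  expect_lt(max(abs(tc$signal - rl$signal)), 1e-6)
  expect_true(all(tc$signal >= 0 & tc$signal <= 1))
  expect_error(simulate_two_compartment(layout, batch, truth, b_m = b_m,
                                        k_M = 0, noise = noiseless()),
               "transport error")
})

test_that("transport limitation lowers the fitted observed rate", {
  layout <- small_layout(n_channels = 1L)
  batch <- mnp_batch(1, layout)
  truth <- default_truth()
  kon_si <- truth[["PD-L2"]]$kon_bi * 1e-3
  k_m <- 1e-6
  b_m_da10 <- 10 * k_m / kon_si
  tc <- simulate_two_compartment(layout, batch, truth, b_m = b_m_da10,
                                 k_M = k_m, noise = noiseless())
  rl <- simulate_dataset(layout, batch, truth, noiseless())
  fit_tc <- tc |> subtract_reference() |> fit_binding_curves()
  fit_rl <- rl |> subtract_reference() |> fit_binding_curves()
  expect_lt(fit_tc$k_obs[1], fit_rl$k_obs[1])
})

test_that("calibration plate generator matches its stated design", {
  # zero noise: points exactly on the line
  plate <- simulate_calibration_plate(true_slope = 0.4,
                                      true_intercept = 0.07, noise_sd = 0)
  std <- dplyr::filter(plate, role == "standard")
  expect_equal(std$absorbance_425nm, 0.4 * std$concentration_nM + 0.07)
  # default standards in duplicate: 14 standard rows + unknown rows
  expect_equal(nrow(std), 14L)
  expect_equal(sum(plate$role == "unknown"), 2L)
  expect_true(all(is.na(plate$concentration_nM[plate$role == "unknown"])))
  expect_error(simulate_calibration_plate(noise_sd = -1), "noise_sd")
  expect_error(simulate_calibration_plate(standards = numeric(0)),
               "standards")
})
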