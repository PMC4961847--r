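test_that("noiseless traces are recovered to machine-level accuracy", {
  layout <- small_layout()
  batch <- mnp_batch(1, layout)
  truth <- default_truth()[["PD-L2"]]
  traces <- simulate_dataset(layout, batch, default_truth(), noiseless())
  fits <- traces |> subtract_reference() |> fit_binding_curves()
  for (ch in 0:3) {
    C <- batch$channel_M[ch + 1]
    k_true <- truth$kon_bi * C + truth$koff_bi
    a_true <- truth$kon_bi * C / k_true
    f <- dplyr::filter(fits, channel == ch, sensor == 0)
    expect_equal(f$k_obs, k_true, tolerance = 1e-7)
    expect_equal(f$amplitude_A, a_true, tolerance = 1e-7)
    expect_lt(f$rmse, 1e-10 * a_true)
    expect_true(f$converged)
    expect_equal(f$n_points, 80L)
  }
})

test_that("fitting is scale-equivariant and time-shift-covariant", {
  layout <- small_layout(1L)
  traces <- simulate_dataset(layout, mnp_batch(1, layout), default_truth(),
                             noise_model(0.01, 0, seed = 4))
  d <- traces |> subtract_reference() |>
    dplyr::filter(bait == "PD-L2", sensor == 0)
  base <- fit_binding_curve(d$time_s, d$signal, t0 = 60)
  scaled <- fit_binding_curve(d$time_s, 3.7 * d$signal, t0 = 60)
  expect_equal(scaled$amplitude_A, 3.7 * base$amplitude_A,
               tolerance = 1e-9)
  expect_equal(scaled$k_obs, base$k_obs, tolerance = 1e-9)
  shifted <- fit_binding_curve(d$time_s + 123, d$signal, t0 = 60 + 123)
  expect_equal(shifted$k_obs, base$k_obs, tolerance = 1e-9)
  expect_equal(shifted$amplitude_A, base$amplitude_A, tolerance = 1e-9)
})

test_that("reference subtraction cancels channel-common signal exactly", {
  layout <- small_layout()
  traces <- simulate_dataset(layout, mnp_batch(1, layout), default_truth(),
                             noise_model(0.02, 0.05, seed = 6))
  # arbitrary common-mode component: baseline step plus slow drift
  drift <- function(t) 0.3 * (t >= 60) + 0.002 * t
  drifted <- dplyr::mutate(traces, signal = signal + drift(time_s))
  attr(drifted, "onset_time") <- attr(traces, "onset_time")
  f0 <- traces |> subtract_reference() |> fit_binding_curves()
  f1 <- drifted |> subtract_reference() |> fit_binding_curves()
  # compare converged fits (non-identified ridge fits are flagged and
  # excluded from kinetics anyway)
  keep <- f0$converged & f1$converged
  expect_gt(sum(keep), 4L)
  # common-mode cancellation is exact in the data; the residual is the
  # fit's sensitivity to last-ulp arithmetic differences
  expect_equal(f1$k_obs[keep], f0$k_obs[keep], tolerance = 1e-6)
  expect_equal(f1$amplitude_A[keep], f0$amplitude_A[keep],
               tolerance = 1e-6)
})

test_that("probe minus flat reference recovers the pure binding curve", {
  layout <- small_layout(1L)
  traces <- simulate_dataset(layout, mnp_batch(1, layout), default_truth(),
                             noiseless())
  shifted <- dplyr::mutate(traces, signal = signal + 0.25)
  sub <- subtract_reference(shifted)
  probe <- dplyr::filter(sub, role == "probe", sensor == 0)
  clean <- dplyr::filter(traces, role == "probe", sensor == 0)
  expect_equal(probe$signal, clean$signal, tolerance = 1e-12)
  # reference sensors are retained and flagged
  expect_true(all(sub$consumed_as_reference[sub$role == "negative_control"]))
  # a channel without any reference-capable sensor errors
  orphan <- dplyr::filter(shifted, role == "probe")
  expect_error(subtract_reference(orphan), "no reference")
})

test_that("onset synchronization detects and removes an injected lag", {
  layout <- small_layout(2L)
  traces <- simulate_dataset(layout, mnp_batch(1, layout), default_truth(),
                             noise_model(0.005, 0, seed = 8))
  # already-aligned traces are unchanged
  sync0 <- synchronize_onset(traces, onset_time = 60)
  expect_equal(sync0$time_s, traces$time_s, tolerance = 1e-9)
  # shift channel 1 by two samples (+11 s)
  lagged <- dplyr::mutate(
    traces, time_s = time_s + ifelse(channel == 1, 11, 0))
  sync <- synchronize_onset(lagged, onset_time = 60)
  ch1 <- dplyr::filter(sync, channel == 1, sensor == 0)
  ch1_ref <- dplyr::filter(traces, channel == 1, sensor == 0)
  expect_lt(abs(ch1$time_s[1] - ch1_ref$time_s[1]),
            layout$sampling_interval + 1e-9)
  expect_error(synchronize_onset(traces, onset_time = 1e5), "windowing")
})

test_that("flat channels fall back to the configured onset with a warning", {
  layout <- small_layout(1L)
  traces <- simulate_dataset(layout, mnp_batch(1, layout),
                             truth_map = list(),  # nothing binds
                             noise_model(0.01, 0, seed = 9))
  expect_warning(sync <- synchronize_onset(traces, onset_time = 60),
                 "undetectable")
  expect_equal(sync$time_s, traces$time_s)
})

test_that("flat noise traces yield a rate indistinguishable from zero", {
  layout <- small_layout(1L)
  n_null <- 0
  n_seeds <- 60
  for (s in seq_len(n_seeds)) {
    traces <- simulate_dataset(layout, mnp_batch(1, layout),
                               truth_map = list(),
                               noise_model(0.02, 0, seed = 2000 + s))
    d <- dplyr::filter(traces, sensor == 0)
    f <- fit_binding_curve(d$time_s, d$signal, t0 = 60)
    ok <- !f$converged || !is.finite(f$se_kobs) ||
      abs(f$k_obs) < 2 * f$se_kobs ||
      f$amplitude_A < 3 * 0.02  # amplitude within the noise floor
    n_null <- n_null + ok
  }
  expect_gt(n_null / n_seeds, 0.9)
})

test_that("Jacobian-based k_obs SE matches the Monte-Carlo SD", {
  layout <- small_layout(1L)
  batch <- mnp_batch(1, layout)
  ks <- ses <- numeric(200)
  for (s in 1:200) {
    traces <- simulate_dataset(layout, batch, default_truth(),
                               noise_model(0.02, 0, seed = 5000 + s))
    d <- dplyr::filter(traces, sensor == 0) |>
      dplyr::mutate(signal = signal)
    f <- fit_binding_curve(d$time_s, d$signal, t0 = 60)
    ks[s] <- f$k_obs; ses[s] <- f$se_kobs
  }
  expect_lt(abs(sd(ks) / median(ses) - 1), 0.35)
})

test_that("window handling: truncation warns, short traces are excluded", {
  layout <- small_layout(1L)
  traces <- simulate_dataset(layout, mnp_batch(1, layout), default_truth(),
                             noiseless(),
                             duration = 60 + 80 * 5.5)
  d <- dplyr::filter(traces, bait == "PD-L2", sensor == 0)
  expect_warning(fit_binding_curve(d$time_s, d$signal, t0 = 60,
                                   window = 200), "truncated")
  short <- d[d$time_s < 95, ]  # fewer than 8 post-onset samples
  expect_error(fit_binding_curve(short$time_s, short$signal, t0 = 60),
               "fewer than 8")
  expect_error(fit_binding_curve(d$time_s, rep(NA_real_, nrow(d)), t0 = 60),
               "all-NaN")
})

test_that("duplicate aggregation reports mean, SD and singleton NA", {
  fits <- tibble::tibble(
    channel = c(0L, 0L, 1L), sensor = c(0L, 1L, 0L),
    bait = "X", amplitude_A = c(2, 4, 3), k_obs = c(2e-3, 4e-3, 1e-3),
    se_A = 0.1, se_kobs = 1e-4, t0 = 60, rmse = 0.01, n_points = 80L,
    converged = TRUE
  )
  class(fits) <- c("binding_fits", class(fits))
  agg <- aggregate_duplicates(fits)
  r0 <- dplyr::filter(agg, channel == 0)
  expect_equal(r0$k_obs_mean, 3e-3)
  expect_equal(r0$k_obs_sd, sqrt(2) * 1e-3)
  expect_equal(r0$amplitude_mean, 3)
  r1 <- dplyr::filter(agg, channel == 1)
  expect_true(is.na(r1$k_obs_sd))
  # identical duplicates give SD zero
  same <- dplyr::mutate(fits[c(1, 1), ], sensor = c(0L, 1L))
  expect_equal(aggregate_duplicates(same)$k_obs_sd, 0)
})

test_that("amplitude heterogeneity does not propagate into the rate", {
  layout <- small_layout(1L)
  batch <- mnp_batch(1, layout)
  rel_spread <- function(x) sd(x) / mean(x)
  k_spread <- a_spread <- numeric(50)
  for (s in 1:50) {
    traces <- simulate_dataset(layout, batch, default_truth(),
                               noise_model(0.002, 0.1, seed = 300 + s))
    f <- traces |> subtract_reference() |> fit_binding_curves()
    k_spread[s] <- rel_spread(f$k_obs)
    a_spread[s] <- rel_spread(f$amplitude_A)
  }
  expect_lt(median(k_spread), 0.5 * median(a_spread))
})

test_that("dissociation-phase fitting is explicitly unsupported", {
  expect_error(fit_dissociation_curve(), "unsupported")
})
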