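#' Ground-truth bivalent kinetics for simulation
#'
#' Bundle of the bivalent association rate `kon_bi` (M^-1 s^-1), bivalent
#' dissociation rate `koff_bi` (s^-1) and their ratio, the bivalent
#' dissociation constant `kd_bi = koff_bi / kon_bi` (M). These are the
#' avidity-level rates of a multivalent nanoparticle complex binding surface
#' bait, not single-site rates.
#'
#' Defaults (`kon_bi = 1e6 M^-1 s^-1`, `koff_bi = 1e-4 s^-1`) place the
#' observed rate `k_obs = kon_bi * C + koff_bi` between roughly 3.5e-4 and
#' 1.1e-3 s^-1 over a 0.25-1 nM dilution series, so the rate varies
#' severalfold across a 4-channel chip within an 80-sample window.
#'
#' @param kon_bi Bivalent association rate, M^-1 s^-1 (> 0).
#' @param koff_bi Bivalent dissociation rate, s^-1 (>= 0).
#' @return Object of class `kinetic_truth` with fields `kon_bi`, `koff_bi`,
#'   `kd_bi`.
#' @export
kinetic_truth <- function(kon_bi = 1e6, koff_bi = 1e-4) {
  if (!is.finite(kon_bi) || kon_bi <= 0) {
    stop("kinetics error: kon_bi must be positive", call. = FALSE)
  }
  if (!is.finite(koff_bi) || koff_bi < 0) {
    stop("kinetics error: koff_bi must be nonnegative", call. = FALSE)
  }
  structure(list(kon_bi = kon_bi, koff_bi = koff_bi,
                 kd_bi = koff_bi / kon_bi),
            class = "kinetic_truth")
}

#' Sensor noise model for simulated traces
#'
#' Additive, homoscedastic Gaussian noise per sample with SD `sigma_rel`
#' expressed as a fraction of the nominal saturation amplitude (1 signal
#' unit), plus multiplicative log-normal amplitude heterogeneity across
#' duplicate sensors with coefficient of variation `amp_cv` (mean amplitude
#' 1). Amplitude scatter between duplicates affects fitted amplitudes but
#' not observed rates, mirroring sensor-to-sensor coverage differences.
#'
#' @param sigma_rel Per-sample Gaussian SD as a fraction of saturation
#'   amplitude (>= 0). Default 0.02.
#' @param amp_cv Per-sensor amplitude CV across duplicates (>= 0).
#'   Default 0.05.
#' @param seed Master integer seed; per-sensor streams are derived from it.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(sigma_rel = 0.02, amp_cv = 0.05, seed = 1L) {
  if (!is.finite(sigma_rel) || sigma_rel < 0) {
    stop("noise error: sigma_rel must be nonnegative", call. = FALSE)
  }
  if (!is.finite(amp_cv) || amp_cv < 0) {
    stop("noise error: amp_cv must be nonnegative", call. = FALSE)
  }
  structure(list(sigma_rel = sigma_rel, amp_cv = amp_cv,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Nanoparticle batch: eluted concentration and channel dilution series
#'
#' The eluted complex concentration (from absorbance calibration) diluted
#' into the per-channel concentrations by the layout's dilution fractions
#' (default 100/75/50/25%).
#'
#' @param eluted_nM Eluted MNP-complex concentration, nM (>= 0).
#' @param layout A `chip_layout` supplying the dilution fractions.
#' @param prey Name of the flowed (prey) protein.
#' @return Object of class `mnp_batch` with `eluted_nM`, `channel_nM`
#'   (per-channel nM), `channel_M` (molar) and `prey`.
#' @export
mnp_batch <- function(eluted_nM, layout = chip_layout(), prey = "prey") {
  if (!is.finite(eluted_nM) || eluted_nM < 0) {
    stop("batch error: eluted concentration must be nonnegative",
         call. = FALSE)
  }
  validate_layout(layout)
  channel_nM <- eluted_nM * layout$dilution_fractions
  structure(list(prey = prey, eluted_nM = eluted_nM,
                 channel_nM = channel_nM, channel_M = channel_nM * 1e-9),
            class = "mnp_batch")
}

#' Langmuir-isotherm coverage under reaction-limited flow
#'
#' Closed-form fractional coverage of bait sites by nanoparticle complexes
#' when the bulk concentration `C` is held constant by continuous flow
#' (reaction-limited regime):
#' \deqn{\theta(t) = \theta_{eq} (1 - e^{-k_{obs} (t - t_0)}), \quad
#'       k_{obs} = k_{on}^{bi} C + k_{off}^{bi}, \quad
#'       \theta_{eq} = \frac{k_{on}^{bi} C}{k_{on}^{bi} C + k_{off}^{bi}}}
#' for `t >= t0` and 0 before onset. This is the solution of the Langmuir
#' rate equation \eqn{d\theta/dt = k_{on}^{bi} C (1-\theta) -
#' k_{off}^{bi}\theta} from \eqn{\theta(t_0) = 0}.
#'
#' @param t Time(s), seconds (vectorised).
#' @param C Complex concentration, molar (>= 0).
#' @param truth A `kinetic_truth`.
#' @param t0 Binding onset time, seconds.
#' @return Coverage in \[0, 1\], same length as `t`.
#' @export
langmuir_theta <- function(t, C, truth, t0 = 0) {
  stopifnot(inherits(truth, "kinetic_truth"))
  if (!is.finite(C) || C < 0) {
    stop("kinetics error: concentration must be nonnegative", call. = FALSE)
  }
  k_obs <- truth$kon_bi * C + truth$koff_bi
  if (k_obs == 0) {
    stop("degenerate-kinetics error: kon_bi*C + koff_bi = 0", call. = FALSE)
  }
  theta_eq <- truth$kon_bi * C / k_obs
  ifelse(t < t0, 0, theta_eq * (1 - exp(-k_obs * (t - t0))))
}

# deterministic per-sensor RNG substream: independent of how many sensors
# exist, so adding sensors never perturbs existing traces
sensor_seed <- function(master, channel, sensor) {
  as.integer((master + 1000003 * (channel + 1) + 10007 * (sensor + 1)) %%
               2147483629)
}

#' Simulate a multiplexed binding-trace dataset
#'
#' Generates one trace per (channel, sensor) on the layout's uniform time
#' grid. Probe sensors whose bait has an entry in `truth_map` follow the
#' reaction-limited Langmuir closed form at that channel's concentration,
#' scaled by a per-sensor log-normal amplitude (mean 1, CV `amp_cv`), with
#' additive Gaussian noise. Probe baits absent from `truth_map`
#' (non-binders) and control sensors are flat noise around zero — the
#' baseline does not shift at sample introduction, the platform's
#' characteristic pH/salinity insensitivity. Deterministic for a given seed;
#' random streams are partitioned per (channel, sensor).
#'
#' @param layout A `chip_layout`.
#' @param batch An `mnp_batch` giving per-channel concentrations.
#' @param truth_map Named list of `kinetic_truth`, keyed by bait name.
#'   Baits not listed are simulated as non-binders.
#' @param noise A `noise_model`.
#' @param duration Total recording length, seconds; must allow at least 80
#'   samples after onset. Default covers 90 post-onset samples.
#' @return A tidy trace tibble (`channel`, `sensor`, `bait`, `role`,
#'   `time_s`, `signal`) with attributes `onset_time` and
#'   `sampling_interval`.
#' @examples
#' layout <- chip_layout()
#' traces <- simulate_dataset(
#'   layout, mnp_batch(1.0, layout),
#'   truth_map = list("PD-L2" = kinetic_truth(1e6, 1e-4)),
#'   noise = noise_model(sigma_rel = 0.02, seed = 7)
#' )
#' dplyr::count(traces, channel, sensor) |> head()
#' @export
simulate_dataset <- function(layout, batch,
                             truth_map,
                             noise = noise_model(),
                             duration = NULL) {
  validate_layout(layout)
  stopifnot(inherits(batch, "mnp_batch"), inherits(noise, "noise_model"))
  if (is.null(duration)) {
    duration <- layout$onset_time + 90 * layout$sampling_interval
  }
  if (duration < layout$onset_time + 80 * layout$sampling_interval) {
    stop("simulation error: duration must allow >= 80 samples after onset",
         call. = FALSE)
  }
  lt <- layout_table(layout)
  unknown <- setdiff(names(truth_map), unique(lt$bait))
  if (length(unknown) > 0L) {
    stop("configuration error: truth_map baits absent from layout: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  times <- seq(0, duration, by = layout$sampling_interval)
  t0 <- layout$onset_time
  sdlog <- if (noise$amp_cv > 0) sqrt(log(1 + noise$amp_cv^2)) else 0

  sim_one <- function(channel, sensor, bait, role) {
    C <- batch$channel_M[channel + 1L]
    truth <- truth_map[[bait]]
    binder <- role == "probe" && !is.null(truth)
    clean <- if (binder) langmuir_theta(times, C, truth, t0) else
      rep(0, length(times))
    withr_seed <- sensor_seed(noise$seed, channel, sensor)
    old <- .Random.seed_get()
    set.seed(withr_seed)
    amp <- if (binder && sdlog > 0) {
      exp(stats::rnorm(1, -sdlog^2 / 2, sdlog))  # mean-1 log-normal
    } else 1
    eps <- if (noise$sigma_rel > 0) {
      stats::rnorm(length(times), 0, noise$sigma_rel)
    } else rep(0, length(times))
    .Random.seed_restore(old)
    tibble::tibble(channel = channel, sensor = sensor, bait = bait,
                   role = role, time_s = times, signal = amp * clean + eps)
  }

  out <- purrr::pmap(lt[c("channel", "sensor", "bait", "role")], sim_one) |>
    purrr::list_rbind()
  attr(out, "onset_time") <- t0
  attr(out, "sampling_interval") <- layout$sampling_interval
  out
}

# save/restore the global RNG state so simulation seeds are self-contained
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Simulate traces under a quasi-steady two-compartment transport model
#'
#' Oracle for the reaction-limited simplification. When analyte transport to
#' the sensor surface is finite, the near-surface concentration is depleted
#' by binding; eliminating it quasi-steadily from the two-compartment model
#' gives
#' \deqn{\frac{d\theta}{dt} = \frac{k_{on}^{bi} C (1-\theta) -
#'   k_{off}^{bi}\theta}{1 + Da_{loc} (1-\theta)}, \qquad
#'   Da_{loc} = \frac{k_{on}^{bi} b_m}{k_M}}
#' with `b_m` the bait surface-site density (mol/m^2) and `k_M` the
#' mass-transfer coefficient (m/s). As `k_M` grows, `Da_loc -> 0` and the
#' solution converges pointwise to the reaction-limited Langmuir curve.
#' Integrated with a stiff ODE solver; noise applied exactly as in
#' [simulate_dataset()], so the two simulators differ only in the
#' deterministic kinetics.
#'
#' @inheritParams simulate_dataset
#' @param b_m Bait surface-site density, mol/m^2.
#' @param k_M Mass-transfer coefficient, m/s (> 0). Obtain from
#'   [regime_report()].
#' @return A tidy trace tibble as [simulate_dataset()].
#' @export
simulate_two_compartment <- function(layout, batch, truth_map,
                                     b_m, k_M,
                                     noise = noise_model(),
                                     duration = NULL) {
  validate_layout(layout)
  stopifnot(inherits(batch, "mnp_batch"), inherits(noise, "noise_model"))
  if (!is.finite(k_M) || k_M <= 0) {
    stop("transport error: mass-transfer coefficient k_M must be positive",
         call. = FALSE)
  }
  if (!is.finite(b_m) || b_m < 0) {
    stop("transport error: surface-site density b_m must be nonnegative",
         call. = FALSE)
  }
  if (is.null(duration)) {
    duration <- layout$onset_time + 90 * layout$sampling_interval
  }
  lt <- layout_table(layout)
  unknown <- setdiff(names(truth_map), unique(lt$bait))
  if (length(unknown) > 0L) {
    stop("configuration error: truth_map baits absent from layout: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  times <- seq(0, duration, by = layout$sampling_interval)
  t0 <- layout$onset_time

  theta_2c <- function(C, truth) {
    # kon in M^-1 s^-1 == 1e-3 m^3 mol^-1 s^-1
    da_loc <- (truth$kon_bi * 1e-3) * b_m / k_M
    rhs <- function(t, y, parms) {
      th <- y[1]
      dth <- (truth$kon_bi * C * (1 - th) - truth$koff_bi * th) /
        (1 + da_loc * (1 - th))
      list(dth)
    }
    post <- times[times >= t0]
    ts <- if (isTRUE(all.equal(post[1], t0))) post else c(t0, post)
    sol <- deSolve::ode(y = c(theta = 0), times = ts, func = rhs,
                        parms = NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)
    th <- utils::tail(sol[, "theta"], length(post))
    out <- numeric(length(times))
    out[times >= t0] <- pmin(pmax(th, 0), 1)
    out
  }

  sdlog <- if (noise$amp_cv > 0) sqrt(log(1 + noise$amp_cv^2)) else 0
  sim_one <- function(channel, sensor, bait, role) {
    C <- batch$channel_M[channel + 1L]
    truth <- truth_map[[bait]]
    binder <- role == "probe" && !is.null(truth)
    clean <- if (binder) theta_2c(C, truth) else rep(0, length(times))
    old <- .Random.seed_get()
    set.seed(sensor_seed(noise$seed, channel, sensor))
    amp <- if (binder && sdlog > 0) {
      exp(stats::rnorm(1, -sdlog^2 / 2, sdlog))
    } else 1
    eps <- if (noise$sigma_rel > 0) {
      stats::rnorm(length(times), 0, noise$sigma_rel)
    } else rep(0, length(times))
    .Random.seed_restore(old)
    tibble::tibble(channel = channel, sensor = sensor, bait = bait,
                   role = role, time_s = times, signal = amp * clean + eps)
  }

  out <- purrr::pmap(lt[c("channel", "sensor", "bait", "role")], sim_one) |>
    purrr::list_rbind()
  attr(out, "onset_time") <- t0
  attr(out, "sampling_interval") <- layout$sampling_interval
  out
}

#' Simulate an absorbance calibration plate
#'
#' Emulates the 425-nm microplate measurement used to quantify eluted
#' nanoparticle complexes: standards at known concentrations (default the
#' 1 nM stock and its dilutions to 0.9, 0.8, 0.6, 0.4, 0.2 and 0.1 nM), in
#' replicate wells, plus unknown-eluate wells, with absorbance
#' `slope * c + intercept + N(0, noise_sd)`.
#'
#' @param true_slope Absorbance per nM.
#' @param true_intercept Blank absorbance.
#' @param standards Standard concentrations, nM (nonempty, nonnegative).
#' @param replicates Wells per standard (default 2, duplicates).
#' @param unknown_nM True concentration of the unknown eluate, nM.
#' @param unknown_replicates Wells for the unknown (default 2).
#' @param noise_sd Absorbance noise SD (>= 0).
#' @param seed Integer seed.
#' @return A tibble with columns `well`, `role` (`"standard"`/`"unknown"`),
#'   `concentration_nM` (NA for unknown wells), `absorbance_425nm`.
#' @export
simulate_calibration_plate <- function(true_slope = 0.5,
                                       true_intercept = 0.05,
                                       standards = c(1.0, 0.9, 0.8, 0.6,
                                                     0.4, 0.2, 0.1),
                                       replicates = 2L,
                                       unknown_nM = 0.55,
                                       unknown_replicates = 2L,
                                       noise_sd = 0,
                                       seed = 1L) {
  if (length(standards) == 0L || any(!is.finite(standards)) ||
      any(standards < 0)) {
    stop("parameter error: standards must be nonempty and nonnegative",
         call. = FALSE)
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("parameter error: noise_sd must be nonnegative", call. = FALSE)
  }
  conc <- c(rep(standards, each = replicates),
            rep(unknown_nM, unknown_replicates))
  role <- c(rep("standard", length(standards) * replicates),
            rep("unknown", unknown_replicates))
  old <- .Random.seed_get()
  set.seed(as.integer(seed))
  eps <- if (noise_sd > 0) stats::rnorm(length(conc), 0, noise_sd) else
    rep(0, length(conc))
  .Random.seed_restore(old)
  tibble::tibble(
    well = sprintf("W%02d", seq_along(conc)),
    role = role,
    concentration_nM = ifelse(role == "standard", conc, NA_real_),
    absorbance_425nm = true_slope * conc + true_intercept + eps
  )
}

#' Write / read a calibration plate as CSV
#' @param plate Calibration tibble from [simulate_calibration_plate()].
#' @param path CSV path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   the plate tibble.
#' @export
write_calibration <- function(plate, path) {
  readr::write_csv(plate, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) {
    stop("calibration file not found: ", path, call. = FALSE)
  }
  pl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("role", "concentration_nM", "absorbance_425nm")
  missing_cols <- setdiff(needed, names(pl))
  if (length(missing_cols) > 0L) {
    stop("calibration format error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pl
}
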