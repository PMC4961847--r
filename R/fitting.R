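#' Subtract channel-local reference signals
#'
#' Removes channel-common, non-binding signal (electronic drift, bulk
#' effects) from every probe trace by subtracting, at each time point, the
#' mean signal of that channel's reference sensors. If a channel declares
#' dedicated `"reference"` sensors those are used; otherwise the
#' negative-control sensors (e.g. BSA, non-cognate IgG), whose signals stay
#' low and constant, serve as the reference. Any signal common to all
#' sensors in a channel cancels exactly, so fitted rates are invariant to
#' baseline steps or drift.
#'
#' @param traces A trace tibble with a `role` column (use [attach_roles()]
#'   or pass `layout`).
#' @param layout Optional `chip_layout`, used to attach roles if absent.
#' @return The traces with probe signals reference-subtracted; sensors used
#'   as reference keep their original signal and are flagged
#'   `consumed_as_reference`.
#' @export
subtract_reference <- function(traces, layout = NULL) {
  if (!("role" %in% names(traces))) {
    if (is.null(layout)) {
      stop("configuration error: traces carry no roles and no layout given",
           call. = FALSE)
    }
    traces <- attach_roles(traces, layout)
  }
  ref_role_for <- function(roles) {
    if (any(roles == "reference")) "reference" else "negative_control"
  }
  per_channel <- function(d, key) {
    rr <- ref_role_for(d$role)
    refs <- d |> dplyr::filter(.data$role == rr)
    if (nrow(refs) == 0L) {
      stop("configuration error: channel ", key$channel,
           " has no reference or negative-control sensor", call. = FALSE)
    }
    ref_mean <- refs |>
      dplyr::summarise(ref = mean(.data$signal), .by = "time_s")
    d |>
      dplyr::left_join(ref_mean, by = "time_s") |>
      dplyr::mutate(
        signal = ifelse(.data$role == "probe",
                        .data$signal - .data$ref, .data$signal),
        consumed_as_reference = .data$role == rr
      ) |>
      dplyr::select(-"ref") |>
      dplyr::mutate(channel = key$channel)
  }
  out <- traces |>
    dplyr::group_by(.data$channel) |>
    dplyr::group_map(per_channel) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$channel, .data$sensor, .data$time_s)
  for (a in c("onset_time", "sampling_interval")) {
    attr(out, a) <- attr(traces, a)
  }
  out
}

#' Synchronize binding onsets across channels
#'
#' Sample introduction can reach different channels at slightly different
#' times; traces are post-synchronized so every channel's binding onset sits
#' at the same nominal time (default 60 s, i.e. 1 min). Detection is a
#' two-step deterministic rule on the channel-mean probe signal: (1) find
#' the first sample exceeding the baseline mean plus 5 baseline SDs
#' (baseline = the first `baseline_samples` samples); (2) back-extrapolate a
#' straight line fitted through the following `rise_samples` samples to its
#' intersection with the baseline mean — the raw crossing lags the true
#' departure point by threshold/initial-slope, which would misalign
#' channels at different concentrations, so the tangent intersection is
#' used as the (nearly unbiased) onset estimate. The channel's time axis is
#' shifted, in whole sampling intervals, so that estimate lands at
#' `onset_time`. If no crossing is found (flat channel) the configured
#' onset is kept with a warning.
#'
#' @param traces A trace tibble with roles.
#' @param onset_time Target onset time, seconds; defaults to the traces'
#'   `onset_time` attribute, else 60.
#' @param baseline_samples Samples used for the baseline statistics
#'   (default 8).
#' @param rise_samples Samples of the rising phase used for the tangent
#'   back-extrapolation (default 15).
#' @return The traces with shifted `time_s` and attribute `onset_time`.
#' @export
synchronize_onset <- function(traces, onset_time = NULL,
                              baseline_samples = 8L, rise_samples = 15L) {
  if (is.null(onset_time)) {
    onset_time <- attr(traces, "onset_time") %||% 60
  }
  if (!("role" %in% names(traces))) {
    stop("configuration error: traces carry no roles", call. = FALSE)
  }
  span <- range(traces$time_s)
  if (onset_time < span[1] || onset_time > span[2]) {
    stop("windowing error: onset ", onset_time,
         " s outside recorded span [", span[1], ", ", span[2], "] s",
         call. = FALSE)
  }
  per_channel <- function(d, key) {
    mean_probe <- d |>
      dplyr::filter(.data$role == "probe") |>
      dplyr::summarise(signal = mean(.data$signal), .by = "time_s") |>
      dplyr::arrange(.data$time_s)
    shift <- 0
    if (nrow(mean_probe) > baseline_samples) {
      base <- mean_probe$signal[seq_len(baseline_samples)]
      thr <- mean(base) + 5 * stats::sd(base)
      idx <- which(mean_probe$signal > thr)
      idx <- idx[idx > baseline_samples]
      if (length(idx) > 0L) {
        i <- idx[1]
        ri <- i:min(i + rise_samples - 1L, nrow(mean_probe))
        cf <- stats::coef(stats::lm(signal ~ time_s, data = mean_probe[ri, ]))
        detected <- if (length(ri) >= 3L && is.finite(cf[2]) && cf[2] > 0) {
          # tangent intersection with the baseline level
          (mean(base) - cf[1]) / cf[2]
        } else {
          mean_probe$time_s[i]
        }
        shift <- onset_time - detected
        # snap to the sampling grid so spacing invariants survive
        dt <- stats::median(diff(mean_probe$time_s))
        shift <- round(shift / dt) * dt
      } else {
        warning("channel ", key$channel, ": onset undetectable (flat ",
                "signals); keeping configured onset ", onset_time, " s",
                call. = FALSE)
      }
    }
    d |> dplyr::mutate(channel = key$channel,
                       time_s = .data$time_s + shift)
  }
  out <- traces |>
    dplyr::group_by(.data$channel) |>
    dplyr::group_map(per_channel) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$channel, .data$sensor, .data$time_s)
  attr(out, "onset_time") <- onset_time
  attr(out, "sampling_interval") <- attr(traces, "sampling_interval")
  out
}

#' Fit the exponential association model to one binding trace
#'
#' Nonlinear least-squares fit of
#' \deqn{S(t) = A (1 - e^{-k_{obs} (t - t_0)})}
#' over the first `window` samples at or after the (fixed) onset `t0`. Only
#' the amplitude `A` and the observed rate `k_obs` are free; `t0` comes from
#' onset synchronization, matching a two-parameter fit. Levenberg-Marquardt
#' with an analytic Jacobian, deterministic initial values (`A0` = max
#' windowed signal; `k0` = ln 2 / time-to-half-amplitude) and bounds
#' `A >= 0`, `k_obs >= 0`. Standard errors come from the Jacobian at the
#' optimum. Non-convergence is reported via `converged = FALSE`, not an
#' error.
#'
#' @param time_s,signal Numeric vectors for one (reference-subtracted)
#'   trace.
#' @param t0 Fixed onset time, seconds.
#' @param window Number of post-onset samples to fit (default 80); longer
#'   requests than available truncate with a warning.
#' @return A one-row tibble: `amplitude_A`, `k_obs`, `se_A`, `se_kobs`,
#'   `t0`, `rmse`, `n_points`, `converged`.
#' @export
fit_binding_curve <- function(time_s, signal, t0, window = 80L) {
  keep <- is.finite(signal) & is.finite(time_s)
  if (!any(keep)) stop("fit data error: all-NaN trace", call. = FALSE)
  time_s <- time_s[keep]; signal <- signal[keep]
  post <- which(time_s >= t0)
  if (length(post) < 8L) {
    stop("fit data error: fewer than 8 points after onset", call. = FALSE)
  }
  if (length(post) < window) {
    warning("window of ", window, " points truncated to ", length(post),
            " available post-onset points", call. = FALSE)
  }
  idx <- post[seq_len(min(window, length(post)))]
  tt <- time_s[idx] - t0
  y_raw <- signal[idx]
  n <- length(y_raw)
  # normalise to unit scale: makes the optimisation scale-equivariant to
  # floating precision and conditions the Jacobian
  y_scale <- max(abs(y_raw))
  if (y_scale == 0) {
    return(tibble::tibble(amplitude_A = 0, k_obs = 0, se_A = 0,
                          se_kobs = 0, t0 = t0, rmse = 0, n_points = n,
                          converged = TRUE))
  }
  yy <- y_raw / y_scale

  a0 <- max(max(yy), 1e-9)
  half_idx <- which(yy >= a0 / 2)[1]
  dt <- if (n >= 2) stats::median(diff(tt)) else 1
  t_half <- max(tt[half_idx], dt)
  k0 <- log(2) / t_half
  # refine the start by profiling: A is linear given k_obs, so scan a
  # deterministic log-spaced k grid and keep the profiled minimum; this
  # avoids stalling on the A/k_obs ridge of weakly saturating traces
  k_grid <- exp(seq(log(1e-4 / max(tt)), log(20 / dt), length.out = 80))
  prof_rss <- vapply(k_grid, function(k) {
    g <- 1 - exp(-k * tt)
    a <- sum(yy * g) / sum(g * g)
    sum((yy - a * g)^2)
  }, numeric(1))
  k_prof <- k_grid[which.min(prof_rss)]
  g0 <- 1 - exp(-k_prof * tt)
  a_prof <- sum(yy * g0) / sum(g0 * g0)
  if (is.finite(a_prof) && a_prof > 0) {
    a0 <- a_prof
    k0 <- k_prof
  }

  model <- function(p, t) p[1] * (1 - exp(-p[2] * t))
  resid_fn <- function(p) yy - model(p, tt)
  jac_fn <- function(p) {
    e <- exp(-p[2] * tt)
    cbind(-(1 - e), -p[1] * tt * e)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(A = a0, k_obs = k0), fn = resid_fn, jac = jac_fn,
      lower = c(0, 0), upper = c(Inf, Inf),
      control = minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14,
                                           maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(tibble::tibble(amplitude_A = NA_real_, k_obs = NA_real_,
                          se_A = NA_real_, se_kobs = NA_real_, t0 = t0,
                          rmse = NA_real_, n_points = n, converged = FALSE))
  }
  p <- stats::coef(fit)
  r <- resid_fn(p)
  rss <- sum(r^2)
  sigma2 <- rss / max(n - 2L, 1L)
  J <- jac_fn(p)
  covm <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  ses <- if (is.null(covm)) c(NA_real_, NA_real_) else {
    d <- diag(covm); d[d < 0] <- NA_real_; sqrt(d)
  }
  converged <- fit$info %in% 1:4
  tibble::tibble(
    amplitude_A = y_scale * unname(p[1]), k_obs = unname(p[2]),
    se_A = y_scale * ses[1], se_kobs = ses[2], t0 = t0,
    rmse = y_scale * sqrt(rss / n), n_points = n, converged = converged
  )
}

#' Fit binding curves for every probe trace
#'
#' Applies [fit_binding_curve()] to each (channel, sensor) trace whose role
#' matches `roles`, after reference subtraction. Traces with fewer than 8
#' post-onset samples are skipped with a warning naming the sensor.
#'
#' @param traces A reference-subtracted trace tibble with roles.
#' @param t0 Fixed onset, seconds; defaults to the traces' `onset_time`
#'   attribute.
#' @param window Post-onset samples per fit (default 80).
#' @param roles Roles to fit (default `"probe"`).
#' @return A tibble of class `binding_fits`, one row per fitted sensor:
#'   `channel`, `sensor`, `bait`, the [fit_binding_curve()] columns.
#' @examples
#' layout <- chip_layout()
#' traces <- simulate_dataset(layout, mnp_batch(1, layout),
#'                            list("PD-L2" = kinetic_truth()),
#'                            noise_model(sigma_rel = 0, amp_cv = 0))
#' fits <- traces |> subtract_reference() |> fit_binding_curves()
#' dplyr::filter(fits, bait == "PD-L2")
#' @export
fit_binding_curves <- function(traces, t0 = NULL, window = 80L,
                               roles = "probe") {
  if (is.null(t0)) t0 <- attr(traces, "onset_time") %||% 60
  if (!("role" %in% names(traces))) {
    stop("configuration error: traces carry no roles", call. = FALSE)
  }
  fit_one <- function(d, key) {
    n_post <- sum(d$time_s >= t0)
    if (n_post < 8L) {
      warning("channel ", key$channel, " sensor ", key$sensor,
              ": only ", n_post, " post-onset points; excluded",
              call. = FALSE)
      return(NULL)
    }
    fit_binding_curve(d$time_s, d$signal, t0 = t0, window = window) |>
      dplyr::mutate(channel = key$channel, sensor = key$sensor,
                    bait = d$bait[1], .before = 1)
  }
  out <- traces |>
    dplyr::filter(.data$role %in% roles) |>
    dplyr::group_by(.data$channel, .data$sensor) |>
    dplyr::group_map(fit_one) |>
    purrr::list_rbind()
  class(out) <- c("binding_fits", class(out))
  out
}

#' Aggregate duplicate-sensor fits
#'
#' Collapses per-sensor fits to one row per (bait, channel): mean and SD of
#' the observed rate and amplitude across duplicate sensors. A singleton
#' "duplicate" reports SD as missing (NA), never 0. Only converged fits
#' enter the aggregate.
#'
#' @param fits A `binding_fits` tibble.
#' @return A tibble: `bait`, `channel`, `n_sensors`, `k_obs_mean`,
#'   `k_obs_sd`, `amplitude_mean`, `amplitude_sd`.
#' @export
aggregate_duplicates <- function(fits) {
  fits |>
    dplyr::filter(.data$converged) |>
    dplyr::summarise(
      n_sensors = dplyr::n(),
      k_obs_mean = mean(.data$k_obs),
      k_obs_sd = if (dplyr::n() > 1L) stats::sd(.data$k_obs) else NA_real_,
      amplitude_mean = mean(.data$amplitude_A),
      amplitude_sd = if (dplyr::n() > 1L) stats::sd(.data$amplitude_A) else
        NA_real_,
      .by = c("bait", "channel")
    ) |>
    dplyr::arrange(.data$bait, .data$channel)
}

#' Dissociation-phase fitting is not supported
#'
#' Bivalent (avidity) binding makes the off-rate so slow that no
#' significant signal drop is observable in a practical washout window, so
#' the off-rate is obtained from the intercept of the k_obs-vs-concentration
#' regression instead (see [pool_kobs()]). This stub documents that choice.
#'
#' @param ... Ignored.
#' @export
fit_dissociation_curve <- function(...) {
  stop("unsupported: dissociation-phase fitting; the bivalent off-rate is ",
       "estimated from the intercept of the k_obs-vs-concentration ",
       "regression (see pool_kobs)", call. = FALSE)
}

#' Write / read per-sensor fits as TSV
#' @param fits A `binding_fits` tibble.
#' @param path TSV path.
#' @return `write_fits` returns `path` invisibly; `read_fits` the fits
#'   tibble.
#' @export
write_fits <- function(fits, path) {
  readr::write_tsv(fits, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_fits
#' @export
read_fits <- function(path) {
  if (!file.exists(path)) stop("fits file not found: ", path, call. = FALSE)
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  class(out) <- c("binding_fits", class(out))
  out
}

#' Plot binding traces by channel
#'
#' @param traces A trace tibble.
#' @param baits Optional bait subset.
#' @return A ggplot: signal vs time, coloured by bait, faceted by channel.
#' @export
plot_traces <- function(traces, baits = NULL) {
  d <- traces
  if (!is.null(baits)) d <- dplyr::filter(d, .data$bait %in% baits)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$signal,
                                  colour = .data$bait,
                                  group = interaction(.data$bait,
                                                      .data$sensor))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~channel, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Time (s)", y = "Signal (a.u.)", colour = "Bait") +
    ggplot2::theme_minimal()
}
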