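#' Decouple bivalent rates by regressing k_obs on concentration
#'
#' Under pseudo-first-order Langmuir kinetics the observed rate is linear in
#' the complex concentration, `k_obs = kon_bi * C + koff_bi`, so a single
#' association-phase experiment at several concentrations decouples the two
#' rates without a washout measurement: the slope of the ordinary
#' least-squares line of pooled (C, k_obs) points is `kon_bi`, the
#' y-intercept is `koff_bi`, and `kd_bi = koff_bi / kon_bi`. Points from
#' multiple experiments are pooled into one regression. The regression is
#' unweighted by default (`weights = "none"`); duplicate-SD inverse-variance
#' weighting is available with `weights = "sd"`.
#'
#' A negative fitted intercept (off-rate below the noise floor) is reported
#' as-is with a warning, never clamped; `kd_bi` then carries the same
#' warning. The `kd_bi` standard error is first-order (delta-method) using
#' the full slope/intercept covariance.
#'
#' @param kobs_table Tibble with one row per (bait, channel \[, experiment\])
#'   point: columns `bait`, `concentration_nM`, `k_obs`, optionally
#'   `k_obs_sd` and `experiment`. Use [aggregate_duplicates()] joined to an
#'   [mnp_batch()], or [kobs_points()].
#' @param bait Bait to analyse (required when several are present).
#' @param prey Prey name carried to reporting.
#' @param weights `"none"` (default) or `"sd"` (weights 1/k_obs_sd^2).
#' @return Object of class `bivalent_kinetics`: `kon_bi` (M^-1 s^-1),
#'   `koff_bi` (s^-1), `kd_bi` (M), each with SE; `r_squared`, `n_points`,
#'   the point table, and the underlying `lm`. Methods:
#'   [tidy.bivalent_kinetics()], [glance.bivalent_kinetics()],
#'   [autoplot.bivalent_kinetics()].
#' @export
pool_kobs <- function(kobs_table, bait = NULL, prey = "prey",
                      weights = c("none", "sd")) {
  weights <- match.arg(weights)
  d <- kobs_table
  if (!is.null(bait)) d <- dplyr::filter(d, .data$bait == !!bait)
  if (is.null(bait)) {
    ub <- unique(d$bait)
    if (length(ub) > 1L) {
      stop("kinetics error: several baits present (",
           paste(ub, collapse = ", "), "); pass `bait`", call. = FALSE)
    }
    bait <- ub
  }
  d <- d |> dplyr::filter(is.finite(.data$k_obs),
                          is.finite(.data$concentration_nM))
  if (nrow(d) < 2L) {
    stop("insufficient-data error: fewer than 2 usable k_obs points",
         call. = FALSE)
  }
  if (length(unique(d$concentration_nM)) < 2L) {
    stop("rank-deficiency error: single concentration; cannot decouple ",
         "kon from koff", call. = FALSE)
  }
  d <- d |> dplyr::mutate(concentration_M = .data$concentration_nM * 1e-9)
  w <- if (weights == "sd") {
    if (!("k_obs_sd" %in% names(d)) || any(!is.finite(d$k_obs_sd)) ||
        any(d$k_obs_sd <= 0)) {
      stop("kinetics error: weights = \"sd\" needs finite positive ",
           "k_obs_sd for every point", call. = FALSE)
    }
    1 / d$k_obs_sd^2
  } else NULL
  fit <- stats::lm(k_obs ~ concentration_M, data = d, weights = w)
  cf <- stats::coef(fit)
  kon <- unname(cf[2]); koff <- unname(cf[1])
  vc <- suppressWarnings(stats::vcov(fit))  # exact lines: perfect fit
  se <- sqrt(diag(vc))
  se_kon <- unname(se[2]); se_koff <- unname(se[1])
  two_points <- nrow(d) == 2L
  if (two_points) se_kon <- se_koff <- NA_real_
  kd <- koff / kon
  # delta method: var(kd) = (d kd/d koff)^2 v11 + (d kd/d kon)^2 v22 + cross
  se_kd <- if (two_points) NA_real_ else {
    g <- c(1 / kon, -koff / kon^2)  # (d/d intercept, d/d slope)
    sqrt(drop(t(g) %*% vc %*% g))
  }
  warn <- NULL
  if (koff < 0) {
    warn <- "negative fitted intercept: koff_bi below noise floor"
    warning(warn, "; reported unclamped", call. = FALSE)
  }
  structure(
    list(prey = prey, bait = bait,
         kon_bi = kon, se_kon = se_kon,
         koff_bi = koff, se_koff = se_koff,
         kd_bi = kd, se_kd = se_kd,
         r_squared = suppressWarnings(summary(fit))$r.squared,
         n_points = nrow(d),
         points = d, fit = fit, warning = warn),
    class = "bivalent_kinetics"
  )
}

#' Build the (concentration, k_obs) point table for [pool_kobs()]
#'
#' Joins aggregated duplicate fits to a batch's per-channel concentrations,
#' tagging each point with an experiment id so repeated runs pool into one
#' regression.
#'
#' @param agg Output of [aggregate_duplicates()].
#' @param batch The `mnp_batch` flowed in that experiment.
#' @param experiment Experiment identifier (default 1).
#' @return Tibble: `bait`, `channel`, `experiment`, `concentration_nM`,
#'   `k_obs`, `k_obs_sd`.
#' @export
kobs_points <- function(agg, batch, experiment = 1L) {
  stopifnot(inherits(batch, "mnp_batch"))
  agg |>
    dplyr::mutate(
      experiment = experiment,
      concentration_nM = batch$channel_nM[.data$channel + 1L],
      k_obs = .data$k_obs_mean,
      k_obs_sd = .data$k_obs_sd
    ) |>
    dplyr::select("bait", "channel", "experiment", "concentration_nM",
                  "k_obs", "k_obs_sd")
}

#' Convert a bivalent to a monovalent dissociation constant
#'
#' A nanoparticle complex engages surface bait through `valency` sites; the
#' avidity-enhanced (bivalent) dissociation constant relates to the
#' single-site one through an effective local concentration `c_eff` — the
#' concentration a tethered second site experiences once the first is
#' bound. The geometric-mean avidity model used here is
#' \deqn{K_D^{mono} = \left(K_D^{bi}\, c_{eff}^{\,v-1}\right)^{1/v}}
#' which reduces to the identity at `valency = 1` and to
#' \eqn{\sqrt{K_D^{bi} c_{eff}}} for the default bivalent case. `c_eff` has
#' no default: monovalent affinities scale with it, so it must be an
#' explicit, recorded choice.
#'
#' @param kin A `bivalent_kinetics` object, or a bivalent K_D in molar.
#' @param c_eff Effective local concentration, molar (> 0).
#' @param valency Number of simultaneously engaged sites (default 2).
#' @return A one-row tibble: `prey`, `bait`, `kd_bi_M`, `kd_mono_M`,
#'   `kd_mono_uM`, `se_kd_mono_M` (delta method, when available), `valency`,
#'   `c_eff_M`.
#' @export
kd_monovalent <- function(kin, c_eff, valency = 2L) {
  if (inherits(kin, "bivalent_kinetics")) {
    kd_bi <- kin$kd_bi; se_kd <- kin$se_kd
    prey <- kin$prey; bait <- kin$bait
  } else {
    kd_bi <- as.numeric(kin); se_kd <- NA_real_
    prey <- NA_character_; bait <- NA_character_
  }
  if (!is.finite(kd_bi) || kd_bi <= 0) {
    stop("domain error: kd_bi must be positive for avidity conversion",
         call. = FALSE)
  }
  if (!is.finite(c_eff) || c_eff <= 0) {
    stop("domain error: c_eff must be positive", call. = FALSE)
  }
  if (valency < 1L) stop("domain error: valency must be >= 1", call. = FALSE)
  kd_mono <- (kd_bi * c_eff^(valency - 1))^(1 / valency)
  # delta method through the power law
  se_mono <- if (is.finite(se_kd)) {
    (kd_mono / (valency * kd_bi)) * se_kd
  } else NA_real_
  tibble::tibble(prey = prey, bait = bait, kd_bi_M = kd_bi,
                 kd_mono_M = kd_mono, kd_mono_uM = kd_mono * 1e6,
                 se_kd_mono_M = se_mono, valency = as.integer(valency),
                 c_eff_M = c_eff)
}

#' Invert the avidity conversion
#'
#' @param kd_mono Monovalent K_D, molar.
#' @inheritParams kd_monovalent
#' @return The bivalent K_D in molar.
#' @export
kd_bivalent_from_mono <- function(kd_mono, c_eff, valency = 2L) {
  if (!is.finite(kd_mono) || kd_mono <= 0 || !is.finite(c_eff) ||
      c_eff <= 0 || valency < 1L) {
    stop("domain error: kd_mono and c_eff must be positive, valency >= 1",
         call. = FALSE)
  }
  kd_mono^valency / c_eff^(valency - 1)
}

#' Sensitivity of the monovalent K_D to the assumed valency
#'
#' Evaluates the avidity conversion at valencies 1-3 and reports the
#' max/min spread ratio: assuming monovalent or trivalent instead of
#' bivalent binding shifts the inferred single-site affinity substantially
#' whenever `kd_bi << c_eff`, which is why the binding mode must be
#' established before affinities are quoted.
#'
#' @inheritParams kd_monovalent
#' @param valencies Valencies to evaluate (default 1:3).
#' @return A tibble (one row per valency) with attribute `spread_ratio`
#'   (max/min kd_mono), also in column `spread_ratio`.
#' @export
valency_sensitivity <- function(kin, c_eff, valencies = 1:3) {
  rows <- purrr::map(valencies,
                     ~ kd_monovalent(kin, c_eff = c_eff, valency = .x)) |>
    purrr::list_rbind()
  spread <- max(rows$kd_mono_M) / min(rows$kd_mono_M)
  rows$spread_ratio <- spread
  attr(rows, "spread_ratio") <- spread
  rows
}

#' Format an interaction table
#'
#' Renders a list of analysed interactions in the conventional orientation
#' (prey flowed / bait immobilized) with monovalent K_D in micromolar;
#' missing values are rendered `"N/A"`.
#'
#' @param kin_list List of `bivalent_kinetics` objects.
#' @param c_eff Effective concentration, molar, for the avidity conversion.
#' @param valency Assumed valency (default 2).
#' @return A tibble: `prey`, `bait`, `kd_mono_uM` (character, 2 significant
#'   digits or "N/A"), `kon_bi`, `koff_bi`, `n`, `r_squared`.
#' @export
report_interactions <- function(kin_list, c_eff, valency = 2L) {
  stopifnot(length(kin_list) >= 1L)
  fmt <- function(x, digits = 2) {
    ifelse(is.na(x), "N/A", as.character(signif(x, digits)))
  }
  purrr::map(kin_list, function(k) {
    mono <- tryCatch(kd_monovalent(k, c_eff = c_eff, valency = valency),
                     error = function(e) NULL)
    tibble::tibble(
      prey = k$prey, bait = k$bait,
      kd_mono_uM = fmt(if (is.null(mono)) NA_real_ else mono$kd_mono_uM),
      kon_bi = k$kon_bi, koff_bi = k$koff_bi,
      n = k$n_points, r_squared = k$r_squared
    )
  }) |>
    purrr::list_rbind()
}

#' @export
print.bivalent_kinetics <- function(x, ...) {
  cat("<bivalent_kinetics> ", x$prey, " (flowed) -> ", x$bait,
      " (immobilized)\n", sep = "")
  cat(sprintf("  kon_bi  %.4g +/- %.2g  M^-1 s^-1\n", x$kon_bi, x$se_kon))
  cat(sprintf("  koff_bi %.4g +/- %.2g  s^-1\n", x$koff_bi, x$se_koff))
  cat(sprintf("  KD_bi   %.4g +/- %.2g  M\n", x$kd_bi, x$se_kd))
  cat(sprintf("  R^2 %.4f over %d points\n", x$r_squared, x$n_points))
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' Tidy a bivalent-kinetics fit
#' @param x A `bivalent_kinetics`.
#' @param ... Unused.
#' @return A tibble with rows kon_bi, koff_bi, kd_bi (estimate, std.error,
#'   unit).
#' @export
tidy.bivalent_kinetics <- function(x, ...) {
  tibble::tibble(
    term = c("kon_bi", "koff_bi", "kd_bi"),
    estimate = c(x$kon_bi, x$koff_bi, x$kd_bi),
    std.error = c(x$se_kon, x$se_koff, x$se_kd),
    unit = c("M^-1 s^-1", "s^-1", "M")
  )
}

#' One-row summary of a bivalent-kinetics fit
#' @param x A `bivalent_kinetics`.
#' @param ... Unused.
#' @return A one-row tibble: `r.squared`, `nobs`, `n.experiments`.
#' @export
glance.bivalent_kinetics <- function(x, ...) {
  n_exp <- if ("experiment" %in% names(x$points)) {
    length(unique(x$points$experiment))
  } else 1L
  tibble::tibble(r.squared = x$r_squared, nobs = x$n_points,
                 n.experiments = n_exp)
}

#' Plot the k_obs-vs-concentration regression
#' @param object A `bivalent_kinetics`.
#' @param ... Unused.
#' @return A ggplot of pooled points and the fitted line whose slope is
#'   kon_bi and intercept koff_bi.
#' @export
autoplot.bivalent_kinetics <- function(object, ...) {
  d <- object$points
  aes_pts <- if ("experiment" %in% names(d)) {
    ggplot2::aes(x = .data$concentration_nM, y = .data$k_obs,
                 shape = factor(.data$experiment))
  } else {
    ggplot2::aes(x = .data$concentration_nM, y = .data$k_obs)
  }
  ggplot2::ggplot(d, aes_pts) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(slope = object$kon_bi * 1e-9,
                         intercept = object$koff_bi,
                         colour = "firebrick") +
    ggplot2::labs(x = "Complex concentration (nM)",
                  y = expression(k[obs] ~ (s^-1)),
                  shape = "Experiment",
                  title = sprintf("%s -> %s: slope = kon, intercept = koff",
                                  object$prey, object$bait)) +
    ggplot2::theme_minimal()
}
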