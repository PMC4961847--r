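#' Fit the absorbance-vs-concentration calibration line
#'
#' Ordinary least-squares fit of absorbance at 425 nm on known MNP
#' concentration, using the standard wells of a calibration plate. The
#' intercept is estimated, not forced through zero (the buffer blank is
#' nonzero in practice). Replicate wells enter as individual points to
#' preserve degrees of freedom for the residual SD.
#'
#' @param plate A calibration tibble with columns `role`,
#'   `concentration_nM`, `absorbance_425nm` (as produced by
#'   [simulate_calibration_plate()] or [read_calibration()]).
#' @return Object of class `calibration_curve`: fields `slope`
#'   (absorbance/nM), `intercept`, `r_squared`, `residual_sd`, `n_points`,
#'   plus the underlying `lm` fit and the standards used. Methods:
#'   [tidy.calibration_curve()], [glance.calibration_curve()],
#'   [autoplot.calibration_curve()].
#' @export
fit_calibration <- function(plate) {
  std <- plate |> dplyr::filter(.data$role == "standard")
  if (nrow(std) < 3L) {
    stop("calibration error: need >= 3 standard rows", call. = FALSE)
  }
  if (any(!is.finite(std$concentration_nM)) || any(std$concentration_nM < 0)) {
    stop("calibration data error: negative or missing standard ",
         "concentration", call. = FALSE)
  }
  if (length(unique(std$concentration_nM)) < 2L) {
    stop("calibration rank-deficiency error: all standards at one ",
         "concentration", call. = FALSE)
  }
  fit <- stats::lm(absorbance_425nm ~ concentration_nM, data = std)
  sm <- suppressWarnings(summary(fit))  # noiseless plates: perfect fit
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = sm$r.squared,
      residual_sd = sm$sigma,
      n_points = nrow(std),
      standard_range_nM = range(std$concentration_nM),
      fit = fit,
      standards = std
    ),
    class = "calibration_curve"
  )
}

#' Predict a concentration from absorbance (inverse regression)
#'
#' Inverts the calibration line: `c = (A - intercept) / slope`, averaging
#' replicate absorbance readings of the unknown first. The standard error
#' follows the classical OLS inverse-prediction (calibration) formula
#' \deqn{SE(\hat c) = \frac{s}{|\hat\beta_1|}\sqrt{\frac{1}{m} +
#'   \frac{1}{n} + \frac{(\hat c - \bar x)^2}{S_{xx}}}}
#' with `m` unknown replicates, `n` standard points, and `S_xx` the
#' standards' concentration sum of squares. Negative predictions are
#' returned as-is with a warning flag, never clipped; predictions outside
#' the standard range are flagged as extrapolation.
#'
#' @param curve A `calibration_curve`.
#' @param absorbance One or more absorbance readings of the same unknown
#'   (replicates are averaged).
#' @return A one-row tibble: `concentration_nM`, `se_nM`, `n_replicates`,
#'   `negative` and `extrapolated` flags.
#' @export
predict_concentration <- function(curve, absorbance) {
  stopifnot(inherits(curve, "calibration_curve"))
  x_range <- diff(curve$standard_range_nM)
  y_scale <- max(abs(curve$standards$absorbance_425nm), 1e-300)
  if (abs(curve$slope) * x_range < 1e-10 * y_scale) {
    stop("degenerate-curve error: calibration slope is zero", call. = FALSE)
  }
  absorbance <- absorbance[is.finite(absorbance)]
  if (length(absorbance) == 0L) {
    stop("calibration data error: no finite absorbance readings",
         call. = FALSE)
  }
  a_bar <- mean(absorbance)
  m <- length(absorbance)
  c_hat <- (a_bar - curve$intercept) / curve$slope
  x <- curve$standards$concentration_nM
  sxx <- sum((x - mean(x))^2)
  se <- (curve$residual_sd / abs(curve$slope)) *
    sqrt(1 / m + 1 / curve$n_points + (c_hat - mean(x))^2 / sxx)
  negative <- c_hat < 0
  rng <- curve$standard_range_nM
  tol <- 1e-9 * max(diff(rng), 1e-12)  # don't flag the endpoints themselves
  extrapolated <- c_hat < rng[1] - tol || c_hat > rng[2] + tol
  if (negative) {
    warning("predicted concentration is negative (", signif(c_hat, 4),
            " nM); returned unclipped", call. = FALSE)
  } else if (extrapolated) {
    warning("predicted concentration ", signif(c_hat, 4),
            " nM lies outside the standard range [",
            curve$standard_range_nM[1], ", ", curve$standard_range_nM[2],
            "] nM (extrapolation)", call. = FALSE)
  }
  tibble::tibble(concentration_nM = c_hat, se_nM = se, n_replicates = m,
                 negative = negative, extrapolated = extrapolated)
}

#' Dilute an eluted concentration into per-channel concentrations
#'
#' Applies the layout's serial dilution scheme (default 100/75/50/25% of the
#' eluted concentration) to a calibrated eluate concentration.
#'
#' @param eluted_nM Eluted concentration, nM (>= 0).
#' @param layout A `chip_layout`.
#' @param prey Prey protein name carried through to reporting.
#' @return An `mnp_batch`.
#' @export
channel_concentrations <- function(eluted_nM, layout = chip_layout(),
                                   prey = "prey") {
  mnp_batch(eluted_nM, layout, prey = prey)
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("<calibration_curve> absorbance(425 nm) ~ concentration (nM)\n")
  cat(sprintf("  slope      %.6g  abs/nM\n", x$slope))
  cat(sprintf("  intercept  %.6g  abs\n", x$intercept))
  cat(sprintf("  R^2        %.6f   residual SD %.3g   n = %d\n",
              x$r_squared, x$residual_sd, x$n_points))
  invisible(x)
}

#' Tidy a calibration curve
#' @param x A `calibration_curve`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient (term, estimate,
#'   std.error).
#' @export
tidy.calibration_curve <- function(x, ...) {
  sm <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = unname(sm[, "Estimate"]),
    std.error = unname(sm[, "Std. Error"])
  )
}

#' One-row summary of a calibration curve
#' @param x A `calibration_curve`.
#' @param ... Unused.
#' @return A one-row tibble: `r.squared`, `sigma`, `nobs`.
#' @export
glance.calibration_curve <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, sigma = x$residual_sd,
                 nobs = x$n_points)
}

#' Plot a calibration curve
#' @param object A `calibration_curve`.
#' @param ... Unused.
#' @return A ggplot: standard points and the fitted line.
#' @export
autoplot.calibration_curve <- function(object, ...) {
  ggplot2::ggplot(object$standards,
                  ggplot2::aes(x = .data$concentration_nM,
                               y = .data$absorbance_425nm)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "MNP concentration (nM)", y = "Absorbance at 425 nm",
                  title = sprintf("Calibration: R² = %.4f",
                                  object$r_squared)) +
    ggplot2::theme_minimal()
}
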