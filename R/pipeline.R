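#' Assemble a pipeline run configuration
#'
#' Collects everything one reproducible run needs: the chip layout, the
#' ground truth for simulation (or paths to measured inputs), noise and
#' calibration settings, fitting options and the avidity-conversion
#' parameters. Validated up front so misconfiguration fails before any
#' computation.
#'
#' @param layout A `chip_layout` (or path to a layout JSON).
#' @param seed Integer master seed, recorded in every output.
#' @param prey Prey protein name.
#' @param truth Named list of `kinetic_truth` keyed by bait (simulation
#'   ground truth); ignored when `traces_path` is given.
#' @param traces_path Optional path to an existing traces CSV; when given,
#'   simulation is skipped.
#' @param calibration_path Optional path to an existing calibration CSV.
#' @param eluted_nM True eluted concentration used when simulating
#'   (default 1.0).
#' @param cal_slope,cal_intercept,cal_noise_sd Calibration-plate simulation
#'   parameters (absorbance/nM, absorbance, absorbance).
#' @param sigma_rel,amp_cv Trace noise parameters (see [noise_model()]).
#' @param onset `"auto"` for detection or a fixed time in seconds
#'   (default: the layout's `onset_time`).
#' @param window Post-onset samples per fit (default 80).
#' @param kd_mono Request monovalent-K_D conversion (default `TRUE`).
#' @param c_eff Effective concentration, molar; required when
#'   `kd_mono = TRUE`.
#' @param valency Assumed valency (default 2).
#' @param b_m Optional bait surface-site density, mol/m^2; when given a
#'   transport regime report is produced.
#' @return A validated `run_config` list.
#' @export
run_config <- function(layout = chip_layout(), seed = 1L, prey = "prey",
                       truth = list("PD-L2" = kinetic_truth()),
                       traces_path = NULL, calibration_path = NULL,
                       eluted_nM = 1.0,
                       cal_slope = 0.5, cal_intercept = 0.05,
                       cal_noise_sd = 0.005,
                       sigma_rel = 0.02, amp_cv = 0.05,
                       onset = NULL, window = 80L,
                       kd_mono = TRUE, c_eff = NULL, valency = 2L,
                       b_m = NULL) {
  if (is.character(layout)) layout <- read_layout(layout)
  validate_layout(layout)
  if (isTRUE(kd_mono) && is.null(c_eff)) {
    stop("configuration error: kd_mono requested but c_eff not supplied; ",
         "the effective concentration has no default", call. = FALSE)
  }
  if (!is.null(traces_path) && !file.exists(traces_path)) {
    stop("configuration error: traces_path does not exist: ", traces_path,
         call. = FALSE)
  }
  if (!is.null(calibration_path) && !file.exists(calibration_path)) {
    stop("configuration error: calibration_path does not exist: ",
         calibration_path, call. = FALSE)
  }
  structure(
    list(layout = layout, seed = as.integer(seed), prey = prey,
         truth = truth, traces_path = traces_path,
         calibration_path = calibration_path, eluted_nM = eluted_nM,
         cal_slope = cal_slope, cal_intercept = cal_intercept,
         cal_noise_sd = cal_noise_sd, sigma_rel = sigma_rel,
         amp_cv = amp_cv, onset = onset, window = as.integer(window),
         kd_mono = isTRUE(kd_mono), c_eff = c_eff,
         valency = as.integer(valency), b_m = b_m),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — calibrate, simulate (or load traces),
#' reference-subtract, synchronize, fit, pool k_obs, convert to monovalent
#' K_D, and (optionally) diagnose the transport regime — writing each
#' stage's standard files under `out_dir` plus a `run_manifest.json`
#' recording inputs, seed, parameters and output checksums. Rerunning with
#' an identical config reproduces all numeric outputs bit-identically.
#'
#' Files written: `layout.json`, `calibration.csv`, `calibration.json`,
#' `traces.csv`, `fits.tsv`, `kinetics.tsv`, `kinetics.json`,
#' `report.tsv`, optionally `regime.json`, and `run_manifest.json`.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created if absent); one directory per
#'   run.
#' @return A list with the in-memory stage results (`calibration`,
#'   `batch`, `traces`, `fits`, `kinetics`, `monovalent`, `regime`,
#'   `manifest`) and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  layout <- config$layout
  pth <- function(f) file.path(out_dir, f)
  stage <- "layout"
  res <- tryCatch({
    write_layout(layout, pth("layout.json"))

    stage <- "calibrate"
    plate <- if (!is.null(config$calibration_path)) {
      read_calibration(config$calibration_path)
    } else {
      simulate_calibration_plate(
        true_slope = config$cal_slope, true_intercept = config$cal_intercept,
        unknown_nM = config$eluted_nM, noise_sd = config$cal_noise_sd,
        seed = config$seed + 101L
      )
    }
    write_calibration(plate, pth("calibration.csv"))
    curve <- fit_calibration(plate)
    unknown_abs <- plate$absorbance_425nm[plate$role == "unknown"]
    pred <- predict_concentration(curve, unknown_abs)
    jsonlite::write_json(
      list(slope = curve$slope, intercept = curve$intercept,
           r_squared = curve$r_squared, residual_sd = curve$residual_sd,
           n_points = curve$n_points,
           eluted_nM = pred$concentration_nM, eluted_se_nM = pred$se_nM),
      pth("calibration.json"), auto_unbox = TRUE, digits = NA
    )
    batch <- mnp_batch(pred$concentration_nM, layout, prey = config$prey)

    stage <- "simulate"
    traces <- if (!is.null(config$traces_path)) {
      read_traces(config$traces_path, layout)
    } else {
      true_batch <- mnp_batch(config$eluted_nM, layout, prey = config$prey)
      simulate_dataset(
        layout, true_batch, config$truth,
        noise = noise_model(config$sigma_rel, config$amp_cv,
                            seed = config$seed)
      )
    }
    write_traces(traces, pth("traces.csv"))

    stage <- "fit"
    sub <- subtract_reference(traces, layout)
    onset <- config$onset %||% layout$onset_time
    sync <- if (identical(onset, "auto")) {
      synchronize_onset(sub, layout$onset_time)
    } else {
      attr(sub, "onset_time") <- as.numeric(onset)
      sub
    }
    fits <- fit_binding_curves(sync, window = config$window)
    write_fits(fits, pth("fits.tsv"))

    stage <- "kinetics"
    agg <- aggregate_duplicates(fits)
    pts <- kobs_points(agg, batch)
    target_baits <- if (!is.null(config$truth)) {
      intersect(names(config$truth), unique(pts$bait))
    } else unique(pts$bait)
    kin_list <- purrr::map(
      target_baits,
      ~ pool_kobs(pts, bait = .x, prey = config$prey)
    )
    names(kin_list) <- target_baits
    kin_tbl <- purrr::map(kin_list, function(k) {
      tibble::tibble(prey = k$prey, bait = k$bait, kon_bi = k$kon_bi,
                     se_kon = k$se_kon, koff_bi = k$koff_bi,
                     se_koff = k$se_koff, kd_bi_M = k$kd_bi,
                     se_kd_bi_M = k$se_kd, r_squared = k$r_squared,
                     n_points = k$n_points)
    }) |> purrr::list_rbind()
    readr::write_tsv(kin_tbl, pth("kinetics.tsv"), progress = FALSE)

    mono <- NULL
    if (config$kd_mono) {
      mono <- purrr::map(kin_list, function(k) {
        # a noise-floor (nonpositive) KD_bi cannot be converted; report NA
        tryCatch(
          kd_monovalent(k, c_eff = config$c_eff, valency = config$valency),
          error = function(e) tibble::tibble(
            prey = k$prey, bait = k$bait, kd_bi_M = k$kd_bi,
            kd_mono_M = NA_real_, kd_mono_uM = NA_real_,
            se_kd_mono_M = NA_real_, valency = config$valency,
            c_eff_M = config$c_eff)
        )
      }) |> purrr::list_rbind()
    }
    jsonlite::write_json(
      list(kinetics = kin_tbl, monovalent = mono, seed = config$seed),
      pth("kinetics.json"), auto_unbox = TRUE, digits = NA
    )

    stage <- "report"
    rep_tbl <- report_interactions(
      kin_list, c_eff = config$c_eff %||% NA_real_,
      valency = config$valency
    )
    readr::write_tsv(rep_tbl, pth("report.tsv"), progress = FALSE)

    regime <- NULL
    if (!is.null(config$b_m)) {
      stage <- "regime"
      kon_est <- kin_tbl$kon_bi[1]
      regime <- regime_report(transport_params(), channel_geometry(),
                              kon_bi = kon_est, b_m = config$b_m)
      jsonlite::write_json(glance(regime), pth("regime.json"),
                           auto_unbox = TRUE, digits = NA)
    }

    stage <- "manifest"
    files <- sort(setdiff(list.files(out_dir), "run_manifest.json"))
    manifest <- list(
      package = "mnpkinetics",
      version = as.character(utils::packageVersion("mnpkinetics")),
      seed = config$seed,
      parameters = list(
        prey = config$prey, eluted_nM = config$eluted_nM,
        sigma_rel = config$sigma_rel, amp_cv = config$amp_cv,
        window = config$window, onset = config$onset %||% "layout",
        c_eff = config$c_eff, valency = config$valency, b_m = config$b_m
      ),
      outputs = as.list(tools::md5sum(file.path(out_dir, files))) |>
        stats::setNames(files)
    )
    jsonlite::write_json(manifest, pth("run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(calibration = curve, eluted = pred, batch = batch, traces = traces,
         fits = fits, kinetics = kin_list, kinetics_table = kin_tbl,
         monovalent = mono, regime = regime, manifest = manifest,
         out_dir = out_dir)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  res
}
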