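#' Read and write binding-trace files
#'
#' Binding traces travel between pipeline stages as long-format CSV
#' (comma-delimited, UTF-8, mandatory header) with one record per
#' (time, channel, sensor) observation and columns `time_s`, `channel`,
#' `sensor`, `bait`, `signal`. Signals are in arbitrary sensor units,
#' proportional to the coverage of bound nanoparticle complexes; only ratios
#' and rates are interpreted downstream, so no absolute signal calibration
#' is required. `read_traces()` validates the file, attaches roles from the
#' layout when one is supplied, and returns the tidy trace table every other
#' stage consumes.
#'
#' @param path CSV file path.
#' @param layout Optional `chip_layout`; when given, a `role` column is
#'   joined on and every (channel, sensor) is checked against the layout.
#' @return A tibble with columns `channel`, `sensor`, `bait`, `role` (if a
#'   layout was supplied), `time_s`, `signal`, sorted by channel, sensor,
#'   time.
#' @details Validation errors are raised for: missing columns (named in the
#'   message), non-finite signals, duplicated (channel, sensor, time)
#'   records, and time grids that are not strictly increasing with constant
#'   spacing (the offending sensor is identified).
#' @export
read_traces <- function(path, layout = NULL) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  # base parser: correctly rounded doubles, so write -> read is bit-exact
  tr <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  needed <- c("time_s", "channel", "sensor", "bait", "signal")
  missing_cols <- setdiff(needed, names(tr))
  if (length(missing_cols) > 0L) {
    stop("trace format error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tr <- tr |>
    dplyr::mutate(channel = as.integer(.data$channel),
                  sensor = as.integer(.data$sensor),
                  bait = as.character(.data$bait),
                  time_s = as.numeric(.data$time_s),
                  signal = as.numeric(.data$signal)) |>
    dplyr::arrange(.data$channel, .data$sensor, .data$time_s)
  validate_traces(tr)
  if (!is.null(layout)) tr <- attach_roles(tr, layout)
  tr
}

#' @rdname read_traces
#' @param traces A trace tibble (as produced by [simulate_dataset()] or
#'   [read_traces()]).
#' @export
write_traces <- function(traces, path) {
  validate_traces(traces)
  # 17 significant digits: doubles survive the text round-trip bit-exactly
  out <- traces |>
    dplyr::select("time_s", "channel", "sensor", "bait", "signal") |>
    dplyr::mutate(time_s = sprintf("%.17g", .data$time_s),
                  signal = sprintf("%.17g", .data$signal))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Validate a trace table
#'
#' Checks the invariants every stage relies on: finite signals, no
#' duplicated (channel, sensor, time) records, and per-sensor time grids
#' that are strictly increasing with constant spacing (relative tolerance
#' 1e-9 on the step).
#'
#' @param traces A trace tibble.
#' @return The traces, invisibly, if valid.
#' @export
validate_traces <- function(traces) {
  needed <- c("time_s", "channel", "sensor", "bait", "signal")
  missing_cols <- setdiff(needed, names(traces))
  if (length(missing_cols) > 0L) {
    stop("trace format error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(traces$signal))) {
    stop("trace data error: non-finite signals present", call. = FALSE)
  }
  keys <- paste(traces$channel, traces$sensor, traces$time_s)
  if (anyDuplicated(keys)) {
    bad <- traces[duplicated(keys), , drop = FALSE][1, ]
    stop("trace data error: duplicated record at channel ", bad$channel,
         ", sensor ", bad$sensor, ", t = ", bad$time_s, " s", call. = FALSE)
  }
  check_grid <- function(d) {
    t <- sort(d$time_s)
    if (length(t) >= 2L) {
      dt <- diff(t)
      if (any(dt <= 0) ||
          (max(dt) - min(dt)) > 1e-9 * max(abs(dt))) {
        stop("trace data error: non-uniform or non-increasing time grid ",
             "for channel ", d$channel[1], ", sensor ", d$sensor[1],
             call. = FALSE)
      }
    }
    NULL
  }
  traces |>
    dplyr::group_by(.data$channel, .data$sensor) |>
    dplyr::group_map(~ check_grid(.x |>
      dplyr::mutate(channel = .y$channel, sensor = .y$sensor)))
  invisible(traces)
}

#' Attach layout roles to traces
#'
#' Joins the layout's (channel, sensor) -> (bait, role) assignment onto a
#' trace table and cross-checks that every trace's bait matches the layout.
#'
#' @param traces A trace tibble.
#' @param layout A `chip_layout`.
#' @return The traces with a `role` column.
#' @export
attach_roles <- function(traces, layout) {
  lt <- layout_table(layout)
  joined <- traces |>
    dplyr::select(-dplyr::any_of(c("role", "dilution_fraction"))) |>
    dplyr::left_join(lt, by = c("channel", "sensor"),
                     suffix = c("", ".layout"))
  if (any(is.na(joined$role))) {
    bad <- joined |> dplyr::filter(is.na(.data$role)) |>
      dplyr::distinct(.data$channel, .data$sensor)
    stop("trace data error: sensors absent from layout: ",
         paste(sprintf("(ch %d, s %d)", bad$channel, bad$sensor),
               collapse = ", "), call. = FALSE)
  }
  mismatch <- joined$bait != joined$bait.layout
  if (any(mismatch)) {
    bad <- joined[which(mismatch)[1], ]
    stop("trace data error: bait mismatch with layout at channel ",
         bad$channel, ", sensor ", bad$sensor, " (file: ", bad$bait,
         ", layout: ", bad$bait.layout, ")", call. = FALSE)
  }
  joined |>
    dplyr::select("channel", "sensor", "bait", "role", "dilution_fraction",
                  "time_s", "signal")
}
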