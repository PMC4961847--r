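#' Chip layout: channels, sensors, baits and acquisition parameters
#'
#' A `chip_layout` describes one magneto-nanosensor chip integrated with a
#' multi-channel microfluidic: how many channels it has, which bait protein
#' sits on each sensor, what role each bait plays in the analysis, the
#' per-channel dilution of the eluted nanoparticle stock, and the acquisition
#' timing. The immobilization pattern is identical across channels, so a
#' single `bait_map` (one bait name per sensor index) applies to every
#' channel.
#'
#' Roles drive the downstream analysis: `"probe"` sensors carry baits whose
#' kinetics are of interest, `"negative_control"` sensors carry non-binding
#' proteins (e.g. BSA, non-cognate IgG) used for reference subtraction, and
#' `"reference"` marks dedicated reference sensors where a chip provides
#' them. Channels and sensors are indexed from 0.
#'
#' @param bait_map Character vector, one bait name per sensor index
#'   (applied identically to every channel). Default: six probe baits in
#'   duplicate plus four negative-control sensors (16 sensors).
#' @param role_map Named character vector mapping bait name to one of
#'   `"probe"`, `"negative_control"`, `"reference"`.
#' @param n_channels Number of microfluidic channels (default 4).
#' @param dilution_fractions Per-channel fraction of the eluted MNP
#'   concentration, in (0, 1]. Default `c(1, 0.75, 0.5, 0.25)`.
#' @param sampling_interval Sensor readout period in seconds (default 5.5).
#' @param onset_time Nominal binding-onset time in seconds (default 60,
#'   i.e. sample introduction near 1 min).
#'
#' @return A validated object of class `chip_layout`.
#' @examples
#' layout <- chip_layout()
#' layout_table(layout)
#' @export
chip_layout <- function(bait_map = default_bait_map(),
                        role_map = default_role_map(),
                        n_channels = 4L,
                        dilution_fractions = c(1, 0.75, 0.5, 0.25),
                        sampling_interval = 5.5,
                        onset_time = 60) {
  layout <- structure(
    list(
      bait_map = as.character(bait_map),
      role_map = role_map,
      n_channels = as.integer(n_channels),
      sensors_per_channel = length(bait_map),
      dilution_fractions = as.numeric(dilution_fractions),
      sampling_interval = as.numeric(sampling_interval),
      onset_time = as.numeric(onset_time)
    ),
    class = "chip_layout"
  )
  validate_layout(layout)
}

#' Default bait map: six baits in duplicate plus four negative controls
#'
#' Sensor assignment for a 16-sensor channel: six distinct probe baits, each
#' on two identical sensors, and four control sensors (two BSA, two
#' non-cognate mouse IgG).
#' @return Character vector of length 16.
#' @export
default_bait_map <- function() {
  probes <- c("PD-1", "PD-L1", "PD-L2", "B7-1", "bait5", "bait6")
  c(rep(probes, each = 2), rep(c("BSA", "mIgG"), each = 2))
}

#' Default role map for [default_bait_map()]
#' @return Named character vector of roles.
#' @export
default_role_map <- function() {
  c("PD-1" = "probe", "PD-L1" = "probe", "PD-L2" = "probe",
    "B7-1" = "probe", "bait5" = "probe", "bait6" = "probe",
    "BSA" = "negative_control", "mIgG" = "negative_control")
}

#' Validate a chip layout
#'
#' Checks the structural invariants a layout must satisfy before any stage
#' will accept it: known roles for every bait, equal duplicate counts for
#' every probe/control bait, dilution fractions in (0, 1], at least one
#' reference-capable sensor per channel (reference subtraction is impossible
#' otherwise), and positive timing parameters.
#'
#' @param layout A `chip_layout`.
#' @return The layout, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_layout <- function(layout) {
  stopifnot(inherits(layout, "chip_layout"))
  bm <- layout$bait_map
  rm_ <- layout$role_map
  if (length(bm) < 1L) stop("layout error: empty bait_map", call. = FALSE)
  unknown <- setdiff(unique(bm), names(rm_))
  if (length(unknown) > 0L) {
    stop("layout error: baits without a role: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  bad_role <- setdiff(unique(rm_), c("probe", "negative_control", "reference"))
  if (length(bad_role) > 0L) {
    stop("layout error: unknown roles: ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  }
  counts <- table(bm)
  roles_of <- rm_[names(counts)]
  # duplicates: every probe/control bait appears the same number of times
  dup_counts <- counts[roles_of %in% c("probe", "negative_control")]
  if (length(unique(as.integer(dup_counts))) > 1L) {
    stop("layout error: baits are not replicated an identical number of ",
         "times: ", paste(names(dup_counts), as.integer(dup_counts),
                          sep = "=", collapse = ", "), call. = FALSE)
  }
  n_ref <- sum(rm_[bm] %in% c("negative_control", "reference"))
  if (n_ref == 0L) {
    stop("layout error: no negative-control or reference sensors; ",
         "reference subtraction impossible", call. = FALSE)
  }
  df <- layout$dilution_fractions
  if (length(df) != layout$n_channels) {
    stop("layout error: dilution_fractions length (", length(df),
         ") != n_channels (", layout$n_channels, ")", call. = FALSE)
  }
  if (any(!is.finite(df)) || any(df <= 0) || any(df > 1)) {
    stop("layout error: dilution fractions must lie in (0, 1]", call. = FALSE)
  }
  if (!is.finite(layout$sampling_interval) || layout$sampling_interval <= 0) {
    stop("layout error: sampling_interval must be positive", call. = FALSE)
  }
  if (!is.finite(layout$onset_time) || layout$onset_time < 0) {
    stop("layout error: onset_time must be nonnegative", call. = FALSE)
  }
  invisible(layout)
}

#' Tabulate a chip layout
#'
#' Expands the per-channel bait map into one row per (channel, sensor) with
#' the bait name, role, and dilution fraction — the join table used to
#' attach roles and concentrations to traces.
#'
#' @param layout A `chip_layout`.
#' @return A tibble with columns `channel`, `sensor`, `bait`, `role`,
#'   `dilution_fraction`.
#' @export
layout_table <- function(layout) {
  validate_layout(layout)
  per_channel <- tibble::tibble(
    sensor = seq_along(layout$bait_map) - 1L,
    bait = layout$bait_map,
    role = unname(layout$role_map[layout$bait_map])
  )
  tidyr::crossing(channel = seq_len(layout$n_channels) - 1L, per_channel) |>
    dplyr::mutate(
      dilution_fraction = layout$dilution_fractions[.data$channel + 1L]
    ) |>
    dplyr::arrange(.data$channel, .data$sensor)
}

#' @export
print.chip_layout <- function(x, ...) {
  cat("<chip_layout>\n")
  cat("  channels:            ", x$n_channels, "\n")
  cat("  sensors per channel: ", x$sensors_per_channel, "\n")
  cat("  dilution fractions:  ", paste(x$dilution_fractions, collapse = ", "),
      "\n")
  cat("  sampling interval:   ", x$sampling_interval, "s\n")
  cat("  onset time:          ", x$onset_time, "s\n")
  roles <- unname(x$role_map[x$bait_map])
  cat("  baits: ", paste(sprintf("%s(%s)", unique(x$bait_map),
                                 substr(x$role_map[unique(x$bait_map)], 1, 1)),
                         collapse = " "), "\n")
  cat("  probe sensors/channel:", sum(roles == "probe"),
      " control:", sum(roles != "probe"), "\n")
  invisible(x)
}

#' Write / read a chip layout as JSON
#'
#' The JSON file carries exactly the `chip_layout` fields, so
#' `read_layout(write_layout(x, p))` reproduces `x`.
#'
#' @param layout A `chip_layout`.
#' @param path File path.
#' @return `write_layout` returns `path` invisibly; `read_layout` returns a
#'   validated `chip_layout`.
#' @export
write_layout <- function(layout, path) {
  validate_layout(layout)
  out <- list(
    bait_map = layout$bait_map,
    role_map = as.list(layout$role_map),
    n_channels = layout$n_channels,
    dilution_fractions = layout$dilution_fractions,
    sampling_interval = layout$sampling_interval,
    onset_time = layout$onset_time
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) {
    stop("layout file not found: ", path, call. = FALSE)
  }
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  chip_layout(
    bait_map = j$bait_map,
    role_map = unlist(j$role_map),
    n_channels = j$n_channels,
    dilution_fractions = j$dilution_fractions,
    sampling_interval = j$sampling_interval,
    onset_time = j$onset_time
  )
}
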