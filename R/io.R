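#' Analysis configuration
#'
#' @param bin_width angular bin width in degrees (default 15; must divide
#'   360).
#' @param alpha significance level for the correlation gate (default 0.05).
#' @param exclude_first_rotation override of the protocol's first-rotation
#'   exclusion (`NULL` keeps the protocol's setting).
#' @param phi_from `"spikes"` or `"bins"` (see [compute_tuning()]).
#' @param sd_convention `"angular_deviation"` or `"circular_sd"`.
#' @param output_dir directory for result files.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(bin_width = 15, alpha = 0.05,
                            exclude_first_rotation = NULL,
                            phi_from = c("spikes", "bins"),
                            sd_convention = c("angular_deviation", "circular_sd"),
                            output_dir = ".") {
  if (360 %% bin_width != 0) {
    skytuner_error("skytuner_config_error", "bin_width must divide 360")
  }
  stopifnot(alpha > 0, alpha < 1)
  structure(
    list(
      bin_width = bin_width,
      alpha = alpha,
      exclude_first_rotation = exclude_first_rotation,
      phi_from = match.arg(phi_from),
      sd_convention = match.arg(sd_convention),
      output_dir = output_dir
    ),
    class = "analysis_config"
  )
}

#' Read a spike-time CSV
#'
#' Expects a header line with a `time_s` column of spike times in seconds
#' (an optional `recording_id` column names the recording). Unsorted
#' times are sorted with a warning; missing columns, non-numeric rows and
#' negative times raise typed parse errors naming the offending line.
#'
#' @param path CSV file path.
#' @return a [spike_train()].
#' @export
read_spike_csv <- function(path) {
  if (!file.exists(path)) {
    skytuner_error("skytuner_parse_error", sprintf("file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = NA)
  if (!"time_s" %in% names(df)) {
    skytuner_error("skytuner_parse_error",
                   sprintf("%s: missing required column 'time_s'", path))
  }
  raw <- df$time_s
  t <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.finite(t))
  if (length(bad)) {
    skytuner_error("skytuner_parse_error",
                   sprintf("%s: non-numeric time_s at data line %d", path, bad[1]))
  }
  neg <- which(t < 0)
  if (length(neg)) {
    skytuner_error("skytuner_parse_error",
                   sprintf("%s: negative time_s at data line %d", path, neg[1]))
  }
  if (is.unsorted(t)) {
    warning(sprintf("%s: time_s not sorted; sorting", path))
  }
  id <- if ("recording_id" %in% names(df) && nrow(df)) as.character(df$recording_id[1])
        else sub("\\.csv$", "", basename(path))
  spike_train(t, recording_id = id)
}

#' Write a spike train to CSV
#'
#' @param spikes a [spike_train()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spike_csv <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_train"))
  # full precision so write -> read round-trips bit-identically
  utils::write.csv(
    data.frame(time_s = sprintf("%.17g", spikes$times),
               recording_id = spikes$recording_id),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read / write a stimulus protocol as YAML
#'
#' The protocol config is a key-value tree with `segments` (fields of
#' [rotation_segment()]), `off_intervals`, `stationary_intervals` and
#' `exclude_first_rotation`. Periodicity is implied by the stimulus kind.
#'
#' @param path YAML file path.
#' @return `read_protocol_yaml()`: a [stimulus_protocol()].
#' @export
read_protocol_yaml <- function(path) {
  if (!file.exists(path)) {
    skytuner_error("skytuner_parse_error", sprintf("file not found: %s", path))
  }
  y <- yaml::read_yaml(path)
  segments <- lapply(y$segments, function(s) {
    rotation_segment(
      stimulus_kind = s$stimulus_kind,
      direction = s$direction,
      angular_velocity = s$angular_velocity,
      start_time = s$start_time %||% 0,
      start_angle = s$start_angle %||% 0,
      n_turns = s$n_turns %||% 3,
      elevation = s$elevation,
      visual_angle = s$visual_angle
    )
  })
  stimulus_protocol(
    segments,
    off_intervals = lapply(y$off_intervals, as.numeric),
    stationary_intervals = y$stationary_intervals %||% list(),
    exclude_first_rotation = y$exclude_first_rotation %||% TRUE
  )
}

#' @rdname read_protocol_yaml
#' @param protocol a [stimulus_protocol()].
#' @return `write_protocol_yaml()`: `path`, invisibly.
#' @export
write_protocol_yaml <- function(protocol, path) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  y <- list(
    segments = lapply(protocol$segments, function(s) {
      s[c("stimulus_kind", "direction", "angular_velocity", "start_time",
          "start_angle", "n_turns", "elevation", "visual_angle")]
    }),
    off_intervals = lapply(protocol$off_intervals, as.numeric),
    stationary_intervals = protocol$stationary_intervals,
    exclude_first_rotation = protocol$exclude_first_rotation
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

# Serializable view of a tuning result (degrees and impulses/s only).
# R2 is omitted entirely for non-significant results.
.tuning_result_record <- function(x) {
  rec <- list(
    recording_id = x$recording_id,
    stimulus_kind = x$stimulus_kind,
    group = x$group,
    periodicity = x$periodicity,
    phi_max = if (is.na(x$phi_max)) NULL else x$phi_max,
    r = x$r,
    circ_sd = x$circ_sd,
    ci95_halfarc = if (is.na(x$ci95_halfarc)) NULL else x$ci95_halfarc,
    p = x$p,
    significant = x$significant,
    n_rotations = x$n_rotations,
    n_samples = x$n_samples,
    n_spikes = x$n_spikes,
    bin_width = x$bin_width,
    opponency = x$opponency
  )
  if (x$significant && !is.na(x$R2)) rec$R2 <- x$R2
  if (!is.null(x$background)) {
    rec$background <- list(
      mean_rate = x$background$mean_rate,
      sd = x$background$sd,
      n_bins = x$background$n_bins
    )
  }
  rec
}

#' Plot-ready circular-histogram table
#'
#' Flattens a binned tuning curve and its summary statistics into the
#' values needed to redraw a polar histogram: one row per angular bin
#' (bin center, mean rate, SD across trial pairs, background mean) plus
#' one metadata row carrying Phi_max, r and the confidence-arc limits
#' (empty when Phi_max is undefined).
#'
#' @param binned a [bin_spike_angles()] result.
#' @param result the matching [compute_tuning()] result.
#' @return data frame with columns `row_type`, `bin_center`, `mean_rate`,
#'   `sd`, `background_mean`, `phi_max`, `r`, `ci_lo`, `ci_hi`.
#' @export
render_polarplot_data <- function(binned, result) {
  stopifnot(inherits(binned, "binned_tuning"), inherits(result, "tuning_result"))
  bg <- if (!is.null(result$background)) result$background$mean_rate else NA_real_
  data_rows <- data.frame(
    row_type = "bin",
    bin_center = binned$bin_centers,
    mean_rate = binned$mean_rate,
    sd = binned$sd_rate,
    background_mean = bg,
    phi_max = NA_real_, r = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
    stringsAsFactors = FALSE
  )
  has_phi <- !is.na(result$phi_max)
  has_ci <- has_phi && !is.na(result$ci95_halfarc)
  meta <- data.frame(
    row_type = "meta",
    bin_center = NA_real_, mean_rate = NA_real_, sd = NA_real_,
    background_mean = bg,
    phi_max = if (has_phi) result$phi_max else NA_real_,
    r = if (has_phi) result$r else NA_real_,
    ci_lo = if (has_ci) (result$phi_max - result$ci95_halfarc) %% result$periodicity
            else NA_real_,
    ci_hi = if (has_ci) (result$phi_max + result$ci95_halfarc) %% result$periodicity
            else NA_real_,
    stringsAsFactors = FALSE
  )
  rbind(data_rows, meta)
}

#' Summary table of tuning results
#'
#' One row per neuron x stimulus x rotation group with the columns of a
#' standard sensitivity table: n (rotations), Phi_max, r, and R^2 or
#' "n.s." for non-significant tuning.
#'
#' @param results list of [compute_tuning()] results.
#' @return data frame with columns `recording_id`, `stimulus`, `group`,
#'   `n`, `phi_max`, `r`, `R2` (character; `"n.s."` when not significant).
#' @export
summary_table <- function(results) {
  if (inherits(results, "tuning_result")) results <- list(results)
  do.call(rbind, lapply(results, function(x) {
    data.frame(
      recording_id = x$recording_id,
      stimulus = x$stimulus_kind,
      group = x$group,
      n = x$n_rotations,
      phi_max = if (x$significant) sprintf("%.1f", x$phi_max) else "n.s.",
      r = if (x$significant) sprintf("%.2f", x$r) else "",
      R2 = if (x$significant) sprintf("%.2f", x$R2) else "",
      stringsAsFactors = FALSE
    )
  }))
}

#' Run the full analysis and write a result bundle
#'
#' Reads a spike CSV and a protocol YAML, computes background activity
#' and per-group (`cw`, `ccw`, `both`) tuning for every stimulus kind in
#' the protocol, and writes to `config$output_dir`: one JSON file of
#' tuning-result records, one binned-curve CSV and one polar-plot CSV per
#' result, a summary-table CSV, and a machine-readable run manifest
#' (inputs, configuration, package version).
#'
#' @param config an [analysis_config()].
#' @param spikes_path path to the spike-time CSV.
#' @param protocol_path path to the protocol YAML.
#' @return invisibly, the list of [compute_tuning()] results.
#' @export
run_analysis <- function(config, spikes_path, protocol_path) {
  stopifnot(inherits(config, "analysis_config"))
  spikes <- read_spike_csv(spikes_path)
  protocol <- read_protocol_yaml(protocol_path)
  if (!is.null(config$exclude_first_rotation)) {
    protocol$exclude_first_rotation <- isTRUE(config$exclude_first_rotation)
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  kinds <- unique(vapply(protocol$segments, `[[`, character(1), "stimulus_kind"))
  background <- tryCatch(background_stats(spikes, protocol),
                         skytuner_error = function(e) NULL)
  results <- list()
  for (kind in kinds) {
    present <- unique(rotation_windows(protocol)$direction[
      rotation_windows(protocol)$stimulus_kind == kind])
    groups <- c(intersect(c("cw", "ccw"), present),
                if (length(present) > 0) "both")
    for (grp in groups) {
      res <- tryCatch(
        compute_tuning(spikes, protocol, kind, grp,
                       bin_width = config$bin_width, alpha = config$alpha,
                       phi_from = config$phi_from,
                       sd_convention = config$sd_convention,
                       background = background),
        skytuner_insufficient_data = function(e) NULL
      )
      if (is.null(res)) next
      results[[paste(kind, grp, sep = "_")]] <- res
      stem <- file.path(config$output_dir,
                        paste(spikes$recording_id, kind, grp, sep = "_"))
      utils::write.csv(
        data.frame(bin_center = res$binned$bin_centers,
                   mean_rate = res$binned$mean_rate,
                   sd = res$binned$sd_rate,
                   n = res$binned$n_rotations),
        paste0(stem, "_curve.csv"), row.names = FALSE
      )
      utils::write.csv(render_polarplot_data(res$binned, res),
                       paste0(stem, "_polar.csv"), row.names = FALSE)
    }
  }
  if (!length(results)) {
    skytuner_error("skytuner_insufficient_data",
                   "no analyzable trials in the protocol")
  }
  jsonlite::write_json(
    lapply(unname(results), .tuning_result_record),
    file.path(config$output_dir, paste0(spikes$recording_id, "_results.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  utils::write.csv(summary_table(results),
                   file.path(config$output_dir,
                             paste0(spikes$recording_id, "_summary.csv")),
                   row.names = FALSE)
  manifest <- list(
    package = "skytuner",
    version = as.character(utils::packageVersion("skytuner")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = list(spikes = normalizePath(spikes_path),
                  protocol = normalizePath(protocol_path)),
    config = unclass(config)
  )
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

#' Simulate a preset neuron and write its spike train and protocol
#'
#' Convenience front end over [scenario_library()],
#' [simulate_spike_train()], [write_spike_csv()] and
#' [write_protocol_yaml()], used by the command-line interface.
#'
#' @param preset preset name from [scenario_library()], or a
#'   [neuron_model()].
#' @param protocol a [stimulus_protocol()]; the default is three cw and
#'   three ccw polarizer rotations at 30 degrees/s (spot presets rotate a
#'   light spot instead).
#' @param seed integer seed.
#' @param out_dir output directory.
#' @return invisibly, list with `spikes_path`, `protocol_path`, `spikes`,
#'   `protocol`.
#' @export
simulate_to_files <- function(preset, protocol = NULL, seed = 1, out_dir = ".") {
  params <- if (inherits(preset, "neuron_model")) preset else {
    lib <- scenario_library()
    if (!preset %in% names(lib)) {
      skytuner_error("skytuner_config_error",
                     sprintf("unknown preset '%s' (have: %s)", preset,
                             paste(names(lib), collapse = ", ")))
    }
    lib[[preset]]
  }
  if (is.null(protocol)) {
    kind <- if (params$harmonic == 2) "polarizer_blue" else "spot_green"
    protocol <- make_protocol(kind, velocities = 30, n_turns = 3)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spikes <- simulate_spike_train(params, protocol, seed = seed)
  sp <- file.path(out_dir, paste0(params$label, "_spikes.csv"))
  pp <- file.path(out_dir, paste0(params$label, "_protocol.yaml"))
  write_spike_csv(spikes, sp)
  write_protocol_yaml(protocol, pp)
  invisible(list(spikes_path = sp, protocol_path = pp,
                 spikes = spikes, protocol = protocol))
}
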