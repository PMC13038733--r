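#' Rotation segment of a stimulus protocol
#'
#' One block of consecutive full 360-degree rotations of a single stimulus.
#' The polarizer presents the angle of polarization (AoP), an axial quantity
#' with 180-degree periodicity; unpolarized light spots present an azimuth
#' with 360-degree periodicity. Periodicity is derived from the stimulus
#' kind and cannot be set inconsistently.
#'
#' @param stimulus_kind one of `"polarizer_blue"`, `"spot_green"`,
#'   `"spot_uv"`.
#' @param direction rotation direction, `"cw"` (0 to 360, increasing angle)
#'   or `"ccw"` (360 to 0, decreasing angle).
#' @param angular_velocity rotation speed in degrees per second (> 0);
#'   typical protocol values are 30, 40 or 60.
#' @param start_time absolute time of rotation onset, seconds (>= 0).
#' @param start_angle presented angle at `start_time`, degrees in \[0, 360).
#'   0 is the E-vector parallel to the body axis (polarizer) or the azimuth
#'   directly anterior (spots).
#' @param n_turns number of consecutive full rotations (positive integer;
#'   0 allowed for an empty segment).
#' @param elevation stimulus elevation in degrees (metadata; 90 = zenith for
#'   the polarizer, 45 for the light spots).
#' @param visual_angle angular size of the stimulus in degrees (metadata).
#'
#' @return An object of class `rotation_segment`: a list with the above
#'   fields plus `periodicity` (180 for the polarizer, else 360) and
#'   `duration` (`n_turns * 360 / angular_velocity`, seconds).
#' @export
#' @examples
#' rotation_segment("polarizer_blue", "cw", 30, start_time = 30, n_turns = 3)
rotation_segment <- function(stimulus_kind = c("polarizer_blue", "spot_green", "spot_uv"),
                             direction = c("cw", "ccw"),
                             angular_velocity,
                             start_time = 0,
                             start_angle = 0,
                             n_turns = 3,
                             elevation = NULL,
                             visual_angle = NULL) {
  stimulus_kind <- match.arg(stimulus_kind)
  direction <- match.arg(direction)
  stopifnot(
    is.numeric(angular_velocity), length(angular_velocity) == 1L,
    is.finite(angular_velocity), angular_velocity > 0,
    is.numeric(start_time), length(start_time) == 1L, start_time >= 0,
    is.numeric(start_angle), length(start_angle) == 1L,
    start_angle >= 0, start_angle < 360,
    is.numeric(n_turns), length(n_turns) == 1L,
    n_turns >= 0, n_turns == round(n_turns)
  )
  if (is.null(elevation)) {
    elevation <- if (stimulus_kind == "polarizer_blue") 90 else 45
  }
  if (is.null(visual_angle)) {
    visual_angle <- if (stimulus_kind == "polarizer_blue") 32.5 else 16.3
  }
  structure(
    list(
      stimulus_kind = stimulus_kind,
      direction = direction,
      angular_velocity = angular_velocity,
      start_time = start_time,
      start_angle = start_angle,
      n_turns = as.integer(n_turns),
      periodicity = if (stimulus_kind == "polarizer_blue") 180 else 360,
      elevation = elevation,
      visual_angle = visual_angle,
      duration = n_turns * 360 / angular_velocity
    ),
    class = "rotation_segment"
  )
}

#' Stimulus protocol: the full schedule of one recording
#'
#' Collects rotation segments, stimulus-off intervals (all lights off; the
#' only periods used for background-activity estimation) and stationary
#' lights-on intervals (stimulus present but not rotating; excluded from
#' both tuning and background analysis).
#'
#' @param segments list of [rotation_segment()] objects, non-overlapping in
#'   time.
#' @param off_intervals list of numeric `c(start, end)` pairs, seconds.
#' @param stationary_intervals list of lists with fields `start`, `end`,
#'   `stimulus_kind`, `angle` (degrees) for lights-on but non-rotating
#'   periods.
#' @param exclude_first_rotation drop the first presented rotation of each
#'   stimulus kind from analysis (default `TRUE`), because stimulus onset
#'   commonly evokes a phasic transient unrelated to angular tuning.
#'
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(segments,
                              off_intervals = list(),
                              stationary_intervals = list(),
                              exclude_first_rotation = TRUE) {
  if (inherits(segments, "rotation_segment")) segments <- list(segments)
  stopifnot(is.list(segments), all(vapply(segments, inherits, logical(1), "rotation_segment")))
  off_intervals <- lapply(off_intervals, function(iv) {
    iv <- as.numeric(iv)
    stopifnot(length(iv) == 2L, iv[1] <= iv[2], iv[1] >= 0)
    iv
  })
  # all intervals (segments, off, stationary) must be mutually disjoint
  spans <- lapply(segments, function(s) c(s$start_time, s$start_time + s$duration))
  spans <- c(spans, off_intervals,
             lapply(stationary_intervals, function(iv) c(iv$start, iv$end)))
  if (length(spans) > 1L) {
    m <- do.call(rbind, spans)
    m <- m[order(m[, 1]), , drop = FALSE]
    if (any(m[-1, 1] < m[-nrow(m), 2] - 1e-9)) {
      skytuner_error("skytuner_overlap_error",
                     "protocol intervals overlap in time")
    }
  }
  structure(
    list(
      segments = segments,
      off_intervals = off_intervals,
      stationary_intervals = stationary_intervals,
      exclude_first_rotation = isTRUE(exclude_first_rotation)
    ),
    class = "stimulus_protocol"
  )
}

#' Spike train: ordered spike event times of one recording
#'
#' @param times numeric vector of spike times in seconds, non-negative;
#'   sorted on construction.
#' @param recording_id identifier carried through to outputs.
#' @param meta optional free-form metadata list.
#'
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, recording_id = "recording", meta = list()) {
  times <- as.numeric(times)
  if (any(!is.finite(times))) {
    skytuner_error("skytuner_parse_error", "non-finite spike times")
  }
  if (any(times < 0)) {
    skytuner_error("skytuner_parse_error", "negative spike times")
  }
  structure(
    list(times = sort(times), recording_id = recording_id, meta = meta),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train '%s': %d spikes", x$recording_id, length(x$times)))
  if (length(x$times)) cat(sprintf(", %.3f-%.3f s", min(x$times), max(x$times)))
  cat(">\n")
  invisible(x)
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("<stimulus_protocol: %d segment(s), %d off interval(s)%s>\n",
              length(x$segments), length(x$off_intervals),
              if (x$exclude_first_rotation) ", first rotation excluded" else ""))
  invisible(x)
}

#' Presented stimulus angle at an absolute time
#'
#' Linear motion within a segment: clockwise rotation increases the angle
#' (0 to 360), counterclockwise decreases it (360 to 0); the result is
#' reduced to \[0, 360).
#'
#' @param segment a [rotation_segment()].
#' @param t absolute time(s) in seconds; each must fall in the half-open
#'   segment window `[start_time, start_time + duration)`.
#' @return angle(s) in degrees, \[0, 360).
#' @export
#' @examples
#' seg <- rotation_segment("polarizer_blue", "cw", 30, n_turns = 3)
#' angle_at_time(seg, 2) # 60
angle_at_time <- function(segment, t) {
  stopifnot(inherits(segment, "rotation_segment"))
  t <- as.numeric(t)
  if (any(t < segment$start_time | t >= segment$start_time + segment$duration)) {
    skytuner_error("skytuner_window_error",
                   "time outside the segment's rotation window")
  }
  s <- if (segment$direction == "cw") 1 else -1
  (segment$start_angle + s * segment$angular_velocity * (t - segment$start_time)) %% 360
}

#' Enumerate single-rotation trial windows of a protocol
#'
#' Each full 360-degree turn of each segment becomes one trial window.
#' With `exclude_first_rotation` on, the first presented turn of each
#' stimulus kind (chronologically first across segments) is dropped.
#'
#' @param protocol a [stimulus_protocol()].
#' @return data frame, one row per retained window, in chronological order:
#'   `segment` (index into `protocol$segments`), `stimulus_kind`,
#'   `direction`, `turn` (1-based index within its segment), `t_start`,
#'   `t_end` (half-open window, seconds), `velocity` (deg/s),
#'   `periodicity` (180 or 360).
#' @export
rotation_windows <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  rows <- lapply(seq_along(protocol$segments), function(i) {
    seg <- protocol$segments[[i]]
    if (seg$n_turns == 0L) return(NULL)
    turn_dur <- 360 / seg$angular_velocity
    turns <- seq_len(seg$n_turns)
    data.frame(
      segment = i,
      stimulus_kind = seg$stimulus_kind,
      direction = seg$direction,
      turn = turns,
      t_start = seg$start_time + (turns - 1) * turn_dur,
      t_end = seg$start_time + turns * turn_dur,
      velocity = seg$angular_velocity,
      periodicity = seg$periodicity,
      stringsAsFactors = FALSE
    )
  })
  win <- do.call(rbind, rows)
  if (is.null(win) || nrow(win) == 0L) {
    return(data.frame(
      segment = integer(), stimulus_kind = character(),
      direction = character(), turn = integer(),
      t_start = numeric(), t_end = numeric(),
      velocity = numeric(), periodicity = numeric(),
      stringsAsFactors = FALSE
    ))
  }
  win <- win[order(win$t_start), , drop = FALSE]
  if (protocol$exclude_first_rotation) {
    drop <- !duplicated(win$stimulus_kind) # first presented turn per kind
    win <- win[!drop, , drop = FALSE]
  }
  rownames(win) <- NULL
  win
}

#' Convert spike times within a trial window to stimulus angles
#'
#' @param spikes a [spike_train()].
#' @param window one row of the data frame returned by
#'   [rotation_windows()], together with the owning protocol's segment; in
#'   practice pass `protocol` too and the row index, or a one-row data
#'   frame subset.
#' @param protocol the [stimulus_protocol()] the window came from.
#' @return numeric vector of angles in degrees \[0, 360), one per spike in
#'   the half-open window `[t_start, t_end)`, in spike order. Empty when no
#'   spike falls inside.
#' @export
spike_angles <- function(spikes, window, protocol) {
  stopifnot(inherits(spikes, "spike_train"),
            is.data.frame(window), nrow(window) == 1L,
            inherits(protocol, "stimulus_protocol"))
  seg <- protocol$segments[[window$segment]]
  t <- spikes$times
  t <- t[t >= window$t_start & t < window$t_end]
  if (!length(t)) return(numeric(0))
  angle_at_time(seg, t)
}

#' Collect per-trial spike angles for one stimulus kind and rotation group
#'
#' Convenience wrapper: enumerates retained rotation windows, filters by
#' stimulus kind and direction group, and converts spike times to angles
#' per trial.
#'
#' @inheritParams spike_angles
#' @param stimulus_kind stimulus to analyze; `NULL` keeps all kinds (only
#'   sensible when the protocol has one kind).
#' @param group `"cw"`, `"ccw"`, or `"both"`.
#' @return list with `windows` (the retained window data frame) and
#'   `angles` (list of numeric vectors, one per window row).
#' @export
trial_angles <- function(spikes, protocol, stimulus_kind = NULL, group = c("both", "cw", "ccw")) {
  group <- match.arg(group)
  win <- rotation_windows(protocol)
  if (!is.null(stimulus_kind)) win <- win[win$stimulus_kind == stimulus_kind, , drop = FALSE]
  if (group != "both") win <- win[win$direction == group, , drop = FALSE]
  rownames(win) <- NULL
  ang <- lapply(seq_len(nrow(win)), function(i) {
    spike_angles(spikes, win[i, , drop = FALSE], protocol)
  })
  list(windows = win, angles = ang)
}
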