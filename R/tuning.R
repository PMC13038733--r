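#' Background activity from stimulus-off periods
#'
#' Counts spikes in consecutive, non-overlapping 1-second bins placed from
#' the start of each stimulus-off interval; a trailing partial bin is
#' discarded. Mean and SD of the bin counts give the spontaneous firing
#' rate in impulses per second.
#'
#' @param spikes a [spike_train()].
#' @param protocol a [stimulus_protocol()] whose `off_intervals` define the
#'   baseline periods.
#' @return object of class `background_activity`: list with `mean_rate`,
#'   `sd` (impulses/s), `n_bins` and `source_intervals`.
#' @export
background_stats <- function(spikes, protocol) {
  stopifnot(inherits(spikes, "spike_train"), inherits(protocol, "stimulus_protocol"))
  counts <- numeric(0)
  for (iv in protocol$off_intervals) {
    nb <- floor(iv[2] - iv[1] + 1e-9)
    if (nb < 1) next
    edges <- iv[1] + 0:nb
    t <- spikes$times[spikes$times >= iv[1] & spikes$times < iv[1] + nb]
    counts <- c(counts, tabulate(findInterval(t, edges), nbins = nb))
  }
  if (length(counts) < 2L) {
    skytuner_error("skytuner_insufficient_baseline",
                   "fewer than 2 complete 1-s stimulus-off bins available")
  }
  structure(
    list(
      mean_rate = mean(counts),
      sd = stats::sd(counts),
      n_bins = length(counts),
      source_intervals = protocol$off_intervals
    ),
    class = "background_activity"
  )
}

#' @export
print.background_activity <- function(x, ...) {
  cat(sprintf("<background: %.2f +/- %.2f imp/s (n = %d 1-s bins)>\n",
              x$mean_rate, x$sd, x$n_bins))
  invisible(x)
}

# Pair indices: cw and ccw trials paired in presentation order; leftovers
# become singleton "pairs".
.trial_pairs <- function(directions) {
  icw <- which(directions == "cw")
  iccw <- which(directions == "ccw")
  np <- min(length(icw), length(iccw))
  pairs <- list()
  if (np > 0) pairs <- lapply(seq_len(np), function(k) c(icw[k], iccw[k]))
  left <- c(icw[seq_len(length(icw) - np) + np],
            iccw[seq_len(length(iccw) - np) + np])
  c(pairs, lapply(left, identity))
}

#' Per-trial angular histograms and across-pair mean tuning curve
#'
#' Counts the spike angles of each trial in half-open angular bins anchored
#' at 0 degrees, converts counts to firing rates via the dwell time of the
#' stimulus in one bin (`bin_width / angular_velocity` of that trial), and
#' averages bin rates across clockwise/counterclockwise trial pairs
#' (presentation order; unpaired trials count as singleton pairs). SD per
#' bin is taken across pairs.
#'
#' @param trials result of [trial_angles()]: per-trial spike angles plus
#'   their window metadata.
#' @param bin_width bin width in degrees; must divide 360 (the protocolar
#'   choices are 10, 15 and 20).
#' @return object of class `binned_tuning`: list with `bin_width`,
#'   `bin_edges` (lower edges), `bin_centers`, `counts` and `rates`
#'   (trials x bins matrices), `pair_rates` (pairs x bins), `mean_rate`,
#'   `sd_rate` (per bin, across pairs), `n_rotations`, `group`,
#'   `periodicity`, `windows`.
#' @export
bin_spike_angles <- function(trials, bin_width = 15) {
  if (360 %% bin_width != 0) {
    skytuner_error("skytuner_config_error", "bin_width must divide 360")
  }
  win <- trials$windows
  if (is.null(win) || nrow(win) < 1L) {
    skytuner_error("skytuner_insufficient_data", "no retained trials to bin")
  }
  nbins <- as.integer(360 / bin_width)
  edges <- seq(0, 360, by = bin_width)
  counts <- t(vapply(trials$angles, function(a) {
    idx <- floor((a %% 360) / bin_width) + 1L # half-open [edge, edge+width)
    tabulate(idx, nbins = nbins)
  }, integer(nbins)))
  dwell <- bin_width / win$velocity
  rates <- counts / dwell
  pairs <- .trial_pairs(win$direction)
  pair_rates <- t(vapply(pairs, function(ix) colMeans(rates[ix, , drop = FALSE]),
                         numeric(nbins)))
  group <- if (all(win$direction == "cw")) "cw"
           else if (all(win$direction == "ccw")) "ccw" else "both"
  structure(
    list(
      bin_width = bin_width,
      bin_edges = edges[-length(edges)],
      bin_centers = edges[-length(edges)] + bin_width / 2,
      counts = counts,
      rates = rates,
      pair_rates = pair_rates,
      mean_rate = colMeans(pair_rates),
      sd_rate = if (nrow(pair_rates) > 1) apply(pair_rates, 2, stats::sd)
                else rep(NA_real_, nbins),
      n_rotations = nrow(win),
      group = group,
      periodicity = unique(win$periodicity)[1],
      windows = win
    ),
    class = "binned_tuning"
  )
}

#' Full tuning analysis for one neuron, stimulus and rotation group
#'
#' Runs the complete chain: retained-trial spike angles, Phi_max and mean
#' vector length r from pooled spike angles (axial doubling for the
#' polarizer), circular SD and 95% confidence arc, binned tuning curve,
#' and the linear-circular correlation of per-bin mean rates against bin
#' centers. The sample size of the test is the number of bins. R^2 is
#' withheld (NA) when the correlation is not significant at `alpha`,
#' mirroring standard reporting of non-significant tuning.
#'
#' @inheritParams trial_angles
#' @param bin_width angular bin width in degrees (10, 15 or 20 are the
#'   protocolar values; any divisor of 360 is accepted).
#' @param alpha significance level of the correlation gate (default 0.05).
#' @param phi_from `"spikes"` (default): Phi_max/r from pooled individual
#'   spike angles, each spike one unit vector; `"bins"`: from bin centers
#'   weighted by mean rate.
#' @param sd_convention passed to [circ_sd_from_r()].
#' @param background optional [background_stats()] result; computed from
#'   the protocol's off intervals when `NULL` and possible.
#' @return object of class `tuning_result`: list with `phi_max`, `r`,
#'   `circ_sd`, `ci95_halfarc`, `R2` (NA unless significant), `p`,
#'   `significant`, `n_rotations`, `n_samples` (= number of bins),
#'   `group`, `stimulus_kind`, `periodicity`, `binned`
#'   (the [bin_spike_angles()] object), `background`, `opponency`.
#' @export
compute_tuning <- function(spikes, protocol, stimulus_kind = NULL,
                           group = c("both", "cw", "ccw"), bin_width = 15,
                           alpha = 0.05,
                           phi_from = c("spikes", "bins"),
                           sd_convention = c("angular_deviation", "circular_sd"),
                           background = NULL) {
  group <- match.arg(group)
  phi_from <- match.arg(phi_from)
  sd_convention <- match.arg(sd_convention)
  if (is.null(stimulus_kind)) {
    kinds <- unique(vapply(protocol$segments, `[[`, character(1), "stimulus_kind"))
    if (length(kinds) != 1L) {
      skytuner_error("skytuner_config_error",
                     "stimulus_kind must be given for multi-stimulus protocols")
    }
    stimulus_kind <- kinds
  }
  trials <- trial_angles(spikes, protocol, stimulus_kind, group)
  if (nrow(trials$windows) < 1L) {
    skytuner_error("skytuner_insufficient_data",
                   sprintf("no retained %s trials of stimulus '%s'", group, stimulus_kind))
  }
  if (is.null(background)) {
    background <- tryCatch(background_stats(spikes, protocol),
                           skytuner_error = function(e) NULL)
  }
  binned <- bin_spike_angles(trials, bin_width)
  periodicity <- binned$periodicity
  pooled <- unlist(trials$angles)

  est <- tryCatch({
    if (phi_from == "spikes") {
      phi_max(pooled, periodicity)
    } else {
      phi_max(binned$bin_centers, periodicity, weights = binned$mean_rate)
    }
  }, skytuner_error = function(e) NULL)

  if (is.null(est)) {
    phi <- NA_real_; r <- 0; csd <- circ_sd_from_r(0, sd_convention); ci <- NA_real_
  } else {
    phi <- est$phi_max; r <- est$r
    csd <- circ_sd_from_r(r, sd_convention)
    n_phi <- if (phi_from == "spikes") length(pooled) else length(binned$bin_centers)
    ci <- if (n_phi >= 2) ci95_mean_direction(n_phi, r, periodicity) else NA_real_
  }

  test <- tryCatch(
    linear_circular_corr(binned$mean_rate, binned$bin_centers, periodicity),
    skytuner_error = function(e) NULL
  )
  if (is.null(test)) {
    R2 <- NA_real_; p <- 1
  } else {
    R2 <- test$R2; p <- test$p
  }
  significant <- is.finite(p) && p < alpha && !is.na(phi)
  if (!significant) R2 <- NA_real_ # withheld unless the correlation is significant

  opp <- if (!is.na(phi) && !is.null(background)) {
    opponency_classification(binned, background, phi)
  } else "none"

  structure(
    list(
      recording_id = spikes$recording_id,
      stimulus_kind = stimulus_kind,
      group = group,
      periodicity = periodicity,
      phi_max = phi,
      r = r,
      circ_sd = csd,
      ci95_halfarc = ci,
      R2 = R2,
      p = p,
      significant = significant,
      n_rotations = binned$n_rotations,
      n_samples = length(binned$bin_centers),
      n_spikes = length(pooled),
      bin_width = bin_width,
      alpha = alpha,
      phi_from = phi_from,
      opponency = opp,
      binned = binned,
      background = background
    ),
    class = "tuning_result"
  )
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning '%s' %s/%s: ", x$recording_id, x$stimulus_kind, x$group))
  if (x$significant) {
    cat(sprintf("Phi_max = %.1f deg, r = %.2f, R2 = %.2f (p = %.2g, n = %d rotations)",
                x$phi_max, x$r, x$R2, x$p, x$n_rotations))
  } else {
    cat(sprintf("n.s. (p = %.2g, n = %d rotations)", x$p, x$n_rotations))
  }
  cat(">\n")
  invisible(x)
}

#' Opponency classification of a tuning curve
#'
#' A neuron is opponent when it is excited above background at the
#' preferred angle Phi_max and inhibited below background at the
#' anti-preferred angle Phi_min = Phi_max + periodicity/2: the bin
#' containing Phi_min must fall below `mean - sd` of background while the
#' bin at Phi_max exceeds `mean + sd`. Excitation without the inhibitory
#' trough is classified `excitation_only`. For axial stimuli both
#' presentations of each axial class (angle and angle + 180) are averaged.
#'
#' @param binned a [bin_spike_angles()] result.
#' @param background a [background_stats()] result.
#' @param phi_max preferred angle in degrees (on the reported scale,
#'   \[0, periodicity)); `NA` yields `"none"`.
#' @return `"opponent"`, `"excitation_only"` or `"none"`.
#' @export
opponency_classification <- function(binned, background, phi_max) {
  if (is.null(phi_max) || is.na(phi_max)) return("none")
  periodicity <- binned$periodicity
  phi_min <- (phi_max + periodicity / 2) %% periodicity
  rate_at <- function(angle) {
    # mean over the bins presenting this axial/azimuthal class
    reps <- if (periodicity == 180) c(angle, angle + 180) else angle
    idx <- floor((reps %% 360) / binned$bin_width) + 1L
    mean(binned$mean_rate[idx])
  }
  hi <- rate_at(phi_max) > background$mean_rate + background$sd
  lo <- rate_at(phi_min) < background$mean_rate - background$sd
  if (hi && lo) "opponent" else if (hi) "excitation_only" else "none"
}

#' Rotation-direction mismatch of the preferred angle
#'
#' Smallest angular distance between the Phi_max estimates obtained from
#' clockwise-only and counterclockwise-only rotations, under the shared
#' periodicity. Polarization-sensitive neurons commonly show such a
#' mismatch, interpreted as an anticipatory shift of tuning against the
#' rotation direction.
#'
#' @param result_cw,result_ccw [compute_tuning()] results with defined
#'   `phi_max` and equal periodicity.
#' @return mismatch in degrees in \[0, periodicity/2\], or `NA` when either
#'   preferred angle is undefined.
#' @export
#' @examples
#' angular_distance(107.8, 154.4, 180) # 46.6 deg axial mismatch
direction_mismatch <- function(result_cw, result_ccw) {
  stopifnot(inherits(result_cw, "tuning_result"), inherits(result_ccw, "tuning_result"))
  if (result_cw$periodicity != result_ccw$periodicity) {
    skytuner_error("skytuner_domain_error", "periodicities differ between groups")
  }
  if (is.na(result_cw$phi_max) || is.na(result_ccw$phi_max)) return(NA_real_)
  angular_distance(result_cw$phi_max, result_ccw$phi_max, result_cw$periodicity)
}

#' Sliding-window mean firing rate
#'
#' Centered moving-average rate estimate on a uniform time grid: spikes in
#' `[t - window/2, t + window/2]` divided by the window duration actually
#' covered by the recording span (edges use truncated windows).
#'
#' @param spikes a [spike_train()].
#' @param window window size in seconds (default 1).
#' @param grid_step grid spacing in seconds (default 0.01).
#' @param t_range numeric `c(start, end)`; defaults to `0` through the
#'   last spike time.
#' @return data frame with `time` (s) and `rate` (impulses/s).
#' @export
moving_average_rate <- function(spikes, window = 1, grid_step = 0.01, t_range = NULL) {
  stopifnot(inherits(spikes, "spike_train"), window > 0, grid_step > 0)
  if (is.null(t_range)) {
    t_range <- c(0, if (length(spikes$times)) max(spikes$times) else window)
  }
  grid <- seq(t_range[1], t_range[2], by = grid_step)
  lo <- pmax(grid - window / 2, t_range[1])
  hi <- pmin(grid + window / 2, t_range[2])
  n <- findInterval(hi, spikes$times, left.open = FALSE) -
       findInterval(lo, spikes$times, left.open = TRUE)
  data.frame(time = grid, rate = n / pmax(hi - lo, .Machine$double.eps))
}
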